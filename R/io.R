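#' Normalize sequence residues to the DNA alphabet
#'
#' Uppercases the input and converts U to T so all downstream stages work on
#' one alphabet ({A,C,G,T,N}). RNA spelling (U) only reappears in rendered
#' motif tables, which carry both DNA and RNA columns.
#'
#' @param x Character vector of nucleotide sequences. Case-insensitive;
#'   residues must be among A, C, G, T, U, N.
#' @return Character vector of the same length over {A,C,G,T,N}, with a
#'   `source_alphabet` attribute: `"rna"` for elements that contained a U,
#'   `"dna"` otherwise. Idempotent.
#' @examples
#' normalize_to_dna("uuAcg")
#' @export
normalize_to_dna <- function(x) {
  stopifnot(is.character(x))
  up <- toupper(x)
  bad <- grepl("[^ACGTUN]", up)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGTUN]", "", up[bad]), "")))
    stop("invalid residue(s) ", paste(sQuote(chars), collapse = ", "),
         " in sequence(s) ", paste(which(bad), collapse = ", "))
  }
  alph <- ifelse(grepl("U", up, fixed = TRUE), "rna", "dna")
  out <- gsub("U", "T", up, fixed = TRUE)
  attr(out, "source_alphabet") <- alph
  out
}

#' Read transcript or genome sequences from a FASTA file
#'
#' Reads a (possibly gzipped) multi-record FASTA file and normalizes every
#' record to the DNA alphabet via [normalize_to_dna()]. mRNA/EST files may be
#' in RNA spelling; whether a record contained U is kept in the metadata.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, with metadata
#'   columns `description` (header text after the id) and `source_alphabet`
#'   (`"rna"`/`"dna"`). Record order is preserved.
#'   Duplicate ids and empty sequences are errors.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      description = character(0), source_alphabet = character(0))
    return(out)
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    stop("malformed FASTA header (empty id) at record ",
         which(ids == "")[1L])
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- as.character(raw)
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence at record ", which(nchar(seqs) == 0L)[1L])
  }
  norm <- tryCatch(normalize_to_dna(unname(seqs)),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  out <- Biostrings::DNAStringSet(norm)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    description = unname(desc),
    source_alphabet = attr(norm, "source_alphabet"))
  out
}

.site_table_cols <- c("site_id", "chrom", "strand", "tailstart_coord",
                      "region201", "n_source_mrnas")

.validate_site_table <- function(rows, where = "site table") {
  stopifnot(is.data.frame(rows))
  missing <- setdiff(.site_table_cols, names(rows))
  if (length(missing)) {
    stop(where, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  badlen <- which(nchar(rows$region201) != 201L)
  if (length(badlen)) {
    stop(where, ": region201 not 201 characters at row ", badlen[1L])
  }
  badn <- which(rows$n_source_mrnas < 1L)
  if (length(badn)) {
    stop(where, ": n_source_mrnas < 1 at row ", badn[1L])
  }
  badstr <- which(!rows$strand %in% c("+", "-"))
  if (length(badstr)) {
    stop(where, ": strand must be '+' or '-' at row ", badstr[1L])
  }
  invisible(rows)
}

#' Write and read the unique-site table
#'
#' The site table is the pipeline's central artifact: one row per unique
#' poly(A) site with its 201-nt region and genomic locus, serialized as TSV
#' with a fixed header. `read_site_table(write_site_table(x))` is the
#' identity on valid tables.
#'
#' @param rows A data.frame with columns `site_id`, `chrom`, `strand`
#'   (`+`/`-`), `tailstart_coord` (1-based genomic coordinate of the
#'   tail-start base), `region201` (201-character region) and
#'   `n_source_mrnas`. Extra columns are dropped on write.
#' @param path Output (input) file path.
#' @return `write_site_table()` returns `path` invisibly; `read_site_table()`
#'   returns the validated data.frame.
#' @export
write_site_table <- function(rows, path) {
  .validate_site_table(rows)
  utils::write.table(rows[.site_table_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  rows <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           "character", "integer",
                                           "character", "integer"),
                            col.names = .site_table_cols,
                            stringsAsFactors = FALSE)
  .validate_site_table(rows, where = path)
  rows
}
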