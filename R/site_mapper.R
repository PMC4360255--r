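#' Convert between paper coordinates and region-string offsets
#'
#' The 201-nt poly(A) site region uses a coordinate system with no position
#' zero: the tail attachment base (last templated base) is position -1 and
#' the tail-start base is position 1, so the region spans positions
#' -100..-1 and 1..101. `paper_to_index()` maps a paper position to the
#' zero-based offset into the 201-character region string (-100 -> 0,
#' -1 -> 99, 1 -> 100, 5 -> 104, 101 -> 200); `index_to_paper()` is its
#' inverse.
#'
#' @param paper_pos Integer vector of positions in `[-100,-1]` or `[1,101]`.
#' @param index Integer vector of zero-based offsets in `[0,200]`.
#' @return Integer vector of offsets (positions).
#' @export
paper_to_index <- function(paper_pos) {
  p <- as.integer(paper_pos)
  bad <- is.na(p) | p == 0L | p < -100L | p > 101L
  if (any(bad)) stop("paper position out of range [-100,-1] U [1,101]: ",
                     paste(paper_pos[bad], collapse = ", "))
  ifelse(p < 0L, p + 100L, p + 99L)
}

#' @rdname paper_to_index
#' @export
index_to_paper <- function(index) {
  i <- as.integer(index)
  bad <- is.na(i) | i < 0L | i > 200L
  if (any(bad)) stop("region index out of range [0,200]: ",
                     paste(index[bad], collapse = ", "))
  ifelse(i <= 99L, i - 100L, i - 99L)
}

# paper positions of all 201 region offsets, in order
.region_positions <- function() index_to_paper(0:200)

#' Build an exact-match index over a reference genome
#'
#' @param genome A [Biostrings::DNAStringSet] (e.g. from [read_fasta()]) or
#'   a path to a genome FASTA file. Sequence names are chromosome names.
#' @return An object of class `genome_index` used by [map_anchor()] and
#'   [assemble_region()].
#' @export
genome_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    stop("genome sequences must have unique names")
  }
  structure(list(seqs = genome), class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$seqs), "sequence(s),",
      sum(Biostrings::width(x$seqs)), "bp total\n")
  invisible(x)
}

#' Map an anchor to the genome with zero mismatches
#'
#' Finds all and only the verbatim occurrences of the anchor on either
#' strand of the reference. Anchors containing N never match (an N in the
#' transcript cannot be confirmed against the genome under the
#' zero-mismatch rule).
#'
#' @param index A [genome_index()].
#' @param anchor Anchor sequence (one string, typically 100 nt).
#' @return data.frame with one row per locus: `chrom`, `strand` (`+`/`-`)
#'   and `anchor_end_coord`, the 1-based genomic coordinate of the anchor's
#'   3'-most base in transcription orientation (the tail attachment base;
#'   the tail-start base is one base further 3' of it).
#' @export
map_anchor <- function(index, anchor) {
  stopifnot(inherits(index, "genome_index"),
            is.character(anchor), length(anchor) == 1L)
  empty <- data.frame(chrom = character(0), strand = character(0),
                      anchor_end_coord = integer(0),
                      stringsAsFactors = FALSE)
  if (grepl("N", anchor, fixed = TRUE)) return(empty)
  pat <- Biostrings::DNAString(anchor)
  rcp <- Biostrings::reverseComplement(pat)
  out <- empty
  for (chrom in names(index$seqs)) {
    subj <- index$seqs[[chrom]]
    fwd <- Biostrings::matchPattern(pat, subj)
    if (length(fwd)) {
      out <- rbind(out, data.frame(
        chrom = chrom, strand = "+",
        anchor_end_coord = BiocGenerics::end(fwd),
        stringsAsFactors = FALSE))
    }
    rev <- Biostrings::matchPattern(rcp, subj)
    if (length(rev)) {
      # on "-" the anchor's 3' end in transcription orientation is the
      # plus-strand start of the reverse-complement match
      out <- rbind(out, data.frame(
        chrom = chrom, strand = "-",
        anchor_end_coord = BiocGenerics::start(rev),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# Bulk exact mapping of many fixed-width anchors via a PDict; one pass per
# chromosome and strand. Returns one row per (anchor, locus).
#' @noRd
map_anchors_bulk <- function(index, anchors) {
  empty <- data.frame(anchor = character(0), chrom = character(0),
                      strand = character(0), anchor_end_coord = integer(0),
                      stringsAsFactors = FALSE)
  anchors <- unique(anchors)
  ok <- !grepl("N", anchors, fixed = TRUE) &
    nchar(anchors) == nchar(anchors[1L])
  if (length(anchors) == 0L || !any(ok)) return(empty)
  usable <- anchors[ok]
  pd <- Biostrings::PDict(usable)
  pd_rc <- Biostrings::PDict(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(usable))))
  out <- list()
  for (chrom in names(index$seqs)) {
    subj <- index$seqs[[chrom]]
    hits <- Biostrings::matchPDict(pd, subj)
    ends <- IRanges::end(hits)
    n <- lengths(ends)
    if (sum(n)) {
      out[[length(out) + 1L]] <- data.frame(
        anchor = rep(usable, n), chrom = chrom, strand = "+",
        anchor_end_coord = unlist(ends, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
    hits_rc <- Biostrings::matchPDict(pd_rc, subj)
    starts <- IRanges::start(hits_rc)
    n <- lengths(starts)
    if (sum(n)) {
      out[[length(out) + 1L]] <- data.frame(
        anchor = rep(usable, n), chrom = chrom, strand = "-",
        anchor_end_coord = unlist(starts, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the 201-nt poly(A) site region at a mapped locus
#'
#' The region is the 100-nt anchor (paper positions -100..-1), the genomic
#' base corresponding to the tail-start position (position 1), and the 100
#' nt downstream of it (positions 2..101, the 3' cleaved-off region), all in
#' transcription orientation; minus-strand fetches are reverse-complemented.
#' Loci with fewer than 101 genomic bases available past the anchor are
#' dropped (`NULL`), so downstream matrices stay fixed-width.
#'
#' @param index A [genome_index()].
#' @param locus A list or one-row data.frame with `chrom`, `strand`,
#'   `anchor_end_coord` as returned by [map_anchor()].
#' @return One-row data.frame with `chrom`, `strand`, `tailstart_coord`
#'   (1-based genomic coordinate of the base at paper position 1) and
#'   `region201`, or `NULL` when the contig ends too soon.
#' @export
assemble_region <- function(index, locus) {
  stopifnot(inherits(index, "genome_index"))
  chrom <- as.character(locus$chrom)
  strand <- as.character(locus$strand)
  e <- as.integer(locus$anchor_end_coord)
  subj <- index$seqs[[chrom]]
  if (is.null(subj)) stop("unknown chromosome: ", chrom)
  len <- length(subj)
  if (strand == "+") {
    if (e - 99L < 1L || e + 101L > len) return(NULL)
    region <- as.character(Biostrings::subseq(subj, e - 99L, e + 101L))
    tailstart <- e + 1L
  } else if (strand == "-") {
    if (e + 99L > len || e - 101L < 1L) return(NULL)
    window <- Biostrings::subseq(subj, e - 101L, e + 99L)
    region <- as.character(Biostrings::reverseComplement(window))
    tailstart <- e - 1L
  } else {
    stop("strand must be '+' or '-'")
  }
  data.frame(chrom = chrom, strand = strand, tailstart_coord = tailstart,
             region201 = region, stringsAsFactors = FALSE)
}

#' Collapse mapped regions into unique poly(A) sites
#'
#' Sites are counted as one unique site when the 100 nucleotides upstream of
#' the poly(A) site are identical, regardless of whether the downstream
#' cleaved-off region differs. The representative locus is the
#' lexicographically smallest (chrom, tailstart_coord, strand);
#' `n_source_mrnas` are summed over the group. Idempotent.
#'
#' @param regions data.frame of site rows with at least `chrom`, `strand`,
#'   `tailstart_coord`, `region201`; `n_source_mrnas` and `multiplicity`
#'   are carried through (defaulting to 1 when absent).
#' @return data.frame of unique sites with fresh sequential `site_id`s and a
#'   `n_loci_collapsed` column (group size).
#' @export
catalog_unique_sites <- function(regions) {
  stopifnot(is.data.frame(regions))
  if (!"n_source_mrnas" %in% names(regions)) regions$n_source_mrnas <- 1L
  if (!"multiplicity" %in% names(regions)) regions$multiplicity <- 1L
  if (!"n_loci_collapsed" %in% names(regions)) {
    regions$n_loci_collapsed <- 1L
  }
  if (nrow(regions) == 0L) {
    regions$site_id <- character(0)
    return(regions)
  }
  up100 <- substr(regions$region201, 1L, 100L)
  ord <- order(regions$chrom, regions$tailstart_coord, regions$strand)
  regions <- regions[ord, , drop = FALSE]
  up100 <- up100[ord]
  grp <- match(up100, unique(up100))
  rep_idx <- which(!duplicated(grp))
  out <- regions[rep_idx, , drop = FALSE]
  out$n_source_mrnas <- as.integer(
    tapply(regions$n_source_mrnas, grp, sum)[as.character(grp[rep_idx])])
  out$n_loci_collapsed <- as.integer(
    tapply(regions$n_loci_collapsed, grp, sum)[as.character(grp[rep_idx])])
  out$site_id <- sprintf("site%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("site_id", setdiff(names(out), "site_id"))]
}
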