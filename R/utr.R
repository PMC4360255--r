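#' Find sense-direction open reading frames in a tail-stripped transcript
#'
#' Scans the three sense frames of the body (the residues 5' of the poly(A)
#' tail) for ATG-initiated ORFs ending at the first in-frame stop codon
#' (TAA, TAG, TGA). Because the tail is a run of A's, a stop codon may be
#' completed by the first one or two tail adenosines: a body ending `...TG`
#' reads TGA with one borrowed base, a body ending `...T` reads TAA with two
#' borrowed bases. Such ORFs are admitted with `borrowed_tail_bases` set;
#' they are what makes 3'UTR lengths of -1 and -2 possible.
#'
#' @param body Body sequence (one string, DNA alphabet), i.e. the transcript
#'   with its maximal terminal A-run removed. A `transcripts` row from
#'   [screen_transcripts()] may be passed instead.
#' @return data.frame with one row per ORF: `frame` (0/1/2), `start_coord`
#'   (1-based coordinate of the ATG's A), `stop_last_coord` (coordinate of
#'   the stop codon's last base; may exceed the body length by the borrowed
#'   bases), `aa_length` (codons before the stop, so the ATG counts and the
#'   stop does not) and `borrowed_tail_bases` (0-2).
#' @export
find_sense_orfs <- function(body) {
  if (is.data.frame(body)) body <- body$body
  stopifnot(is.character(body), length(body) == 1L)
  L <- nchar(body)
  seq2 <- paste0(body, "AA")  # the first two tail A's can complete a stop
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (f in 0:2) {
    if (f + 1L > nchar(seq2) - 2L) next
    starts <- seq.int(f + 1L, nchar(seq2) - 2L, by = 3L)
    codons <- substring(seq2, starts, starts + 2L)
    atg_i <- which(codons == "ATG")
    stop_i <- which(codons %in% stops)
    # a stop codon may not be built from borrowed bases alone
    stop_i <- stop_i[starts[stop_i] <= L]
    if (!length(atg_i)) next
    for (ai in atg_i) {
      si <- stop_i[stop_i > ai]
      if (!length(si)) next
      si <- si[1L]
      stop_last <- starts[si] + 2L
      out[[length(out) + 1L]] <- data.frame(
        frame = f,
        start_coord = starts[ai],
        stop_last_coord = stop_last,
        aa_length = (starts[si] - starts[ai]) %/% 3L,
        borrowed_tail_bases = max(0L, stop_last - L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), start_coord = integer(0),
                      stop_last_coord = integer(0), aa_length = integer(0),
                      borrowed_tail_bases = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the qualifying ORF for the 3'UTR calculation
#'
#' Among ORFs that could encode at least `min_aa` residues, picks the last
#' one -- the greatest stop coordinate, ties broken by the greatest start
#' coordinate (the distance to the site is measured from the stop codon, so
#' "last" is read as last-ending).
#'
#' @param orfs data.frame from [find_sense_orfs()].
#' @param min_aa Minimum encoded length in amino acids (default 110).
#' @return One-row data.frame, or `NULL` when no ORF qualifies.
#' @export
last_qualifying_orf <- function(orfs, min_aa = 110L) {
  stopifnot(is.data.frame(orfs))
  q <- orfs[orfs$aa_length >= min_aa, , drop = FALSE]
  if (nrow(q) == 0L) return(NULL)
  q[order(-q$stop_last_coord, -q$start_coord), , drop = FALSE][1L, ,
                                                               drop = FALSE]
}

#' 3'UTR length of a poly(A)-tailed transcript
#'
#' The 3'UTR length is the number of nucleotides between the stop codon and
#' the poly(A) site: `tailstart_tx_coord - stop_last_coord - 1`. When the
#' stop codon borrows 1-2 tail adenosines the length is -1 or -2 and the
#' transcript is flagged 3'UTR-less.
#'
#' @param transcript One transcript row from [screen_transcripts()] (needs
#'   `tailstart_tx_coord`), or the coordinate itself.
#' @param orf A qualifying ORF row from [last_qualifying_orf()], or `NULL`.
#' @return list with `utr_length` (integer, >= -2; `NA` when no ORF
#'   qualifies), `qualifying_orf` and `utr_less` (`TRUE` iff negative; `NA`
#'   when undeterminable).
#' @export
utr_length <- function(transcript, orf) {
  tailstart <- if (is.data.frame(transcript) || is.list(transcript)) {
    transcript$tailstart_tx_coord
  } else {
    transcript
  }
  stopifnot(is.numeric(tailstart), length(tailstart) == 1L)
  if (is.null(orf)) {
    return(list(utr_length = NA_integer_, qualifying_orf = NULL,
                utr_less = NA))
  }
  len <- as.integer(tailstart) - as.integer(orf$stop_last_coord) - 1L
  list(utr_length = len, qualifying_orf = orf, utr_less = len < 0L)
}

#' Per-transcript 3'UTR report
#'
#' Runs [find_sense_orfs()], [last_qualifying_orf()] and [utr_length()] over
#' a screened transcript set.
#'
#' @param transcripts `transcripts` data.frame from [screen_transcripts()].
#' @param min_aa Minimum ORF length in amino acids (default 110).
#' @return data.frame with `id`, `orf_start`, `orf_stop_last`, `aa_length`,
#'   `borrowed_tail_bases`, `utr_length`, `utr_less`, `qualified`.
#' @export
utr_report <- function(transcripts, min_aa = 110L) {
  stopifnot(is.data.frame(transcripts))
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    orf <- last_qualifying_orf(find_sense_orfs(tx$body), min_aa = min_aa)
    res <- utr_length(tx, orf)
    data.frame(id = tx$id,
               orf_start = if (is.null(orf)) NA_integer_ else orf$start_coord,
               orf_stop_last = if (is.null(orf)) NA_integer_ else
                 orf$stop_last_coord,
               aa_length = if (is.null(orf)) NA_integer_ else orf$aa_length,
               borrowed_tail_bases = if (is.null(orf)) NA_integer_ else
                 orf$borrowed_tail_bases,
               utr_length = res$utr_length,
               utr_less = res$utr_less,
               qualified = !is.null(orf),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize 3'UTR lengths by group
#'
#' Unweighted per-group mean and median of UTR lengths (negative lengths
#' included); groups with no determinate length are dropped with a warning.
#'
#' @param results Integer/numeric vector of UTR lengths (NAs ignored), or a
#'   [utr_report()] data.frame.
#' @param groups Group labels, recycled against the lengths.
#' @return data.frame with `group`, `n`, `mean`, `median`.
#' @export
summarize_utr_lengths <- function(results, groups) {
  lengths <- if (is.data.frame(results)) results$utr_length else results
  stopifnot(is.numeric(lengths))
  groups <- rep_len(as.character(groups), length(lengths))
  ok <- !is.na(lengths)
  tab <- table(groups)
  kept <- tapply(lengths[ok], groups[ok], length)
  empty <- setdiff(names(tab), names(kept))
  if (length(empty)) {
    warning("group(s) with no determinate UTR length dropped: ",
            paste(empty, collapse = ", "))
  }
  out <- data.frame(
    group = names(kept),
    n = as.integer(kept),
    mean = as.numeric(tapply(lengths[ok], groups[ok], mean)),
    median = as.numeric(tapply(lengths[ok], groups[ok], stats::median)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
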