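#' Locate the terminal poly(A) tail of a transcript
#'
#' A transcript is considered poly(A)-tailed when it ends in an uninterrupted
#' run of at least `min_tail` adenosines. The run is terminal-anchored and
#' maximal: internal A-runs are ignored, and no non-A residue may follow it.
#'
#' @param residues A single normalized (DNA-alphabet) sequence string.
#' @param min_tail Minimum qualifying run length (default 12).
#' @return Integer length of the maximal terminal A-run, or `NA_integer_`
#'   when that run is shorter than `min_tail` (including the empty sequence).
#' @export
find_terminal_tail <- function(residues, min_tail = 12L) {
  stopifnot(is.character(residues), length(residues) == 1L, min_tail >= 1L)
  m <- regexpr("A+$", residues)
  run <- if (m[1L] == -1L) 0L else attr(m, "match.length")
  if (run >= min_tail) as.integer(run) else NA_integer_
}

#' Screen transcripts for qualifying poly(A) tails
#'
#' Keeps transcripts that (i) end in a terminal A-run of at least `min_tail`
#' and (ii) whose tail-stripped body is at least `anchor_len` long, so that a
#' full-length anchor exists for genome mapping. Rejections are counted, not
#' raised.
#'
#' @param records A [Biostrings::DNAStringSet] (e.g. from [read_fasta()]) or
#'   a named character vector of normalized sequences.
#' @param min_tail Minimum terminal A-run length (default 12).
#' @param anchor_len Anchor length: the bases immediately 5' of the tail used
#'   for mapping and redundancy screening (default 100).
#' @return A list with
#'   \describe{
#'     \item{transcripts}{data.frame with columns `id`, `body` (residues 5'
#'       of the tail), `tail_length`, `anchor` (last `anchor_len` bases of
#'       the body) and `tailstart_tx_coord` (1-based transcript coordinate of
#'       the first tail A).}
#'     \item{stats}{list of counts: `n_input`, `no_tail`, `short_body`,
#'       `kept`.}
#'   }
#' @export
screen_transcripts <- function(records, min_tail = 12L, anchor_len = 100L) {
  seqs <- if (methods::is(records, "XStringSet")) {
    stats::setNames(as.character(records), names(records))
  } else {
    records
  }
  stopifnot(is.character(seqs))
  if (is.null(names(seqs)) && length(seqs) > 0L) {
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  }
  m <- regexpr("A+$", seqs)
  run <- ifelse(m == -1L, 0L, attr(m, "match.length"))
  has_tail <- run >= min_tail
  body_len <- nchar(seqs) - run
  long_enough <- body_len >= anchor_len
  keep <- has_tail & long_enough
  body <- substr(seqs[keep], 1L, body_len[keep])
  tx <- data.frame(
    id = names(seqs)[keep],
    body = unname(body),
    tail_length = as.integer(run[keep]),
    anchor = unname(substr(body, body_len[keep] - anchor_len + 1L,
                           body_len[keep])),
    tailstart_tx_coord = as.integer(body_len[keep] + 1L),
    stringsAsFactors = FALSE)
  rownames(tx) <- NULL
  list(transcripts = tx,
       stats = list(n_input = length(seqs),
                    no_tail = sum(!has_tail),
                    short_body = sum(has_tail & !long_enough),
                    kept = sum(keep)))
}

#' Collapse transcripts that share an identical upstream anchor
#'
#' Two transcripts with the same `anchor_len` bases immediately upstream of
#' the tail are redundant copies of the same poly(A) evidence; the first
#' occurrence (input order) is kept as representative. Idempotent.
#'
#' @param transcripts The `transcripts` data.frame from
#'   [screen_transcripts()].
#' @return The deduplicated data.frame, in input order, with an added
#'   `n_source_mrnas` column counting the transcripts collapsed into each
#'   representative.
#' @export
dedupe_by_anchor <- function(transcripts) {
  stopifnot(is.data.frame(transcripts), "anchor" %in% names(transcripts))
  if (nrow(transcripts) == 0L) {
    transcripts$n_source_mrnas <- integer(0)
    return(transcripts)
  }
  # summing any existing counts keeps the operation idempotent
  w <- if ("n_source_mrnas" %in% names(transcripts)) {
    transcripts$n_source_mrnas
  } else {
    rep(1L, nrow(transcripts))
  }
  counts <- tapply(w, transcripts$anchor, sum)
  out <- transcripts[!duplicated(transcripts$anchor), , drop = FALSE]
  out$n_source_mrnas <- as.integer(counts[out$anchor])
  rownames(out) <- NULL
  out
}
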