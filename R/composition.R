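#' Per-position base-frequency matrix over poly(A) site regions
#'
#' Tallies A/C/G/T counts at every position of the (windowed) region across
#' all sites. Positions carrying an N in a given site are excluded from both
#' the numerator and the denominator at that position only, so one ambiguous
#' base does not discard the whole site.
#'
#' @param regions Character vector of 201-character region strings, or a
#'   site data.frame with a `region201` column.
#' @param window Paper-coordinate interval `c(from, to)` (default the whole
#'   region, `c(-100, 101)`).
#' @return An object of class `base_freq_matrix`: a list with `counts`
#'   (4 x W integer matrix, rows A,C,G,T), `denom` (sites with a determinate
#'   base per position), `freq` (counts/denom; columns sum to 1 where
#'   `denom > 0`), `positions` (paper coordinates) and `n_sites`.
#' @export
position_base_frequencies <- function(regions, window = c(-100L, 101L)) {
  if (is.data.frame(regions)) regions <- regions$region201
  stopifnot(is.character(regions))
  if (length(regions) == 0L) stop("no regions supplied")
  if (any(nchar(regions) != 201L)) stop("all regions must be 201 nt")
  idx <- .window_offsets(window)       # zero-based offsets
  chars <- matrix(unlist(strsplit(regions, ""), use.names = FALSE),
                  nrow = length(regions), byrow = TRUE)
  chars <- chars[, idx + 1L, drop = FALSE]
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(chars == b),
                   numeric(ncol(chars)))
  counts <- t(matrix(counts, ncol = 4L,
                     dimnames = list(NULL, bases)))
  storage.mode(counts) <- "integer"
  denom <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(denom, 1L), "/")
  freq[, denom == 0L] <- NA_real_
  positions <- index_to_paper(idx)
  colnames(counts) <- colnames(freq) <- positions
  names(denom) <- positions
  structure(list(counts = counts, denom = denom, freq = freq,
                 positions = positions, n_sites = length(regions)),
            class = "base_freq_matrix")
}

# zero-based region offsets for a paper-coordinate window [from, to]
#' @noRd
.window_offsets <- function(window) {
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  pos <- setdiff(seq.int(window[1L], window[2L]), 0L)
  paper_to_index(pos)
}

#' @export
print.base_freq_matrix <- function(x, ...) {
  cat("base_freq_matrix:", length(x$positions), "positions (",
      x$positions[1L], "..", x$positions[length(x$positions)], "), ",
      x$n_sites, "sites\n")
  invisible(x)
}

#' Sequence-logo information content of a position
#'
#' Computes `IC = log2(J) + sum_j p_j log2 p_j` (i.e. `log2(J)` minus the
#' Shannon entropy), the total letter height at a logo position, with
#' `0 * log2(0)` taken as 0. For DNA (`J = 4`) the value lies in `[0, 2]`
#' bits: 0 when all nucleotides are equiprobable, 2 when a single
#' nucleotide occurs.
#'
#' @param freqs Probability vector of length `J` (must sum to 1 within
#'   `1e-9`; positions with `denom == 0` have no defined IC).
#' @param J Alphabet size (default 4).
#' @return Information content in bits.
#' @export
information_content <- function(freqs, J = 4L) {
  stopifnot(is.numeric(freqs), length(freqs) == J)
  if (any(freqs < 0)) stop("negative probability")
  if (abs(sum(freqs) - 1) > 1e-9) stop("probabilities must sum to 1")
  terms <- ifelse(freqs > 0, freqs * log2(freqs), 0)
  log2(J) + sum(terms)
}

#' Per-position letter heights for a sequence logo
#'
#' Letter height is `p_jw * IC_w`: each letter's size is proportional to its
#' frequency and the column's total height equals the position's
#' information content.
#'
#' @param matrix A [position_base_frequencies()] result.
#' @return 4 x W numeric matrix of heights (rows A,C,G,T); `NA` columns
#'   where no site had a determinate base.
#' @export
seqlogo_heights <- function(matrix) {
  stopifnot(inherits(matrix, "base_freq_matrix"))
  ic <- apply(matrix$freq, 2L, function(p) {
    if (anyNA(p)) NA_real_ else information_content(p)
  })
  sweep(matrix$freq, 2L, ic, "*")
}

.as_dna_base <- function(base) {
  base <- toupper(base)
  if (base == "U") base <- "T"
  if (!base %in% c("A", "C", "G", "T")) stop("base must be one of A,C,G,T/U")
  base
}

#' Find the frequency peak of a base within a window
#'
#' The peak is the single-position argmax of the base's frequency over the
#' window (no smoothing, matching how single-base peak positions are
#' reported). Ties are broken toward the position nearest the poly(A) site:
#' the largest paper coordinate for upstream candidates, the smallest for
#' downstream ones.
#'
#' @param matrix A [position_base_frequencies()] result.
#' @param base `"A"`, `"C"`, `"G"`, `"T"` (or `"U"`, treated as T).
#' @param window Paper-coordinate interval to search, inside the matrix.
#' @return data.frame with `base`, `window_from`, `window_to`,
#'   `peak_position` (paper coordinate) and `peak_frequency` (percent of
#'   sites).
#' @export
find_peak <- function(matrix, base, window) {
  stopifnot(inherits(matrix, "base_freq_matrix"))
  base <- .as_dna_base(base)
  pos <- setdiff(seq.int(window[1L], window[2L]), 0L)
  if (!all(pos %in% matrix$positions)) stop("window outside matrix")
  if (length(pos) == 0L) stop("empty window")
  p <- matrix$freq[base, match(pos, matrix$positions)]
  best <- max(p, na.rm = TRUE)
  cand <- pos[!is.na(p) & p == best]
  # distance to the site: |p| upstream, p downstream
  dist <- ifelse(cand < 0L, -cand, cand)
  peak <- cand[order(dist, cand)][1L]
  data.frame(base = base, window_from = window[1L], window_to = window[2L],
             peak_position = peak, peak_frequency = 100 * best,
             stringsAsFactors = FALSE)
}

#' Summarize the U-A-U-A-U base-abundance pattern
#'
#' Locates the component peaks of the conserved pattern around poly(A)
#' sites: the far-upstream U-rich region (1st UUR), the upstream A-rich
#' region (UAR), the near-upstream U-rich region (2nd UUR), the A frequency
#' at the site itself (SiteA, paper position 1), and the downstream U-rich
#' region (DUR). A component whose window is nearly flat (max minus median
#' below `flatness` percentage points) is flagged as a plateau rather than a
#' peak -- e.g. the downstream U region lacks a sharp peak in plants.
#'
#' @param matrix A 201-wide [position_base_frequencies()] result.
#' @param windows Named list of paper-coordinate intervals for `uur1`,
#'   `uar`, `uur2`, `dur`.
#' @param flatness Plateau threshold in percentage points (default 5).
#' @return data.frame with one row per component: `component`, `base`,
#'   `peak_position`, `peak_frequency` (percent), `plateau`. The SiteA row
#'   has `peak_position = 1` and `plateau = NA` (a single position).
#' @export
summarize_uauau <- function(matrix,
                            windows = list(uur1 = c(-100L, -35L),
                                           uar = c(-30L, -10L),
                                           uur2 = c(-15L, -2L),
                                           dur = c(2L, 40L)),
                            flatness = 5) {
  stopifnot(inherits(matrix, "base_freq_matrix"),
            length(matrix$positions) == 201L)
  lefts <- vapply(windows[c("uur1", "uar", "uur2", "dur")], `[`,
                  numeric(1L), 1L)
  if (is.unsorted(lefts)) stop("component windows must be ordered 5' to 3'")
  comp <- list(uur1 = "T", uar = "A", uur2 = "T", dur = "T")
  rows <- lapply(names(comp), function(nm) {
    pk <- find_peak(matrix, comp[[nm]], windows[[nm]])
    pos <- setdiff(seq.int(windows[[nm]][1L], windows[[nm]][2L]), 0L)
    p <- 100 * matrix$freq[comp[[nm]], match(pos, matrix$positions)]
    data.frame(component = nm, base = comp[[nm]],
               peak_position = pk$peak_position,
               peak_frequency = pk$peak_frequency,
               plateau = (max(p, na.rm = TRUE) -
                            stats::median(p, na.rm = TRUE)) < flatness,
               stringsAsFactors = FALSE)
  })
  site <- data.frame(component = "site_a", base = "A", peak_position = 1L,
                     peak_frequency =
                       100 * matrix$freq["A", match(1L, matrix$positions)],
                     plateau = NA, stringsAsFactors = FALSE)
  out <- rbind(rows[[1L]], rows[[2L]], rows[[3L]], site, rows[[4L]])
  rownames(out) <- NULL
  out
}

#' Average base-frequency matrices across species or runs
#'
#' `species_mean` takes the unweighted mean of the per-matrix frequencies
#' (each species counts once, regardless of how many sites it contributed);
#' `pooled` sums counts element-wise and renormalizes (each site counts
#' once).
#'
#' @param matrices List of [position_base_frequencies()] results of equal
#'   width over the same positions.
#' @param mode `"species_mean"` or `"pooled"`.
#' @return A `base_freq_matrix`. In `species_mean` mode the `counts` and
#'   `denom` slots are the pooled totals but `freq` is the unweighted mean.
#' @export
average_matrices <- function(matrices, mode = c("species_mean", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1L), "base_freq_matrix")))
  W <- vapply(matrices, function(m) length(m$positions), integer(1L))
  if (length(unique(W)) != 1L) stop("matrices have mixed widths")
  counts <- Reduce(`+`, lapply(matrices, `[[`, "counts"))
  denom <- Reduce(`+`, lapply(matrices, `[[`, "denom"))
  if (mode == "pooled") {
    freq <- sweep(counts, 2L, pmax(denom, 1L), "/")
    freq[, denom == 0L] <- NA_real_
  } else {
    freq <- Reduce(`+`, lapply(matrices, `[[`, "freq")) / length(matrices)
  }
  structure(list(counts = counts, denom = denom, freq = freq,
                 positions = matrices[[1L]]$positions,
                 n_sites = sum(vapply(matrices, `[[`, numeric(1L),
                                      "n_sites"))),
            class = "base_freq_matrix")
}

#' Serialize a base-frequency matrix as TSV
#'
#' Positions as rows (paper coordinates, skipping 0), columns A,C,G,T
#' (frequencies) and `denom`.
#'
#' @param matrix A `base_freq_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_base_freq_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "base_freq_matrix"))
  df <- data.frame(position = matrix$positions, t(matrix$freq),
                   denom = matrix$denom, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot per-position base composition
#'
#' Simple line plot of percent A/C/G/T along the region, with the poly(A)
#' site marked; a lightweight view of the pattern the logo renders.
#'
#' @param matrix A `base_freq_matrix`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix.
#' @export
plot_base_composition <- function(matrix, ...) {
  stopifnot(inherits(matrix, "base_freq_matrix"))
  graphics::matplot(matrix$positions, 100 * t(matrix$freq), type = "l",
                    lty = 1, col = c("forestgreen", "blue", "orange", "red"),
                    xlab = "position relative to poly(A) site",
                    ylab = "base frequency (%)", ...)
  graphics::abline(v = 1, lty = 3)
  graphics::legend("topleft", legend = c("A", "C", "G", "T/U"), lty = 1,
                   col = c("forestgreen", "blue", "orange", "red"),
                   bty = "n")
  invisible(matrix)
}
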