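#' Motif search windows in paper coordinates
#'
#' A motif window is the interval of allowed *first-base* positions; the
#' motif's footprint may extend past the window's right edge (membership is
#' judged on the first base only, so footprints can cross the site).
#' Presets:
#' \describe{
#'   \item{hexamer_up50}{`[-50,-1]`, hexamers within 50 nt upstream.}
#'   \item{pentamer_up48}{`[-50,-3]`, the 48-base region ending two bases
#'     upstream of the tail-start position.}
#'   \item{tetramer_at_site}{`[-3,-3]`, the single start such that a 4-mer's
#'     last base covers the tail-start position.}
#'   \item{downstream50}{`[2,51]`, within 50 bases downstream of the site.}
#' }
#'
#' @param name Preset name, or pass a length-2 numeric interval directly to
#'   the consuming functions.
#' @return list with `name` and `interval` (paper coordinates).
#' @export
motif_window <- function(name = c("hexamer_up50", "pentamer_up48",
                                  "tetramer_at_site", "downstream50")) {
  if (is.numeric(name)) {
    stopifnot(length(name) == 2L, name[1L] <= name[2L])
    return(list(name = paste0("custom[", name[1L], ",", name[2L], "]"),
                interval = as.integer(name)))
  }
  name <- match.arg(name)
  interval <- switch(name,
                     hexamer_up50 = c(-50L, -1L),
                     pentamer_up48 = c(-50L, -3L),
                     tetramer_at_site = c(-3L, -3L),
                     downstream50 = c(2L, 51L))
  list(name = name, interval = interval)
}

# all 4^k DNA k-mers in lexicographic order
#' @noRd
all_kmers <- function(k) {
  stopifnot(k >= 1L)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(grid)))
}

#' @noRd
dna_to_rna <- function(x) gsub("T", "U", x, fixed = TRUE)

# k-mers starting at the given zero-based offsets of each region;
# returns a list (per site) of the k-mer character vectors
#' @noRd
.site_window_kmers <- function(regions, k, window) {
  w <- if (is.list(window)) window$interval else window
  starts0 <- .window_offsets(w)
  starts0 <- starts0[starts0 + k <= 201L]   # footprint must fit the region
  if (length(starts0) == 0L) stop("window outside region for k = ", k)
  s <- starts0 + 1L
  lapply(regions, function(r) substring(r, s, s + k - 1L))
}

#' Sites carrying at least one motif copy, per k-mer, within a window
#'
#' For every one of the 4^k motifs, counts the unique sites that have at
#' least one copy whose first base falls in the window (a site counts once
#' per motif regardless of copy number). Zero rows are included, so ranking
#' is always over the full 4^k alphabet; ties are broken lexicographically.
#'
#' @param regions Character vector of 201-nt regions or a site data.frame.
#' @param k Motif length (typically 4, 5 or 6).
#' @param window A [motif_window()] preset name, preset object, or
#'   length-2 paper-coordinate interval of allowed first-base positions.
#' @return data.frame (class `motif_table`) with columns `motif` (DNA),
#'   `motif_rna`, `n_sites_with_copy`, `pct_sites`, `rank`; attributes `k`,
#'   `window`, `n_sites`.
#' @export
count_sites_with_motif <- function(regions, k, window) {
  if (is.data.frame(regions)) regions <- regions$region201
  if (is.character(window) && length(window) == 1L) {
    window <- motif_window(window)
  }
  kmers <- .site_window_kmers(regions, k, window)
  per_site <- lapply(kmers, unique)
  tallied <- table(unlist(per_site, use.names = FALSE))
  motifs <- all_kmers(k)
  n_with <- integer(length(motifs))
  names(n_with) <- motifs
  hit <- intersect(names(tallied), motifs)  # drops N-containing k-mers
  n_with[hit] <- as.integer(tallied[hit])
  n_sites <- length(regions)
  pct <- 100 * n_with / n_sites
  ord <- order(-pct, motifs)
  rank <- integer(length(motifs))
  rank[ord] <- seq_along(motifs)
  out <- data.frame(motif = motifs, motif_rna = dna_to_rna(motifs),
                    n_sites_with_copy = unname(n_with),
                    pct_sites = unname(pct), rank = rank,
                    stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- k
  attr(out, "window") <- if (is.list(window)) window$interval else window
  attr(out, "n_sites") <- n_sites
  class(out) <- c("motif_table", "data.frame")
  out
}

#' Rank of a motif in a motif table
#'
#' @param table A `motif_table` from [count_sites_with_motif()] or
#'   [site_tetramer_distribution()].
#' @param motif Motif in DNA or RNA spelling, length matching the table's
#'   `k`.
#' @return 1-based rank among all 4^k motifs (descending percent, ties
#'   lexicographic).
#' @export
motif_rank <- function(table, motif) {
  stopifnot(inherits(table, "motif_table"))
  motif <- gsub("U", "T", toupper(motif), fixed = TRUE)
  if (nchar(motif) != attr(table, "k")) {
    stop("motif length ", nchar(motif), " != table k = ", attr(table, "k"))
  }
  table$rank[match(motif, table$motif)]
}

#' Per-position location profile of one motif
#'
#' For each paper position, the percentage of sites whose region carries the
#' motif with its *first* base at that position; plus the accumulated
#' percentage, `100 * (total overlapping occurrences across the region) /
#' n_sites`, which may exceed 100.
#'
#' @param regions Character vector of 201-nt regions or a site data.frame.
#' @param motif Motif over the DNA alphabet (RNA spelling accepted).
#' @return list (class `motif_position_profile`) with `motif`, `profile`
#'   (data.frame `position`, `n_sites_with_start`, `pct`), `accumulated_pct`
#'   and `n_sites`.
#' @export
motif_position_profile <- function(regions, motif) {
  if (is.data.frame(regions)) regions <- regions$region201
  motif <- gsub("U", "T", toupper(motif), fixed = TRUE)
  k <- nchar(motif)
  stopifnot(k >= 1L, !grepl("[^ACGT]", motif))
  s <- seq_len(201L - k + 1L)
  counts <- integer(length(s))
  for (r in regions) {
    hits <- substring(r, s, s + k - 1L) == motif
    counts <- counts + hits
  }
  positions <- index_to_paper(s - 1L)
  n <- length(regions)
  list2 <- list(motif = motif,
                profile = data.frame(position = positions,
                                     n_sites_with_start = counts,
                                     pct = 100 * counts / n,
                                     stringsAsFactors = FALSE),
                accumulated_pct = 100 * sum(counts) / n,
                n_sites = n)
  structure(list2, class = "motif_position_profile")
}

#' @export
print.motif_position_profile <- function(x, ...) {
  peak <- x$profile[which.max(x$profile$pct), ]
  cat("motif_position_profile:", x$motif, "over", x$n_sites, "sites; peak",
      sprintf("%.2f%%", peak$pct), "at position", peak$position,
      "; accumulated", sprintf("%.2f%%", x$accumulated_pct), "\n")
  invisible(x)
}

#' Distribution of the 4-mer covering the poly(A) site
#'
#' Each site contributes exactly one tetramer: paper positions -3..1, i.e.
#' the motif whose last base covers the tail-start position. Sites with an
#' N in that slice are excluded (and counted in the `n_excluded` attribute),
#' so percentages sum to 100 over the remaining sites.
#'
#' @param regions Character vector of 201-nt regions or a site data.frame.
#' @return A `motif_table` over all 256 tetramers (attribute
#'   `window = c(-3, -3)`), percentages relative to the included sites.
#' @export
site_tetramer_distribution <- function(regions) {
  if (is.data.frame(regions)) regions <- regions$region201
  tet <- substr(regions, paper_to_index(-3L) + 1L, paper_to_index(1L) + 1L)
  ok <- !grepl("N", tet, fixed = TRUE)
  tallied <- table(tet[ok])
  motifs <- all_kmers(4L)
  n_with <- integer(length(motifs))
  names(n_with) <- motifs
  hit <- intersect(names(tallied), motifs)
  n_with[hit] <- as.integer(tallied[hit])
  n_sites <- sum(ok)
  pct <- 100 * n_with / max(n_sites, 1L)
  ord <- order(-pct, motifs)
  rank <- integer(length(motifs))
  rank[ord] <- seq_along(motifs)
  out <- data.frame(motif = motifs, motif_rna = dna_to_rna(motifs),
                    n_sites_with_copy = unname(n_with),
                    pct_sites = unname(pct), rank = rank,
                    stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- 4L
  attr(out, "window") <- c(-3L, -3L)
  attr(out, "n_sites") <- n_sites
  attr(out, "n_excluded") <- sum(!ok)
  class(out) <- c("motif_table", "data.frame")
  out
}

#' Scan known downstream elements for enrichment
#'
#' Computes the with-at-least-one-copy percentage of each element in the
#' window and compares it against the mean with-copy probability over all
#' same-length motifs in that window, via a two-sided exact binomial test.
#' The default element list holds downstream elements reported for human
#' poly(A) sites (RNA spellings UUAUUU, CCUCCC, UGUGUG, GUGUGU, UGUUUG,
#' AUGCGU).
#'
#' @param regions Character vector of 201-nt regions or a site data.frame.
#' @param elements Character vector of motifs (DNA or RNA spelling).
#' @param window First-base window (preset name, preset, or interval);
#'   default `"downstream50"`.
#' @param alpha Significance level for the verdict (default 0.01).
#' @return data.frame with per element: `element` (DNA), `element_rna`,
#'   `n_sites_with_copy`, `pct_sites`, `null_pct` (mean with-copy percent
#'   over all 4^k motifs of its length), `p_value` and `verdict`
#'   (`"more_frequent"`, `"less_frequent"` or `"not_significant"`).
#' @export
known_element_scan <- function(regions,
                               elements = c("TTATTT", "CCTCCC", "TGTGTG",
                                            "GTGTGT", "TGTTTG", "ATGCGT"),
                               window = "downstream50", alpha = 0.01) {
  if (is.data.frame(regions)) regions <- regions$region201
  elements <- gsub("U", "T", toupper(elements), fixed = TRUE)
  ks <- unique(nchar(elements))
  tables <- lapply(ks, function(k)
    count_sites_with_motif(regions, k, window))
  names(tables) <- ks
  n_sites <- length(regions)
  rows <- lapply(elements, function(el) {
    tab <- tables[[as.character(nchar(el))]]
    null_p <- mean(tab$n_sites_with_copy) / n_sites
    x <- tab$n_sites_with_copy[match(el, tab$motif)]
    test <- stats::binom.test(x, n_sites, p = null_p,
                              alternative = "two.sided")
    verdict <- if (test$p.value >= alpha) {
      "not_significant"
    } else if (x / n_sites > null_p) "more_frequent" else "less_frequent"
    data.frame(element = el, element_rna = dna_to_rna(el),
               n_sites_with_copy = x, pct_sites = 100 * x / n_sites,
               null_pct = 100 * null_p, p_value = test$p.value,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-genome k-mer frequency table
#'
#' Counts k-mers on the given strand of every genome sequence. The default
#' mode counts overlapping windows (so seven consecutive A's contain two
#' AAAAAA copies -- homopolymer counts are conflated, as flagged for
#' whole-chromosome tallies); `"non_overlapping"` counts greedy
#' left-to-right disjoint occurrences instead. Windows containing N are
#' skipped; frequency denominators are `L - k + 1` per sequence.
#'
#' @param genome A [Biostrings::DNAStringSet], `genome_index`, named
#'   character vector, or FASTA path.
#' @param k k-mer length (>= 1).
#' @param mode `"overlapping"` (default) or `"non_overlapping"`.
#' @return list (class `genome_kmer_table`) with `per_chrom` (data.frame
#'   `chrom`, `motif`, `count`, `frequency`) and `pooled` (data.frame
#'   `motif`, `motif_rna`, `count`, `frequency`), plus `k` and `mode`.
#' @export
genome_kmer_frequencies <- function(genome, k,
                                    mode = c("overlapping",
                                             "non_overlapping")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1L)
  if (inherits(genome, "genome_index")) genome <- genome$seqs
  if (is.character(genome) && length(genome) == 1L &&
      file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  motifs <- all_kmers(k)
  per <- lapply(seq_along(genome), function(i) {
    subj <- genome[[i]]
    L <- length(subj)
    denom <- max(L - k + 1L, 1L)
    if (mode == "overlapping") {
      counts <- Biostrings::oligonucleotideFrequency(subj, width = k)
      counts <- counts[motifs]
    } else {
      seqchar <- as.character(subj)
      counts <- vapply(motifs, function(m) {
        hits <- gregexpr(m, seqchar, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) 0L else length(hits)
      }, integer(1L))
    }
    data.frame(chrom = names(genome)[i], motif = motifs,
               count = as.integer(counts),
               frequency = as.numeric(counts) / denom,
               stringsAsFactors = FALSE)
  })
  per_chrom <- do.call(rbind, per)
  total <- tapply(per_chrom$count, per_chrom$motif, sum)[motifs]
  denom_all <- sum(pmax(Biostrings::width(genome) - k + 1L, 1L))
  pooled <- data.frame(motif = motifs, motif_rna = dna_to_rna(motifs),
                       count = as.integer(total),
                       frequency = as.numeric(total) / denom_all,
                       stringsAsFactors = FALSE)
  rownames(pooled) <- NULL
  structure(list(per_chrom = per_chrom, pooled = pooled, k = k,
                 mode = mode),
            class = "genome_kmer_table")
}

#' Fold enrichment of a motif at poly(A) sites over the genome baseline
#'
#' @param site_pct With-copy percentage at sites (0..100).
#' @param genome_freq Genome-wide per-window frequency (a fraction).
#' @return `(site_pct/100) / genome_freq`; `NA_real_` when
#'   `genome_freq == 0` (undefined, flagged rather than an error).
#' @export
enrichment_ratio <- function(site_pct, genome_freq) {
  stopifnot(is.numeric(site_pct), is.numeric(genome_freq))
  out <- (site_pct / 100) / genome_freq
  out[genome_freq == 0] <- NA_real_
  out
}

#' Two-proportion Pearson chi-square test
#'
#' Uncorrected Pearson chi-square on the 2x2 table of with/without counts in
#' two groups (df = 1, no continuity correction); used to compare motif
#' proportions between two mapping runs (e.g. mRNA-based vs RNA-seq-based
#' sites).
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return list with `statistic` and `p_value`.
#' @export
two_proportion_chisq <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  if ((a + c) == 0 || (b + d) == 0) {
    stop("degenerate 2x2 table: a margin is zero")
  }
  n <- n1 + n2
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}
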