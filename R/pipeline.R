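#' Pipeline run configuration
#'
#' Defaults mirror the analysis parameters of the method: minimum tail 12,
#' anchor 100 nt, 201-nt region, minimum qualifying ORF 110 aa, 4-mer site
#' table, 5-mer `[-50,-3]` and 6-mer `[-50,-1]` upstream tables, and the
#' known downstream-element scan in `[2,51]`.
#'
#' @param min_tail Minimum terminal A-run length.
#' @param anchor_len Anchor length for mapping/dedup.
#' @param min_aa Minimum ORF length (amino acids) for the 3'UTR stage.
#' @param profile_motifs Motifs whose location profiles are computed;
#'   `NULL` profiles the top upstream hexamer of the run itself.
#' @param known_elements Elements for the downstream scan.
#' @param uauau_windows Component windows for [summarize_uauau()].
#' @param top_n Rows of each motif table kept in the text report.
#' @param drop_multi_locus Drop anchors mapping to more than one genomic
#'   locus instead of keeping them with multiplicity recorded.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_tail = 12L, anchor_len = 100L, min_aa = 110L,
                       profile_motifs = NULL,
                       known_elements = c("TTATTT", "CCTCCC", "TGTGTG",
                                          "GTGTGT", "TGTTTG", "ATGCGT"),
                       uauau_windows = list(uur1 = c(-100L, -35L),
                                            uar = c(-30L, -10L),
                                            uur2 = c(-15L, -2L),
                                            dur = c(2L, 40L)),
                       top_n = 20L,
                       drop_multi_locus = FALSE) {
  stopifnot(min_tail >= 1L, anchor_len >= 1L, min_aa >= 1L, top_n >= 1L)
  structure(list(min_tail = as.integer(min_tail),
                 anchor_len = as.integer(anchor_len),
                 min_aa = as.integer(min_aa),
                 profile_motifs = profile_motifs,
                 known_elements = known_elements,
                 uauau_windows = uauau_windows,
                 top_n = as.integer(top_n),
                 drop_multi_locus = isTRUE(drop_multi_locus)),
            class = "run_config")
}

#' Run the full poly(A) site mapping and profiling pipeline
#'
#' screen -> dedupe -> map (zero mismatches) -> assemble 201-nt regions ->
#' unique-site catalog -> composition matrix + U-A-U-A-U summary -> motif
#' tables (4-mer at site, 5-mer up48, 6-mer up50, downstream element scan)
#' -> motif location profiles -> 3'UTR report. The pipeline is a pure
#' function of (inputs, config): rerunning it reproduces identical outputs.
#'
#' @param transcripts Transcript FASTA path or [Biostrings::DNAStringSet].
#' @param genome Genome FASTA path, [Biostrings::DNAStringSet] or
#'   [genome_index()].
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, the site table, matrix and
#'   motif tables are written there as TSV.
#' @return list of class `polya_run` with elements `sites` (unique-site
#'   table), `composition` (`base_freq_matrix`), `uauau`, `motif_tables`
#'   (list: `site_tetramer`, `pentamer_up48`, `hexamer_up50`), `profiles`
#'   (list of `motif_position_profile`), `element_scan`, `utr`,
#'   `screen_stats` and `counts` (records at every filter).
#' @export
run_pipeline <- function(transcripts, genome, config = run_config(),
                         outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(transcripts)) transcripts <- read_fasta(transcripts)
  index <- if (inherits(genome, "genome_index")) genome else
    genome_index(genome)

  scr <- screen_transcripts(transcripts, min_tail = config$min_tail,
                            anchor_len = config$anchor_len)
  if (scr$stats$kept == 0L) {
    stop("screen stage: no transcript passed the poly(A) tail screen")
  }
  uniq_tx <- dedupe_by_anchor(scr$transcripts)

  loci <- map_anchors_bulk(index, uniq_tx$anchor)
  mult <- table(loci$anchor)
  n_mapped_anchors <- length(mult)
  if (config$drop_multi_locus) {
    loci <- loci[loci$anchor %in% names(mult)[mult == 1L], , drop = FALSE]
  }
  regions <- vector("list", nrow(loci))
  n_edge <- 0L
  for (i in seq_len(nrow(loci))) {
    r <- assemble_region(index, loci[i, ])
    if (is.null(r)) {
      n_edge <- n_edge + 1L
    } else {
      r$anchor <- loci$anchor[i]
      regions[[i]] <- r
    }
  }
  regions <- do.call(rbind, regions)
  if (is.null(regions) || nrow(regions) == 0L) {
    stop("map stage: no anchor produced a complete 201-nt region")
  }
  regions$n_source_mrnas <-
    uniq_tx$n_source_mrnas[match(regions$anchor, uniq_tx$anchor)]
  regions$multiplicity <- as.integer(mult[regions$anchor])
  sites <- catalog_unique_sites(regions)

  comp <- position_base_frequencies(sites$region201)
  uauau <- summarize_uauau(comp, windows = config$uauau_windows)
  motif_tables <- list(
    site_tetramer = site_tetramer_distribution(sites$region201),
    pentamer_up48 = count_sites_with_motif(sites$region201, 5L,
                                           "pentamer_up48"),
    hexamer_up50 = count_sites_with_motif(sites$region201, 6L,
                                          "hexamer_up50"))
  element_scan <- known_element_scan(sites$region201,
                                     elements = config$known_elements)
  prof_motifs <- config$profile_motifs
  if (is.null(prof_motifs)) {
    prof_motifs <- motif_tables$hexamer_up50$motif[1L]
  }
  profiles <- lapply(prof_motifs,
                     function(m) motif_position_profile(sites$region201, m))
  names(profiles) <- gsub("U", "T", toupper(prof_motifs), fixed = TRUE)
  utr <- utr_report(uniq_tx, min_aa = config$min_aa)

  counts <- list(input = scr$stats$n_input,
                 no_tail = scr$stats$no_tail,
                 short_body = scr$stats$short_body,
                 tailed = scr$stats$kept,
                 distinct_anchors = nrow(uniq_tx),
                 mapped_anchors = n_mapped_anchors,
                 loci = nrow(loci),
                 edge_dropped = n_edge,
                 unique_sites = nrow(sites))
  out <- structure(list(sites = sites, composition = comp, uauau = uauau,
                        motif_tables = motif_tables, profiles = profiles,
                        element_scan = element_scan, utr = utr,
                        screen_stats = scr$stats, counts = counts,
                        config = config),
                   class = "polya_run")
  if (!is.null(outdir)) .write_run(out, outdir)
  out
}

#' @noRd
.write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_site_table(run$sites, file.path(outdir, "sites.tsv"))
  write_base_freq_matrix(run$composition,
                         file.path(outdir, "composition.tsv"))
  for (nm in names(run$motif_tables)) {
    tab <- run$motif_tables[[nm]]
    utils::write.table(utils::head(as.data.frame(tab),
                                   run$config$top_n),
                       file.path(outdir, paste0("motifs_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(run$element_scan,
                     file.path(outdir, "element_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$utr, file.path(outdir, "utr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$uauau, file.path(outdir, "uauau.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- data.frame(stage = names(run$counts),
                       n = unlist(run$counts, use.names = FALSE))
  utils::write.table(counts, file.path(outdir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.polya_run <- function(x, ...) {
  cat("polya_run:", x$counts$unique_sites, "unique sites from",
      x$counts$input, "input transcripts\n")
  cat("  stages:",
      paste(names(x$counts), unlist(x$counts), sep = "=",
            collapse = ", "), "\n")
  top <- utils::head(x$motif_tables$hexamer_up50, 3L)
  cat("  top upstream hexamers:",
      paste(sprintf("%s (%.1f%%)", top$motif_rna, top$pct_sites),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compare motif proportions between two pipeline runs
#'
#' Per motif, a two-proportion Pearson chi-square on
#' (sites with >= 1 copy) / (unique sites) in run A vs run B -- the
#' comparison used to contrast mRNA-based with RNA-seq-read-based site
#' catalogs, where internal priming depresses U-rich site motifs.
#'
#' @param run_a,run_b `polya_run` objects.
#' @param motif Motif(s) to compare (DNA or RNA spelling); `NULL` compares
#'   every motif in the table.
#' @param window Which motif table: `"site_tetramer"`, `"pentamer_up48"` or
#'   `"hexamer_up50"`.
#' @return data.frame with `motif`, `pct_a`, `pct_b`, `statistic`,
#'   `p_value`.
#' @export
compare_runs <- function(run_a, run_b, motif = NULL,
                         window = c("site_tetramer", "pentamer_up48",
                                    "hexamer_up50")) {
  window <- match.arg(window)
  stopifnot(inherits(run_a, "polya_run"), inherits(run_b, "polya_run"))
  ta <- run_a$motif_tables[[window]]
  tb <- run_b$motif_tables[[window]]
  if (is.null(ta) || is.null(tb)) stop("missing motif table: ", window)
  na <- attr(ta, "n_sites")
  nb <- attr(tb, "n_sites")
  motifs <- if (is.null(motif)) ta$motif else
    gsub("U", "T", toupper(motif), fixed = TRUE)
  rows <- lapply(motifs, function(m) {
    xa <- ta$n_sites_with_copy[match(m, ta$motif)]
    xb <- tb$n_sites_with_copy[match(m, tb$motif)]
    if (is.na(xa) || is.na(xb)) stop("motif not in table: ", m)
    res <- if ((xa + xb) == 0L || (na - xa + nb - xb) == 0L) {
      # both proportions 0 (or 1): no difference, degenerate table
      list(statistic = 0, p_value = 1)
    } else {
      two_proportion_chisq(xa, na, xb, nb)
    }
    data.frame(motif = m, motif_rna = dna_to_rna(m),
               pct_a = 100 * xa / na, pct_b = 100 * xb / nb,
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
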