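test_that("windowed motif tables count sites once and span the alphabet", {
  set.seed(51)
  # 6 of 10 sites get AATAAA planted with first base in [-50,-1]
  regs <- random_regions(10)
  for (i in 1:6) {
    off <- paper_to_index(sample(c(-50:-6), 1)) + 1
    substr(regs[i], off, off + 5) <- "AATAAA"
  }
  tab <- count_sites_with_motif(regs, 6, "hexamer_up50")
  expect_equal(nrow(tab), 4096L)
  expect_gte(tab$pct_sites[match("AATAAA", tab$motif)], 60)
  expect_equal(tab$motif_rna[match("AATAAA", tab$motif)], "AAUAAA")

  # a site with two copies still contributes one
  two <- strrep("G", 201)
  substr(two, paper_to_index(-50) + 1, paper_to_index(-50) + 6) <- "AATAAA"
  substr(two, paper_to_index(-30) + 1, paper_to_index(-30) + 6) <- "AATAAA"
  t2 <- count_sites_with_motif(c(two, strrep("G", 201)), 6, "hexamer_up50")
  expect_equal(t2$n_sites_with_copy[match("AATAAA", t2$motif)], 1L)

  # oracle equivalence for several motifs and windows
  regs2 <- random_regions(30)
  for (w in list(c(-50L, -1L), c(-50L, -3L), c(2L, 51L))) {
    tabw <- count_sites_with_motif(regs2, 4, w)
    for (m in c("AATA", "TTTA", sample(tabw$motif, 5))) {
      expect_equal(tabw$pct_sites[match(m, tabw$motif)],
                   naive_site_motif_pct(regs2, m, w[1], w[2]))
    }
  }
  tab4 <- count_sites_with_motif(regs2, 4, "hexamer_up50")
  expect_equal(nrow(tab4), 256L)
})

test_that("motif ranks are 1-based over the full 4^k alphabet", {
  set.seed(52)
  regs <- random_regions(12)
  tab <- count_sites_with_motif(regs, 6, "hexamer_up50")
  expect_equal(motif_rank(tab, tab$motif[1]), 1L)
  expect_equal(sort(tab$rank), 1:4096)
  absent <- tab$motif[tab$n_sites_with_copy == 0][1]
  expect_gt(motif_rank(tab, absent), sum(tab$pct_sites > 0))
  expect_error(motif_rank(tab, "AATA"), "length")
})

test_that("motif location profiles count first-base placements", {
  # all-T region: TTTTTT starts at every eligible offset
  oneT <- strrep("T", 201)
  p <- motif_position_profile(oneT, "TTTTTT")
  expect_equal(nrow(p$profile), 196L)
  expect_equal(p$profile$pct, rep(100, 196))
  expect_equal(p$accumulated_pct, 100 * 196)

  none <- motif_position_profile(strrep("G", 201), "AATAAA")
  expect_equal(none$profile$pct, rep(0, 196))
  expect_equal(none$accumulated_pct, 0)

  # accumulated occurrences >= with-copy site count for the same window
  set.seed(53)
  regs <- random_regions(20)
  pr <- motif_position_profile(regs, "ATTA")
  tab <- count_sites_with_motif(regs, 4, c(-100L, 101L))
  expect_gte(pr$accumulated_pct / 100 * pr$n_sites,
             tab$n_sites_with_copy[match("ATTA", tab$motif)])
})

test_that("start-position counts are conserved across the motif alphabet", {
  set.seed(54)
  regs <- random_regions(15)
  k <- 4L
  total <- 0
  for (m in polyamap:::all_kmers(k)) {
    pr <- motif_position_profile(regs, m)
    total <- total + sum(pr$profile$n_sites_with_start)
  }
  expect_equal(total, length(regs) * (201 - k + 1))
})

test_that("the site tetramer covers positions -3..1 and sums to 100%", {
  reg <- strrep("G", 201)
  substr(reg, 98, 101) <- "TTTA"   # upstream ...TTT, site base A
  tab <- site_tetramer_distribution(reg)
  expect_equal(tab$motif[1], "TTTA")
  expect_equal(tab$pct_sites[1], 100)
  expect_equal(tab$motif_rna[1], "UUUA")

  four <- vapply(c("AAAA", "CCCC", "GGGG", "TTTT"), function(m) {
    r <- strrep("G", 201); substr(r, 98, 101) <- m; r
  }, character(1))
  t4 <- site_tetramer_distribution(four)
  expect_equal(sum(t4$pct_sites), 100)
  expect_equal(sort(t4$pct_sites[t4$n_sites_with_copy > 0]), rep(25, 4))

  set.seed(55)
  regs <- random_regions(40)
  tall <- site_tetramer_distribution(regs)
  slice <- substr(regs, 98, 101)              # direct extraction oracle
  for (m in unique(slice)) {
    expect_equal(tall$n_sites_with_copy[match(m, tall$motif)],
                 sum(slice == m))
  }
  expect_equal(sum(tall$pct_sites), 100)
})

test_that("known-element scan flags planted downstream enrichment", {
  set.seed(56)
  regs <- random_regions(400)
  for (i in 1:120) {                           # plant TGTTTG in 30% of sites
    off <- paper_to_index(sample(2:46, 1)) + 1
    substr(regs[i], off, off + 5) <- "TGTTTG"
  }
  scan <- known_element_scan(regs)
  row <- scan[scan$element == "TGTTTG", ]
  expect_gte(row$pct_sites, 30)
  expect_equal(row$verdict, "more_frequent")
  expect_lt(row$p_value, 0.01)

  none <- known_element_scan(strrep("G", 201), elements = "AATAAA")
  expect_equal(none$pct_sites, 0)
})

test_that("genome k-mer counts use overlapping windows and skip N", {
  g7 <- c(c1 = "AAAAAAA")
  t7 <- genome_kmer_frequencies(Biostrings::DNAStringSet(g7), 6)
  expect_equal(t7$pooled$count[match("AAAAAA", t7$pooled$motif)], 2L)
  t7n <- genome_kmer_frequencies(Biostrings::DNAStringSet(g7), 6,
                                 mode = "non_overlapping")
  expect_equal(t7n$pooled$count[match("AAAAAA", t7n$pooled$motif)], 1L)

  set.seed(57)
  s <- random_dna(10000)
  tab <- genome_kmer_frequencies(Biostrings::DNAStringSet(c(chr = s)), 4)
  expect_equal(sum(tab$pooled$count), 10000L - 4L + 1L)
  want <- naive_kmer_counts(s, 4)
  for (m in names(want)) {
    expect_equal(tab$pooled$count[match(m, tab$pooled$motif)],
                 unname(want[m]))
  }
  expect_equal(tab$pooled$frequency,
               tab$pooled$count / (10000 - 4 + 1))

  withN <- paste0("ACGT", "N", "ACGTAC")
  tN <- genome_kmer_frequencies(Biostrings::DNAStringSet(c(c = withN)), 4)
  expect_equal(sum(tN$pooled$count), sum(naive_kmer_counts(withN, 4)))
})

test_that("enrichment ratios follow the site-vs-genome definition", {
  expect_equal(enrichment_ratio(50, 0.001), 500)
  expect_equal(enrichment_ratio(0, 0.001), 0)
  expect_true(is.na(enrichment_ratio(50, 0)))
})

test_that("the two-proportion chi-square matches an independent reference", {
  same <- two_proportion_chisq(50, 100, 50, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  cases <- list(c(45, 389, 41, 579),   # mRNA vs RNA-seq UUUA counts
                c(10, 50, 30, 70), c(1, 12, 9, 11), c(250, 300, 200, 300))
  for (cs in cases) {
    got <- two_proportion_chisq(cs[1], cs[2], cs[3], cs[4])
    ref <- suppressWarnings(
      stats::prop.test(c(cs[1], cs[3]), c(cs[2], cs[4]), correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  extreme <- two_proportion_chisq(0, 10, 10, 10)
  expect_lt(extreme$p_value, 0.001)
  expect_error(two_proportion_chisq(0, 10, 0, 10), "margin")
})
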