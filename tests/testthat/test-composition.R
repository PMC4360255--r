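test_that("information content matches the logo formula and its bounds", {
  expect_equal(information_content(c(1, 0, 0, 0)), 2.0)
  expect_equal(information_content(rep(0.25, 4)), 0.0)
  expect_equal(information_content(c(0.5, 0.5, 0, 0)), 1.0)
  expect_error(information_content(c(-0.1, 0.5, 0.3, 0.3)), "negative")
  expect_error(information_content(c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  set.seed(41)
  for (i in 1:200) {
    p <- stats::rgamma(4, shape = stats::runif(1, 0.2, 3))
    p <- p / sum(p)
    ic <- information_content(p)
    expect_gte(ic, 0)
    expect_lte(ic, 2)
    expect_equal(ic, ic_oracle(p), tolerance = 1e-12)
  }
})

test_that("per-position base frequencies tally determinate bases only", {
  allA <- rep(strrep("A", 201), 2)
  m <- position_base_frequencies(allA)
  expect_equal(unname(m$freq["A", ]), rep(1, 201))
  expect_equal(unname(m$denom), rep(2L, 201))

  four <- vapply(c("A", "C", "G", "T"), function(b) {
    paste0(strrep("G", 100), b, strrep("G", 100))
  }, character(1))
  m4 <- position_base_frequencies(four)
  expect_equal(unname(m4$freq[, "1"]), rep(0.25, 4))

  withN <- c(paste0(strrep("A", 100), "N", strrep("A", 100)),
             strrep("A", 201))
  mN <- position_base_frequencies(withN)
  expect_equal(unname(mN$denom[101]), 1L)
  expect_equal(unname(mN$freq["A", "1"]), 1)
  expect_error(position_base_frequencies(character(0)), "no regions")
})

test_that("logo letter heights sum to an independently computed IC", {
  set.seed(42)
  m <- position_base_frequencies(random_regions(40))
  h <- seqlogo_heights(m)
  ic2 <- apply(m$freq, 2, ic_oracle)
  expect_equal(unname(colSums(h)), unname(ic2), tolerance = 1e-12)
  allA <- position_base_frequencies(rep(strrep("A", 201), 3))
  hA <- seqlogo_heights(allA)
  expect_equal(unname(hA["A", "5"]), 2)
  expect_equal(unname(colSums(hA)), rep(2, 201))
})

test_that("peak finding is argmax with ties broken toward the site", {
  # planted bump: A raised at -21 only
  regs <- c(rep(paste0(strrep("T", 79), "A", strrep("T", 121)), 7),
            rep(strrep("T", 201), 3))
  m <- position_base_frequencies(regs)
  pk <- find_peak(m, "A", c(-40, -10))
  expect_equal(pk$peak_position, -21L)
  expect_equal(pk$peak_frequency, 70)

  # perfectly flat matrix: cycling regions give 0.25 everywhere
  flat <- vapply(0:3, function(s) {
    paste(rep(c("A", "C", "G", "T"))[(seq_len(201) + s - 1) %% 4 + 1],
          collapse = "")
  }, character(1))
  mf <- position_base_frequencies(flat)
  expect_equal(find_peak(mf, "A", c(-30, -10))$peak_position, -10L)
  expect_equal(find_peak(mf, "T", c(2, 40))$peak_position, 2L)
  expect_error(find_peak(mf, "A", c(-300, -200)), "outside")
})

test_that("U-A-U-A-U summary locates components and flags plateaus", {
  flat <- vapply(0:3, function(s) {
    paste(rep(c("A", "C", "G", "T"))[(seq_len(201) + s - 1) %% 4 + 1],
          collapse = "")
  }, character(1))
  s <- summarize_uauau(position_base_frequencies(flat))
  expect_true(all(s$plateau[s$component != "site_a"]))
  expect_equal(s$component, c("uur1", "uar", "uur2", "site_a", "dur"))
  expect_equal(s$peak_frequency[s$component == "site_a"], 25)
})

test_that("matrix averaging distinguishes species-mean from pooled", {
  mA <- position_base_frequencies(rep(strrep("A", 201), 1))
  mC <- position_base_frequencies(rep(strrep("C", 201), 3))
  sm <- average_matrices(list(mA, mC), mode = "species_mean")
  expect_equal(unname(sm$freq["A", "1"]), 0.5)
  expect_equal(unname(sm$freq["C", "1"]), 0.5)
  pl <- average_matrices(list(mA, mC), mode = "pooled")
  expect_equal(unname(pl$freq["A", "1"]), 0.25)  # 1 of 4 pooled sites
  expect_equal(unname(pl$freq["C", "1"]), 0.75)
  ident <- average_matrices(list(mA, mA), mode = "species_mean")
  expect_equal(ident$freq, mA$freq)

  # pooled average of two sets == frequencies of the concatenation
  set.seed(43)
  r1 <- random_regions(15); r2 <- random_regions(25)
  pooled <- average_matrices(list(position_base_frequencies(r1),
                                  position_base_frequencies(r2)),
                             mode = "pooled")
  both <- position_base_frequencies(c(r1, r2))
  expect_equal(pooled$freq, both$freq)
  expect_equal(pooled$counts, both$counts)

  w45 <- position_base_frequencies(r1, window = c(-30, 15))
  expect_error(average_matrices(list(pooled, w45)), "mixed widths")
})
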