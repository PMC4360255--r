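test_that("the generator is byte-identical under a fixed seed", {
  spec <- synthetic_spec(seed = 5, n_genes = 25)
  a <- simulate_dataset(spec)
  b <- simulate_dataset(spec)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.character(a$transcripts),
                   as.character(b$transcripts))
  expect_identical(a$truth, b$truth)
})

test_that("motif plantings appear at the configured position and fraction", {
  spec <- synthetic_spec(seed = 6, n_genes = 40,
                         plantings = data.frame(motif = "AATAAA",
                                                position = -21L,
                                                fraction = 1.0))
  gen <- generate_genome(spec)
  off <- paper_to_index(-21L) + 1L
  expect_true(all(substr(gen$truth$window201, off, off + 5L) == "AATAAA"))
  expect_true(all(gen$truth$has_motif))
  # the planted motif sits in the transcript body at the same offset
  tails <- substr(gen$truth$body, nchar(gen$truth$body) - 100L + off,
                  nchar(gen$truth$body) - 100L + off + 5L)
  expect_true(all(tails == "AATAAA"))
})

test_that("emitted windows follow the positional template", {
  spec <- synthetic_spec(seed = 7, n_genes = 1500,
                         plantings = data.frame(motif = character(0),
                                                position = integer(0),
                                                fraction = numeric(0)))
  gen <- generate_genome(spec)
  chars <- t(vapply(strsplit(gen$truth$window201, ""), identity,
                    character(201)))
  for (pp in c(-60L, -21L, -7L, 1L, 30L)) {
    col <- paper_to_index(pp) + 1L
    for (b in c("A", "T")) {
      p_hat <- mean(chars[, col] == b)
      p_true <- spec$template[b, col]
      se <- sqrt(p_true * (1 - p_true) / nrow(chars))
      expect_lt(abs(p_hat - p_true), 3 * se + 1e-9)
    }
  }
  # the tail attachment base is never A, so truth anchors are exact
  expect_false(any(chars[, 100] == "A"))
})

test_that("redundancy emits duplicate transcripts with shared anchors", {
  spec <- synthetic_spec(seed = 8, n_genes = 100, redundancy_rate = 0.5)
  sim <- simulate_dataset(spec)
  expect_length(sim$transcripts, 150L)
  scr <- screen_transcripts(sim$transcripts)
  expect_equal(scr$stats$kept, 150L)
  expect_equal(length(unique(scr$transcripts$anchor)), 100L)
  # every transcript's terminal A-run equals its planted tail
  expect_equal(sort(unique(nchar(scr$transcripts$body))),
               sort(unique(nchar(sim$truth$body))))
})

test_that("internal priming replaces reads at genomic A-runs", {
  spec0 <- synthetic_spec(seed = 9, n_genes = 50,
                          internal_priming_rate = 0)
  sim0 <- simulate_dataset(spec0)
  inj0 <- inject_internal_priming(spec0, sim0$genome, sim0$transcripts,
                                  sim0$truth)
  expect_identical(as.character(inj0$transcripts),
                   as.character(sim0$transcripts))

  spec3 <- synthetic_spec(seed = 9, n_genes = 50,
                          internal_priming_rate = 0.3)
  sim3 <- simulate_dataset(spec3)
  expect_equal(sum(sim3$truth$artifact), 15L)
  # artifact tail-start positions fall on the planted genomic A-run
  chrom <- as.character(sim3$genome[[1]])
  art <- sim3$truth[sim3$truth$artifact, ]
  for (i in seq_len(nrow(art))) {
    coord <- art$artifact_tailstart_coord[i]
    base <- substr(chrom, coord, coord)
    if (art$strand[i] == "-") base <- chartr("ACGT", "TGCA", base)
    expect_equal(base, "A")
  }
  # artifact selections are nested across rates at the same seed
  spec15 <- synthetic_spec(seed = 9, n_genes = 50,
                           internal_priming_rate = 0.15)
  sim15 <- simulate_dataset(spec15)
  expect_true(all(which(sim15$truth$artifact) %in%
                    which(sim3$truth$artifact)))
})

test_that("planted UTR lengths, including -1/-2 overlaps, are recovered", {
  spec <- synthetic_spec(seed = 10, n_genes = 30,
                         utr_lengths = c(-1L, -2L, 0L, 5L, 60L, 150L),
                         redundancy_rate = 0)
  sim <- simulate_dataset(spec)
  run <- run_pipeline(sim$transcripts, sim$genome)
  expect_equal(run$counts$unique_sites, 30L)
  gene <- sub("tx_", "", run$utr$id)
  planted <- sim$truth$utr_planted[match(gene, sim$truth$gene_id)]
  expect_true(all(run$utr$qualified))
  expect_equal(run$utr$utr_length, planted)
  expect_equal(run$utr$utr_less, planted < 0L)
  expect_equal(run$utr$borrowed_tail_bases, pmax(0L, -planted))
})
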