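test_that("paper coordinates and region offsets are mutual inverses", {
  expect_equal(paper_to_index(c(-100L, -1L, 1L, 5L, 101L)),
               c(0L, 99L, 100L, 104L, 200L))
  expect_equal(index_to_paper(c(0L, 99L, 100L, 104L, 200L)),
               c(-100L, -1L, 1L, 5L, 101L))
  valid <- setdiff(-100:101, 0L)
  expect_equal(index_to_paper(paper_to_index(valid)), valid)
  expect_error(paper_to_index(0L), "out of range")
  expect_error(paper_to_index(102L), "out of range")
  expect_error(index_to_paper(201L), "out of range")
})

test_that("anchor mapping finds all and only verbatim loci on both strands", {
  set.seed(31)
  anchor <- random_dna(100)
  bg <- random_dna(4000)
  # plant the anchor forward once and reverse-complemented once
  chrom <- paste0(bg, anchor, random_dna(800), revcomp_chr(anchor),
                  random_dna(500))
  idx <- genome_index(c(chr1 = chrom, chr2 = random_dna(2000)))
  got <- map_anchor(idx, anchor)
  want <- naive_map_oracle(c(chr1 = chrom, chr2 = random_dna(0)), anchor)
  expect_equal(got[order(got$strand), ], want[order(want$strand), ],
               ignore_attr = TRUE)
  expect_equal(got$strand[order(got$anchor_end_coord)], c("+", "-"))
  # on "-", anchor_end_coord is the plus-strand start of the rc match
  expect_equal(sort(got$anchor_end_coord),
               c(4001L + 99L, 4001L + 100L + 800L))

  # N never matches under the zero-mismatch rule
  withN <- paste0(substr(anchor, 1, 50), "N", substr(anchor, 52, 100))
  expect_equal(nrow(map_anchor(idx, withN)), 0L)

  # oracle equivalence on random anchors (mostly non-matching)
  for (i in 1:10) {
    a <- random_dna(30)
    expect_equal(map_anchor(idx, a)$anchor_end_coord,
                 naive_map_oracle(c(chr1 = chrom), a)$anchor_end_coord)
  }
})

test_that("bulk PDict mapping agrees with single-anchor mapping", {
  set.seed(32)
  chrom <- random_dna(20000)
  anchors <- c(vapply(1:8, function(i) {
    s <- sample(19000, 1)
    substr(chrom, s, s + 99)           # true positives, either strand below
  }, character(1)), random_dna(100), random_dna(100))
  anchors <- c(anchors, revcomp_chr(anchors[1]))
  idx <- genome_index(c(c1 = chrom))
  bulk <- polyamap:::map_anchors_bulk(idx, anchors)
  for (a in unique(anchors)) {
    one <- map_anchor(idx, a)
    sub <- bulk[bulk$anchor == a, c("chrom", "strand", "anchor_end_coord")]
    expect_equal(sub[order(sub$strand, sub$anchor_end_coord), ],
                 one[order(one$strand, one$anchor_end_coord), ],
                 ignore_attr = TRUE)
  }
})

test_that("region assembly splices anchor + tail-start base + downstream", {
  set.seed(33)
  anchor <- random_dna(100)
  downstream <- random_dna(101)       # site base + 100 nt of 3'COR
  left <- random_dna(300)
  chrom <- paste0(left, anchor, downstream, random_dna(50))
  idx <- genome_index(c(chr = chrom))
  locus <- map_anchor(idx, anchor)
  expect_equal(nrow(locus), 1L)
  reg <- assemble_region(idx, locus)
  expect_equal(nchar(reg$region201), 201L)
  expect_equal(reg$region201, paste0(anchor, downstream))
  expect_equal(substr(reg$region201, 1, 100), anchor)
  expect_equal(reg$tailstart_coord, 300L + 100L + 1L)

  # minus-strand locus: reverse-complement the whole toy genome and check
  # the plus-strand path reproduces the same region
  idx_rc <- genome_index(c(chr = revcomp_chr(chrom)))
  locus_rc <- map_anchor(idx_rc, anchor)
  expect_equal(locus_rc$strand, "-")
  reg_rc <- assemble_region(idx_rc, locus_rc)
  expect_equal(reg_rc$region201, reg$region201)
  expect_equal(reg_rc$tailstart_coord, nchar(chrom) - reg$tailstart_coord + 1L)

  # fewer than 101 genomic bases past the anchor: dropped
  short <- genome_index(c(chr = paste0(left, anchor, random_dna(50))))
  loc2 <- map_anchor(short, anchor)
  expect_null(assemble_region(short, loc2))
})

test_that("unique-site catalog collapses identical upstream-100 sequences", {
  set.seed(34)
  up <- random_dna(100)
  r1 <- data.frame(chrom = "c1", strand = "+", tailstart_coord = 500L,
                   region201 = paste0(up, random_dna(101)),
                   n_source_mrnas = 2L, stringsAsFactors = FALSE)
  r2 <- data.frame(chrom = "c1", strand = "+", tailstart_coord = 900L,
                   region201 = paste0(up, random_dna(101)),  # different COR
                   n_source_mrnas = 1L, stringsAsFactors = FALSE)
  r3 <- data.frame(chrom = "c1", strand = "-", tailstart_coord = 100L,
                   region201 = random_regions(1),
                   n_source_mrnas = 1L, stringsAsFactors = FALSE)
  out <- catalog_unique_sites(rbind(r1, r2, r3))
  expect_equal(nrow(out), 2L)
  merged <- out[substr(out$region201, 1, 100) == up, ]
  expect_equal(merged$tailstart_coord, 500L)   # smallest locus represents
  expect_equal(merged$n_source_mrnas, 3L)
  expect_equal(merged$n_loci_collapsed, 2L)
  # idempotent, pairwise-distinct upstreams
  expect_equal(catalog_unique_sites(out)[names(out)], out)
  expect_equal(anyDuplicated(substr(out$region201, 1, 100)), 0L)
})
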