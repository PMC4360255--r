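# Independent brute-force oracles and small fixture builders shared by the
# module tests. These deliberately use naive algorithms (character scans,
# dictionary tallies) so they stay independent of the package's code paths.

random_dna <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# regions drawn uniformly, optionally with a fixed site base
random_regions <- function(n_sites, len = 201L) {
  vapply(seq_len(n_sites), function(i) random_dna(len), character(1L))
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# naive O(n*m) exact substring scan over both strands of a genome given as a
# named character vector; returns the same columns as map_anchor()
naive_map_oracle <- function(genome_chr, anchor) {
  out <- data.frame(chrom = character(0), strand = character(0),
                    anchor_end_coord = integer(0), stringsAsFactors = FALSE)
  if (grepl("N", anchor, fixed = TRUE)) return(out)
  m <- nchar(anchor)
  rc <- revcomp_chr(anchor)
  for (chrom in names(genome_chr)) {
    s <- genome_chr[[chrom]]
    L <- nchar(s)
    for (i in seq_len(max(L - m + 1L, 0L))) {
      piece <- substr(s, i, i + m - 1L)
      if (piece == anchor) {
        out <- rbind(out, data.frame(chrom = chrom, strand = "+",
                                     anchor_end_coord = i + m - 1L,
                                     stringsAsFactors = FALSE))
      }
      if (piece == rc) {
        out <- rbind(out, data.frame(chrom = chrom, strand = "-",
                                     anchor_end_coord = i,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# naive overlapping k-mer tally (windows containing N skipped)
naive_kmer_counts <- function(seq_chr, k) {
  counts <- integer(0)
  L <- nchar(seq_chr)
  for (i in seq_len(max(L - k + 1L, 0L))) {
    w <- substr(seq_chr, i, i + k - 1L)
    if (grepl("N", w, fixed = TRUE)) next
    counts[w] <- if (is.na(counts[w])) 1L else counts[w] + 1L
  }
  counts
}

# naive per-site with-at-least-one-copy motif tally over first-base paper
# positions in [win_lo, win_hi]
naive_site_motif_pct <- function(regions, motif, win_lo, win_hi) {
  k <- nchar(motif)
  pos <- setdiff(seq.int(win_lo, win_hi), 0L)
  offs <- ifelse(pos < 0L, pos + 100L, pos + 99L) + 1L
  offs <- offs[offs + k - 1L <= 201L]
  hits <- vapply(regions, function(r) {
    any(substring(r, offs, offs + k - 1L) == motif)
  }, logical(1L))
  100 * sum(hits) / length(regions)
}

# maximal terminal A-run by scanning backwards one character at a time
naive_terminal_a_run <- function(x) {
  n <- nchar(x)
  run <- 0L
  while (n - run >= 1L && substr(x, n - run, n - run) == "A") {
    run <- run + 1L
  }
  run
}

# naive sense-frame codon walk: all ATG..first-in-frame-stop ORFs of
# body + "AA" (stop codons needing at least one body base)
naive_sense_orfs <- function(body) {
  seq2 <- paste0(body, "AA")
  L <- nchar(body)
  stops <- c("TAA", "TAG", "TGA")
  res <- NULL
  for (f in 0:2) {
    i <- f + 1L
    while (i + 2L <= nchar(seq2)) {
      if (substr(seq2, i, i + 2L) == "ATG") {
        j <- i + 3L
        while (j + 2L <= nchar(seq2)) {
          cod <- substr(seq2, j, j + 2L)
          if (cod %in% stops && j <= L) {
            res <- rbind(res, data.frame(
              frame = f, start_coord = i, stop_last_coord = j + 2L,
              aa_length = (j - i) %/% 3L,
              borrowed_tail_bases = max(0L, j + 2L - L)))
            break
          }
          j <- j + 3L
        }
      }
      i <- i + 3L
    }
  }
  if (is.null(res)) {
    res <- data.frame(frame = integer(0), start_coord = integer(0),
                      stop_last_coord = integer(0), aa_length = integer(0),
                      borrowed_tail_bases = integer(0))
  }
  res
}

# second, independent implementation of the information-content formula
# (log2 J minus Shannon entropy computed via natural logs)
ic_oracle <- function(p, J = 4) {
  nz <- p[p > 0]
  log2(J) - (-sum(nz * log(nz)) / log(2))
}

# a transcript whose single sense ORF encodes `aa` residues, followed by a
# UTR of `utr` background bases and a poly(A) tail; avoids accidental ATG
# by building the ORF from a fixed non-ATG, stop-free codon
fixture_transcript <- function(aa, utr = 30L, tail = 12L, pad = 9L) {
  orf <- paste0("ATG", strrep("GGC", aa - 1L), "TAA")
  paste0(strrep("C", pad), orf, strrep("C", utr), strrep("A", tail))
}
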