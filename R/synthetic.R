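#' Positional base-composition template for synthetic poly(A) site regions
#'
#' Builds a 4 x 201 matrix of per-position base probabilities over paper
#' positions -100..101 shaped like the conserved U-A-U-A-U pattern:
#' a U-rich far-upstream region, an A-rich bump, a near-upstream U bump, a
#' strong A at the site, and a U-rich downstream region (with a sharp
#' downstream peak in the animal-like template and a flat plateau in the
#' plant-like one). Peak heights default to the magnitudes reported for the
#' respective kingdoms; bump shapes are triangular with a fixed per-base
#' decay so every planted peak has a unique argmax.
#'
#' The tail attachment base (position -1) is given zero A probability
#' (species almost always use U or C there); this also guarantees that a
#' synthetic transcript's maximal terminal A-run is exactly its planted
#' tail.
#'
#' @param kind `"plant"` (A peak -21, U peak -7, flat downstream) or
#'   `"animal"` (A peak -18, U peak -9, downstream U peak +19).
#' @param a_peak_pos,a_peak_height Upstream A-rich bump position / height.
#' @param u_peak_pos,u_peak_height Near-upstream U bump position / height.
#' @param dur_peak_pos,dur_peak_height Downstream U peak (NULL = plateau).
#' @param site_a Probability of A at the tail-start position (default 0.75).
#' @return 4 x 201 probability matrix, rows A,C,G,T, columns named by paper
#'   position; every column sums to 1.
#' @export
composition_template <- function(kind = c("plant", "animal"),
                                 a_peak_pos = NULL, a_peak_height = NULL,
                                 u_peak_pos = NULL, u_peak_height = NULL,
                                 dur_peak_pos = NULL, dur_peak_height = NULL,
                                 site_a = 0.75) {
  kind <- match.arg(kind)
  def <- switch(kind,
    plant = list(a_pos = -21L, a_h = 0.41, u_pos = -7L, u_h = 0.56,
                 d_pos = NULL, d_h = NULL,
                 up = c(A = 0.24, C = 0.14, G = 0.13, T = 0.49),
                 down = c(A = 0.20, C = 0.20, G = 0.18, T = 0.42),
                 attach = c(A = 0, C = 0.30, G = 0.10, T = 0.60)),
    animal = list(a_pos = -18L, a_h = 0.54, u_pos = -9L, u_h = 0.42,
                  d_pos = 19L, d_h = 0.54,
                  up = c(A = 0.28, C = 0.20, G = 0.19, T = 0.33),
                  down = c(A = 0.20, C = 0.20, G = 0.18, T = 0.42),
                  attach = c(A = 0, C = 0.36, G = 0.28, T = 0.36)))
  if (is.null(a_peak_pos)) a_peak_pos <- def$a_pos
  if (is.null(a_peak_height)) a_peak_height <- def$a_h
  if (is.null(u_peak_pos)) u_peak_pos <- def$u_pos
  if (is.null(u_peak_height)) u_peak_height <- def$u_h
  if (is.null(dur_peak_pos) && !is.null(def$d_pos)) {
    dur_peak_pos <- def$d_pos
    dur_peak_height <- def$d_h
  }
  positions <- index_to_paper(0:200)
  tmpl <- matrix(NA_real_, nrow = 4L, ncol = 201L,
                 dimnames = list(c("A", "C", "G", "T"), positions))
  up_cols <- positions <= -2L
  tmpl[, up_cols] <- def$up[rownames(tmpl)]
  tmpl[, positions == -1L] <- def$attach[rownames(tmpl)]
  down_cols <- positions >= 2L
  tmpl[, down_cols] <- def$down[rownames(tmpl)]
  site <- c(A = site_a, C = 0, G = 0, T = 0)
  rest <- def$down[c("C", "G", "T")]
  site[c("C", "G", "T")] <- (1 - site_a) * rest / sum(rest)
  tmpl[, positions == 1L] <- site[rownames(tmpl)]
  tmpl <- .apply_bump(tmpl, positions, "A", a_peak_pos, a_peak_height, 0.08)
  tmpl <- .apply_bump(tmpl, positions, "T", u_peak_pos, u_peak_height, 0.06)
  if (!is.null(dur_peak_pos)) {
    tmpl <- .apply_bump(tmpl, positions, "T", dur_peak_pos,
                        dur_peak_height, 0.05)
  }
  stopifnot(all(abs(colSums(tmpl) - 1) < 1e-12))
  tmpl
}

# triangular bump: raise `base` to height - decay * distance wherever that
# exceeds the current value, rescaling the other bases to keep columns
# normalized; never touches positions -1 and 1
#' @noRd
.apply_bump <- function(tmpl, positions, base, center, height, decay) {
  for (j in seq_along(positions)) {
    p <- positions[j]
    if (p %in% c(-1L, 1L)) next
    v <- height - decay * abs(p - center)
    if (v <= tmpl[base, j]) next
    others <- setdiff(rownames(tmpl), base)
    rest <- tmpl[others, j]
    tmpl[base, j] <- v
    tmpl[others, j] <- (1 - v) * rest / sum(rest)
  }
  tmpl
}

#' Specification for a synthetic genome + transcript dataset
#'
#' Collects every knob of the generator: the positional composition
#' template, motif plantings, tail lengths, transcript redundancy, ORF/UTR
#' structure, and the internal-priming artifact channel. Outputs are fully
#' deterministic given `seed` (each generator stage seeds its own stream
#' from `seed`, `seed + 1`, `seed + 2`, so artifact injection selects nested
#' gene subsets across rates at a fixed seed).
#'
#' @param seed Integer seed (< 2^31 - 3).
#' @param n_genes Number of genes.
#' @param template 4 x 201 base-probability matrix, see
#'   [composition_template()].
#' @param plantings data.frame with `motif` (DNA), `position` (paper
#'   coordinate of the first base) and `fraction` of genes carrying the
#'   motif; rows applied in order. The default plants AATAAA at -21 in 55%
#'   of genes.
#' @param tail_range Inclusive range of planted poly(A) tail lengths
#'   (minimum >= 12).
#' @param redundancy_rate Fraction of transcripts emitted twice.
#' @param internal_priming_rate Fraction of genes whose transcript is
#'   replaced by an internal-priming artifact read.
#' @param min_genomic_a_run Length of the genomic A-run planted in each
#'   gene's upstream flank that the artifact channel primes from.
#' @param orf_aa Encoded ORF length in amino acids (scalar or per-gene).
#' @param utr_lengths Planted 3'UTR lengths, recycled per gene; values in
#'   -2..200. -1 plants a TGA stop borrowing one tail A, -2 a TAA stop
#'   borrowing two. `NULL` samples lengths uniformly from 110..200, which
#'   keeps the whole 201-nt window free of coding sequence.
#' @param background Base probabilities for filler/flank sequence.
#' @param gene_spacing Range of intergenic gap lengths.
#' @param flank_len Genomic flank upstream of each 201-nt window (holds the
#'   planted A-run; must leave >= 131 nt upstream of it).
#' @param chrom_name Name of the single synthetic chromosome.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_genes = 2000L,
                           template = composition_template("plant"),
                           plantings = data.frame(
                             motif = "AATAAA", position = -21L,
                             fraction = 0.55, stringsAsFactors = FALSE),
                           tail_range = c(12L, 30L),
                           redundancy_rate = 0.1,
                           internal_priming_rate = 0,
                           min_genomic_a_run = 8L,
                           orf_aa = 120L,
                           utr_lengths = NULL,
                           background = c(A = 0.3, C = 0.2, G = 0.2,
                                          T = 0.3),
                           gene_spacing = c(80L, 200L),
                           flank_len = 400L,
                           chrom_name = "chr1") {
  stopifnot(n_genes >= 1L, tail_range[1L] >= 12L,
            tail_range[1L] <= tail_range[2L],
            redundancy_rate >= 0, redundancy_rate <= 1,
            internal_priming_rate >= 0, internal_priming_rate <= 1,
            min_genomic_a_run >= 1L, flank_len >= 260L,
            all(dim(template) == c(4L, 201L)),
            abs(sum(background) - 1) < 1e-9,
            seed == as.integer(seed), abs(seed) < 2^31 - 3)
  if (!is.null(utr_lengths)) {
    stopifnot(all(utr_lengths >= -2L), all(utr_lengths <= 200L))
  }
  stopifnot(all(orf_aa >= 1L))
  if (nrow(plantings)) {
    for (i in seq_len(nrow(plantings))) {
      m <- toupper(gsub("U", "T", plantings$motif[i]))
      off <- paper_to_index(plantings$position[i])
      if (off + nchar(m) > 201L) stop("planting footprint exceeds region")
      chars <- strsplit(m, "")[[1L]]
      cols <- off + seq_len(nchar(m))  # 1-based region columns
      if (any(cols == 100L & chars == "A")) {
        stop("planting would put an A at the tail attachment base ",
             "(position -1), which would extend the terminal A-run")
      }
      plantings$motif[i] <- m
      stopifnot(plantings$fraction[i] >= 0, plantings$fraction[i] <= 1)
    }
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 template = template, plantings = plantings,
                 tail_range = as.integer(tail_range),
                 redundancy_rate = redundancy_rate,
                 internal_priming_rate = internal_priming_rate,
                 min_genomic_a_run = as.integer(min_genomic_a_run),
                 orf_aa = orf_aa, utr_lengths = utr_lengths,
                 background = background,
                 gene_spacing = as.integer(gene_spacing),
                 flank_len = as.integer(flank_len),
                 chrom_name = chrom_name),
            class = "synthetic_spec")
}

#' @noRd
.bg_chars <- function(n, background) {
  if (n <= 0L) return(character(0))
  sample(names(background), n, replace = TRUE, prob = background)
}

# ATG + (aa - 1) non-stop codons + stop; guard blocks (ATA ATA ACT AAC)
# every 40 codons plant stops in both shifted frames so no competing ORF of
# >= 110 aa can end after the planted stop
#' @noRd
.make_orf <- function(aa, stop_codon) {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  nonstop <- setdiff(all64, c("TAA", "TAG", "TGA"))
  n_int <- aa - 1L
  codons <- sample(nonstop, n_int, replace = TRUE)
  if (n_int >= 44L) {
    for (g in seq.int(40L, n_int - 3L, by = 40L)) {
      codons[g:(g + 3L)] <- c("ATA", "ATA", "ACT", "AAC")
    }
  }
  paste0("ATG", paste(codons, collapse = ""), stop_codon)
}

#' Generate a synthetic reference genome with known poly(A) site truth
#'
#' Draws each gene's 201-nt poly(A) site window from the positional
#' template, plants signal motifs in the configured gene fractions, embeds
#' the planted ORF (overwriting window bases only when the planted UTR is
#' shorter than the 100-nt anchor, including the -1/-2 stop/tail overlap
#' fixtures), prepends a flank carrying the A-run used by the
#' internal-priming channel, and lays the genes non-overlapping on both
#' strands of one chromosome, each with ample clearance from the contig
#' ends.
#'
#' @param spec A [synthetic_spec()].
#' @return list with `genome` (a one-sequence [Biostrings::DNAStringSet])
#'   and `truth` (one row per gene: locus, strand, true tail-start
#'   coordinate, planted motif presence/position, planted UTR length, the
#'   full transcript body, and the effective 100-nt anchor).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  bases <- c("A", "C", "G", "T")
  # per-position draws from the template
  win <- matrix("", nrow = n, ncol = 201L)
  for (w in seq_len(201L)) {
    win[, w] <- sample(bases, n, replace = TRUE,
                       prob = spec$template[, w])
  }
  # planted UTR lengths and ORFs
  utr <- if (is.null(spec$utr_lengths)) {
    sample(110:200, n, replace = TRUE)
  } else {
    rep_len(as.integer(spec$utr_lengths), n)
  }
  aa <- rep_len(as.integer(spec$orf_aa), n)
  pad_len <- 20L
  body <- character(n)
  for (g in seq_len(n)) {
    u <- utr[g]
    stop_codon <- if (u == 0L) "TAG" else if (u == -1L) "TGA" else "TAA"
    orf <- .make_orf(aa[g], stop_codon)
    orf_nt <- nchar(orf)
    pad <- paste(.bg_chars(pad_len, spec$background), collapse = "")
    if (u >= 100L) {
      filler <- paste(.bg_chars(u - 100L, spec$background), collapse = "")
      up100 <- paste(win[g, 1:100], collapse = "")
      body[g] <- paste0(pad, orf, filler, up100)
    } else if (u >= 0L) {
      # stop codon ends at anchor offset 100 - u; ORF suffix overwrites
      # the start of the anchor, template bases fill the short UTR
      n_over <- 100L - u
      stopifnot(orf_nt > n_over)
      orf_suffix <- substr(orf, orf_nt - n_over + 1L, orf_nt)
      tail_tmpl <- if (u > 0L) {
        paste(win[g, (n_over + 1L):100L], collapse = "")
      } else ""
      up100 <- paste0(orf_suffix, tail_tmpl)
      win[g, 1:100] <- strsplit(up100, "")[[1L]]
      body[g] <- paste0(pad, substr(orf, 1L, orf_nt - n_over), up100)
    } else {
      # -1/-2: the stop codon borrows |u| tail adenosines
      in_body <- orf_nt - (-u)
      orf_body <- substr(orf, 1L, in_body)
      up100 <- substr(orf_body, in_body - 99L, in_body)
      win[g, 1:100] <- strsplit(up100, "")[[1L]]
      win[g, 101L] <- "A"   # the templated base the stop borrows
      body[g] <- paste0(pad, orf_body)
    }
  }
  # motif plantings (skipped where the ORF owns the footprint)
  has_motif <- matrix(FALSE, nrow = n, ncol = max(1L, nrow(spec$plantings)))
  if (nrow(spec$plantings)) {
    for (i in seq_len(nrow(spec$plantings))) {
      m <- strsplit(spec$plantings$motif[i], "")[[1L]]
      cols <- paper_to_index(spec$plantings$position[i]) + seq_along(m)
      sel <- stats::runif(n) < spec$plantings$fraction[i]
      orf_owned <- utr < 100L & (100L - pmax(utr, 0L)) >= min(cols)
      sel <- sel & !orf_owned
      if (any(sel)) {
        win[sel, cols] <- matrix(m, nrow = sum(sel), ncol = length(m),
                                 byrow = TRUE)
        up_cols <- cols[cols <= 100L]
        if (length(up_cols)) {
          for (g in which(sel)) {
            b <- body[g]
            L <- nchar(b)
            substr(body[g], L - 100L + min(up_cols),
                   L - 100L + max(up_cols)) <-
              paste(m[cols <= 100L], collapse = "")
          }
        }
      }
      has_motif[, i] <- sel
    }
  }
  window201 <- apply(win, 1L, paste, collapse = "")
  # genomic layout: [gap][flank with planted A-run][window201] per gene
  strand <- sample(c("+", "-"), n, replace = TRUE)
  run_len <- spec$min_genomic_a_run
  gap_len <- sample(spec$gene_spacing[1L]:spec$gene_spacing[2L], n,
                    replace = TRUE)
  prime_gap <- sample(30:120, n, replace = TRUE)
  glen <- spec$flank_len + 201L
  pieces <- character(2L * n + 1L)
  gene_start <- integer(n)
  prime_tx_pos <- integer(n)
  offset <- 0L
  for (g in seq_len(n)) {
    pieces[2L * g - 1L] <- paste(.bg_chars(gap_len[g], spec$background),
                                 collapse = "")
    offset <- offset + gap_len[g]
    flank <- .bg_chars(spec$flank_len, spec$background)
    q <- spec$flank_len - run_len - prime_gap[g] + 1L  # run start (tx pos)
    flank[q:(q + run_len - 1L)] <- "A"
    flank[q - 1L] <- "C"                 # keep the planted run maximal
    flank[q + run_len] <- "C"
    gene_seq <- paste0(paste(flank, collapse = ""), window201[g])
    if (strand[g] == "-") {
      gene_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gene_seq)))
    }
    gene_start[g] <- offset + 1L
    prime_tx_pos[g] <- q
    pieces[2L * g] <- gene_seq
    offset <- offset + glen
  }
  pieces[2L * n + 1L] <- paste(
    .bg_chars(spec$gene_spacing[2L] + 201L, spec$background), collapse = "")
  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- spec$chrom_name
  tailstart <- ifelse(strand == "+",
                      gene_start + spec$flank_len + 100L,
                      gene_start + 100L)
  prime_run_start <- ifelse(strand == "+",
                            gene_start + prime_tx_pos - 1L,
                            gene_start + glen - prime_tx_pos)
  truth <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = spec$chrom_name,
    strand = strand,
    gene_start = gene_start,
    gene_len = glen,
    tailstart_coord = as.integer(tailstart),
    window201 = window201,
    has_motif = has_motif[, 1L],
    motif = if (nrow(spec$plantings)) spec$plantings$motif[1L] else
      NA_character_,
    motif_position = if (nrow(spec$plantings))
      spec$plantings$position[1L] else NA_integer_,
    utr_planted = utr,
    aa_planted = aa,
    body = body,
    anchor = substr(body, nchar(body) - 99L, nchar(body)),
    prime_tx_pos = prime_tx_pos,
    prime_run_start_coord = as.integer(prime_run_start),
    artifact = FALSE,
    stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

#' Generate poly(A)-tailed transcripts for a synthetic genome
#'
#' Each transcript is its gene's body (5' pad + ORF + planted UTR, ending at
#' the tail attachment base) plus a poly(A) tail drawn from the configured
#' length range; a `redundancy_rate` fraction of transcripts is emitted
#' twice (ids suffixed `_dup`).
#'
#' @param spec A [synthetic_spec()].
#' @param genome,truth Output of [generate_genome()] (`genome` is unused but
#'   kept in the signature for symmetry with the other stages).
#' @return A [Biostrings::DNAStringSet] of transcripts.
#' @export
generate_transcripts <- function(spec, genome, truth) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  n <- nrow(truth)
  tails <- sample(spec$tail_range[1L]:spec$tail_range[2L], n,
                  replace = TRUE)
  seqs <- paste0(truth$body, strrep("A", tails))
  ids <- paste0("tx_", truth$gene_id)
  n_dup <- round(spec$redundancy_rate * n)
  if (n_dup > 0L) {
    dup <- sample(n, n_dup)
    seqs <- c(seqs, seqs[dup])
    ids <- c(ids, paste0(ids[dup], "_dup"))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Replace a gene fraction's transcripts by internal-priming artifacts
#'
#' Emulates oligo(dT) priming inside a genomically A-rich stretch: for the
#' selected genes the transcript is truncated at the planted genomic A-run
#' upstream of the true site and an artificial poly(A) tail is appended, so
#' the apparent tail-start position falls on templated adenosines. At a
#' fixed seed the selected subsets are nested across increasing rates.
#'
#' @param spec A [synthetic_spec()] with `internal_priming_rate > 0` (a
#'   rate of 0 returns the inputs unchanged).
#' @param genome,transcripts,truth Outputs of the previous stages.
#' @return list with modified `transcripts` and `truth` (artifact rows
#'   flagged, with `artifact_tailstart_coord` set; genes lacking a
#'   qualifying A-run are skipped and counted in the `n_skipped`
#'   attribute).
#' @export
inject_internal_priming <- function(spec, genome, transcripts, truth) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth$artifact_tailstart_coord <- NA_integer_
  if (spec$internal_priming_rate <= 0) {
    return(list(transcripts = transcripts, truth = truth,
                n_skipped = 0L))
  }
  set.seed(spec$seed + 2L)
  n <- nrow(truth)
  perm <- sample(n)
  n_sel <- round(spec$internal_priming_rate * n)
  sel <- perm[seq_len(n_sel)]
  tail_art <- sample(spec$tail_range[1L]:spec$tail_range[2L], n,
                     replace = TRUE)
  chrom <- genome[[1L]]
  n_skipped <- 0L
  seqs <- as.character(transcripts)
  ids <- names(transcripts)
  ext <- 30L
  for (g in sel) {
    q <- truth$prime_tx_pos[g]
    if (is.na(q) || q - 100L - ext < 1L) {
      n_skipped <- n_skipped + 1L
      next
    }
    o <- truth$gene_start[g]
    if (truth$strand[g] == "+") {
      from <- o + (q - 100L - ext) - 1L
      to <- o + (q - 1L) - 1L
      body_art <- as.character(Biostrings::subseq(chrom, from, to))
    } else {
      glen <- truth$gene_len[g]
      from <- o + glen - (q - 1L)
      to <- o + glen - (q - 100L - ext)
      body_art <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(chrom, from, to)))
    }
    art <- paste0(body_art, strrep("A", tail_art[g]))
    hit <- ids == paste0("tx_", truth$gene_id[g]) |
      ids == paste0("tx_", truth$gene_id[g], "_dup")
    seqs[hit] <- art
    truth$artifact[g] <- TRUE
    truth$artifact_tailstart_coord[g] <- truth$prime_run_start_coord[g]
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  list(transcripts = out, truth = truth, n_skipped = n_skipped)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generate_genome()], [generate_transcripts()] and,
#' when the artifact rate is positive, [inject_internal_priming()].
#'
#' @param spec A [synthetic_spec()].
#' @return list with `genome`, `transcripts`, `truth`, `spec`.
#' @export
simulate_dataset <- function(spec) {
  gen <- generate_genome(spec)
  tx <- generate_transcripts(spec, gen$genome, gen$truth)
  inj <- inject_internal_priming(spec, gen$genome, tx, gen$truth)
  list(genome = gen$genome, transcripts = inj$transcripts,
       truth = inj$truth, spec = spec)
}

#' Expected per-position base probabilities after motif planting
#'
#' The template mixed with the plantings: at a footprint position the
#' expected probability is `fraction * [base == motif base] + (1 -
#' fraction) * template`. Exact for non-overlapping footprints and for
#' genes whose planted UTR keeps the window free of coding sequence (the
#' default); used by parameter-recovery checks to compute truth-derived
#' expectations.
#'
#' @param spec A [synthetic_spec()].
#' @return 4 x 201 probability matrix like the template.
#' @export
template_effective_probs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  eff <- spec$template
  if (nrow(spec$plantings)) {
    for (i in seq_len(nrow(spec$plantings))) {
      m <- strsplit(spec$plantings$motif[i], "")[[1L]]
      cols <- paper_to_index(spec$plantings$position[i]) + seq_along(m)
      f <- spec$plantings$fraction[i]
      for (j in seq_along(cols)) {
        ind <- as.numeric(rownames(eff) == m[j])
        eff[, cols[j]] <- f * ind + (1 - f) * spec$template[, cols[j]]
      }
    }
  }
  eff
}
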