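---
title: "Mapping poly(A) sites and profiling their sequence context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping poly(A) sites and profiling their sequence context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyamap)
```

## The measurement

Cleavage and polyadenylation leave a precise landmark in every mRNA: the
boundary between the last templated base (the *tail attachment position*)
and the first adenosine of the poly(A) tail (the *tail starting position*).
`polyamap` operationalizes poly(A) site discovery from that landmark alone:

1. **Tail screen.** A transcript is poly(A)-tailed when it ends in an
   uninterrupted terminal run of at least 12 A's (`min_tail = 12`). The run
   is maximal and terminal-anchored; an interrupted run does not qualify.
2. **Anchor dedup.** The 100 nt immediately upstream of the tail (the
   *anchor*) define transcript identity: transcripts sharing an anchor are
   redundant copies and collapse to one representative.
3. **Zero-mismatch mapping.** The anchor is located in the reference genome
   by exact matching on both strands. No mismatches, no indels; anchors
   containing N never match, because an ambiguous base cannot be confirmed
   against the reference.
4. **Region assembly.** Around each mapped tail-start base we keep 201 nt:
   the anchor (positions −100..−1), the tail-start base itself (position 1;
   there is no position 0), and 100 nt of the cleaved-off region
   (positions 2..101), all in transcription orientation.
5. **Unique sites.** Mapped regions whose upstream 100 nt are identical are
   one unique site, regardless of downstream differences — this removes
   inflation from gene copy-number variation. The representative locus is
   the lexicographically smallest `(chrom, coordinate, strand)` and the
   number of collapsed loci and source mRNAs is recorded.

Everything downstream is descriptive statistics over the unique-site
regions: per-position base-frequency matrices, sequence-logo information
content, windowed k-mer tables, motif location profiles, genome-wide k-mer
baselines, and 3′UTR lengths.

Coordinates deserve one remark: `paper_to_index()` maps the signed
positions to zero-based offsets into the 201-character region string
(−100 → 0, −1 → 99, 1 → 100, 5 → 104). The zero-based convention keeps the
two halves of the skip-zero coordinate system one arithmetic expression
apart; R code slices strings at `paper_to_index(p) + 1`.

## Information content and logos

For a column with base probabilities $p_j$ ($J = 4$),

$$\mathrm{IC} = \log_2 J + \sum_j p_j \log_2 p_j,$$

with $0\log_2 0 = 0$; the value lies in $[0, 2]$ bits, 0 for a uniform
column and 2 for a fixed base. Letter heights are $p_j \cdot \mathrm{IC}$,
so a column's stack height equals its information content. Positions where
a site carries an N are excluded from that position's numerator and
denominator only — per-position exclusion wastes less data than dropping
whole sites and matches per-position counting semantics.

## Motif statistics

Motif windows constrain the motif's *first* base only, so footprints may
cross the poly(A) site; this is deliberate and matches how upstream windows
are usually defined. The presets are `[-50,-1]` for hexamers, `[-50,-3]`
for pentamers (the only reading under which that window is exactly 48 bases
and ends two bases upstream of the tail start), the single start `-3` for
the tetramer whose last base covers the site, and `[2,51]` downstream.
Tables always enumerate the full $4^k$ alphabet with deterministic
(lexicographic) tie-breaking, so ranks are comparable across runs; a site
counts once per motif no matter how many copies it carries, while location
profiles additionally report accumulated (overlapping) copies, which can
exceed 100%.

Genome-wide k-mer baselines count overlapping windows by default, which
conflates homopolymers (seven A's contain two AAAAAA); a greedy
non-overlapping mode is available. Enrichment is simply
`(site% / 100) / genome frequency`. For the known downstream elements
(UUAUUU, CCUCCC, UGUGUG, GUGUGU, UGUUUG, AUGCGU) no specific test is
canonical; we use a two-sided exact binomial test of each element's
with-copy count against the mean with-copy probability of all same-length
motifs in the same window (α = 0.01) — the simplest defensible null for
"more frequent than the average motif of its size". Run comparisons (e.g.
mRNA-derived vs RNA-seq-derived catalogs) use the uncorrected Pearson
two-proportion chi-square; the uncorrected form is pinned by an independent
reference implementation in the tests.

## 3′UTR lengths

The 3′UTR length is the number of nucleotides between the stop codon and
the poly(A) site. ORFs are ATG-initiated, read to the first in-frame stop,
in the three sense frames of the tail-stripped body. Because the tail is
all A's, a stop codon can be completed by tail bases: a body ending `…TG`
reads TGA (one borrowed base, UTR −1), a body ending `…T` reads TAA (two
borrowed bases, UTR −2). A body ending `…TA` is observationally identical
to `…T` with a one-base-longer tail — the screen conflates them — so −2 is
the reported value for that case and the generator never constructs it.
The qualifying ORF must encode at least 110 residues (the ATG counts, the
stop does not; the boundary is tested at 109/110). "Last ORF" is read as
last-*ending* (greatest stop coordinate, ties to the greatest start), the
reading consistent with measuring the distance from *the stop codon* to the
site; last-*starting* would differ only when a long ORF spans a shorter
one's stop, and the choice is isolated in `last_qualifying_orf()`.

## What the synthetic generator emulates

`synthetic_spec()` describes a genome whose genes follow a positional
base-composition template over the 201-nt window, shaped like the conserved
U-A-U-A-U pattern: U-rich far upstream, an A-rich bump, a near-upstream U
bump, a strong site A, and a U-rich downstream region. Two presets mirror
the kingdoms' reported geometries — plant-like (A peak −21 at 41%, U peak
−7 at 56%, flat downstream) and animal-like (A peak −18 at 54%, U peak −9
at 42%, downstream U peak +19). Bumps are triangular with a fixed per-base
decay (0.08/base for the A bump, 0.06 for the U bump) so each planted peak
has a unique argmax that parameter-recovery tests can demand *exactly*; the
heights are the study conditions, chosen once from the reported magnitudes.
Signal motifs are planted by overwriting the footprint in a configured gene
fraction (default AATAAA at −21 in 55% of genes, the animal-range
frequency). Transcripts are the gene body (5′ pad + planted ORF + UTR) plus
a tail of 12–30 A's, with a configurable fraction emitted twice to exercise
anchor dedup.

Two constructive guarantees make truth exact rather than approximate:

* The template assigns probability 0 to A at position −1 (real species
  almost always use U or C there), so a transcript's maximal terminal A-run
  is exactly its planted tail and the recorded anchor is the effective
  anchor.
* ORF interiors are non-stop codons with guard blocks (`ATA ATA ACT AAC`,
  which plant stops in both shifted frames) every 40 codons, and planted
  UTRs are capped at 200 nt; no competing ≥110-aa ORF can therefore end
  after the planted stop, and recovered UTR lengths equal the planted ones
  by construction.

The internal-priming channel emulates oligo(dT) priming inside genomically
A-rich stretches: every gene's upstream flank carries a planted A-run
(default 8 A's, 150–250 nt upstream of the true site, outside the profiled
window); at rate *r* the selected genes' transcripts are replaced by reads
truncated at that run with an artificial tail appended. Apparent tail-start
positions then fall on templated adenosines, so mean A frequency at
positions 1..6 rises with *r* — the direction real RNA-seq contamination
shows. Each generator stage seeds its own stream (`seed`, `seed+1`,
`seed+2`), so at a fixed seed the selected gene subsets are *nested* across
rates and the monotonicity is a property of the rate, not of resampling.

What the generator does **not** emulate: splicing, expression-level
variation, sequencing error, alternative polyadenylation within a gene, or
genomes with repeats (anchors are unique almost surely). Passing recovery
tests therefore demonstrates correctness of the measurement machinery under
clean conditions, not robustness to real-data pathologies such as
paralogous anchors or mismatch-laden transcripts — the zero-mismatch rule
simply drops the latter.

## Problem sizes and numerical choices

Parameter-recovery checks run at 2000 genes (binomial SE about 1.1
percentage points, so planted peaks clear their neighbours by 3–5 SE);
the priming-rate monotonicity check uses 600 genes per rate, and boundary
and overlap fixtures use a few dozen. These sizes are the package's chosen
trade-off between statistical resolution and a test suite that runs in a
couple of minutes. Other numerical choices: probability vectors must sum
to 1 within 1e-9; peak ties break toward the position nearest the site;
the plateau flag compares a window's max to its median with a default
threshold of 5 percentage points; multi-locus anchors are retained (they
collapse by the unique-site rule anyway) with multiplicity recorded, and a
`drop_multi_locus` switch excludes them instead.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 7, n_genes = 300)
sim <- simulate_dataset(spec)
run <- run_pipeline(sim$transcripts, sim$genome)
run
#> polya_run: 300 unique sites from 330 input transcripts
#>   stages: input=330, no_tail=0, short_body=0, tailed=330,
#>     distinct_anchors=300, mapped_anchors=300, loci=300, edge_dropped=0,
#>     unique_sites=300
#>   top upstream hexamers: AAUAAA (49.7%), UUUUUA (31.3%), UUUUUU (28.7%)

run$profiles$AATAAA
#> motif_position_profile: AATAAA over 300 sites; peak 48.33% at position
#>   -21 ; accumulated 55.67%

summarize_uauau(run$composition)
#>   component base peak_position peak_frequency plateau
#> 1      uur1    T           -93       55.66667   FALSE
#> 2       uar    A           -21       70.66667   FALSE
#> 3      uur2    T            -7       58.66667   FALSE
#> 4    site_a    A             1       79.66667      NA
#> 5       dur    T            26       50.66667   FALSE
```

The AAUAAA location profile peaks at −21 (where it was planted), the
A-rich/U-rich components sit at −21/−7, and the site is an A in ~80% of
regions. At this small n the plateau flags are noisy; at n = 2000 the
plant-like downstream region is correctly flagged flat.

## Known limitations

Exact anchor matching requires transcripts to match the reference
perfectly over 100 nt; polymorphic or error-containing inputs are silently
unmapped (counted, not rescued). Contig-edge sites lacking 101 downstream
bases are dropped to keep matrices fixed-width. The chi-square comparison
assumes the two runs' site sets are independent samples, which is
approximate when they derive from overlapping transcript pools.
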