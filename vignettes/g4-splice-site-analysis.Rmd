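---
title: "G-quadruplex topography around splice sites: models and methods"
author: "g4splice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G-quadruplex topography around splice sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4splice)
```

## The scientific question

G-quadruplexes (G4s) are four-stranded nucleic-acid structures formed by
stacked guanine tetrads. The DNA consensus motif is four or more runs of at
least three guanines separated by loops of one to seven nucleotides
(G≥3 N1–7 G≥3 N1–7 G≥3 N1–7 G≥3). When such a motif sits on the
non-template (coding) strand near a splice site, the corresponding RNA G4
appears in the pre-mRNA, where it can influence spliceosome recruitment.
`g4splice` implements a reusable genome-wide pipeline for asking whether G4
motifs are positionally enriched around splice junctions, how that
enrichment depends on splice-site strength, strand and intron length, and
whether G4 presence is associated with changes in alternative splicing
(ΔPSI contingency statistics, sQTL enrichment, RNA-binding-protein
occupancy). Every stage can be exercised end to end on seeded synthetic
data with planted ground truth, so the statistical machinery is testable
without any external downloads.

## Motif scanning

The scanner tokenises each strand into maximal G-runs (three or more
consecutive G; runs absorb adjacent Gs greedily, so a run of fifteen Gs is
one run, not a chain) and chains consecutive runs whose gaps are 1–7 nt.
A chain of *k* runs is a G-run block of order *k* (reported capped at 6);
a chain with *k* ≥ 4 is a consensus G4. Hits are therefore leftmost,
maximal and non-overlapping within a strand. Minus-strand motifs are found
by scanning the plus-strand sequence for the mirrored C-pattern, keeping
all coordinates on the plus strand in a single pass. `N` never counts as a
guanine but is permitted inside loops, which is the conservative choice on
masked assemblies. The test suite checks the scanner against an exhaustive
oracle that enumerates every chain candidate and applies the same
leftmost-longest selection, plus a strand-symmetry property under reverse
complement.

```{r scan}
scan_g4("GGGAGTGGGCAGGGGTGGGGG", chrom = "oligo")
```

## Splice sites, strand context and strength

Internal exons of each transcript contribute an acceptor (3'ss) and a donor
(5'ss); junction coordinates are 0-based boundaries in transcription order,
and BED-style half-open intervals are the internal convention everywhere
(GTF input is converted at the boundary). With a genome attached, sites
whose introns are not GT..AG on the gene strand are dropped by default.
Junctions shared by several transcripts are collapsed to one site, since
per-splice-site statistics would otherwise double-count; a flag keeps the
duplicates. A motif is *non-template* when its strand equals the gene
strand — exactly the motifs that become RNA G4s in the transcript.

Splice-site strength is a plain log-odds score against a positional
frequency matrix: `sum(log2((f + eps) / 0.25))` with a pseudocount of
1e-3 and a uniform background. Window geometry follows the usual
donor 9-mer (3 exonic + 6 intronic) / acceptor 23-mer (20 intronic +
3 exonic) convention; widths and the junction offset are read from the
matrix file itself. The matrices shipped under `inst/extdata/` are
synthetic consensus constructs (documented in `synthetic_pfm()`) intended
for tests and the synthetic pipeline, not empirical frequencies. Sites are
stratified into quartiles (or deciles) with tie-aware, near-equal bins;
binning is invariant to adding a constant to all scores.

## Positional profiles and densities

For each signed offset (transcription orientation) around a set of sites,
the metaprofile counts the sites at which a feature registers — by default
any overlapping feature base pair ("coverage" mode, matching how peak base
pairs are treated; start/midpoint registration is available because the
profile convention for motifs is genuinely ambiguous in the field).
Enrichment is the per-offset count over the **median count across a fixed
1 kb window**, whatever the displayed half-width; confidence bands are
Wilson 95% intervals scaled by the same constant. A zero median leaves
enrichment undefined (returned as missing with a warning) rather than
silently rescaled. Group densities are occurrences per window base pair
with a seeded bootstrap (resampling sites with replacement, 1000-fold by
default) for the error bars.

## The dinucleotide-preserving permutation null

GC-rich splice neighbourhoods inflate naive G4 counts, so the corrected
enrichment compares the observed motif count in splice-site windows with
the median count over 1000 independent shuffles of every window. The
shuffle is the exact Altschul–Erickson construction: a uniform random
Eulerian path through the dinucleotide transition multigraph, preserving
the exact 2-mer multiset and the first (hence last) character of each
window. Windows are shuffled independently so no motif can span a window
boundary. The empirical p-value uses the add-one estimator
`(1 + #{perm ≥ obs}) / (N + 1)`, with the raw exceedance fraction also
reported since printed thresholds like p < 0.001 can refer to either
convention. The fused permutation loop is implemented in C++ (with a fast
counter-based PRNG seeded from R's RNG stream, so one master seed fully
determines the whole run) because a calibration of 100 repetitions × 1000
permutations × ~1600 windows — the scale used in the calibration suite —
amounts to hundreds of millions of shuffles; single shuffles go through
the same Eulerian construction in the `dinuc_shuffle()` path.

A note on calibration scale: the fold statistic `observed /
median(permuted)` is only informative when the expected motif mass per
window set is large — a ±10% fold band corresponds to ±3 standard
deviations only once roughly 900 motifs are expected. The null-calibration
test therefore draws windows from a G/C-rich first-order background
(p(G) = p(C) = 0.45, 1600 windows of 200 nt), sized by that power
calculation. At realistic genomic composition the same code path works but
the fold of a desk-scale window set is dominated by count granularity.

## Association statistics

Splicing nodes (Whippet-style ΔPSI tables) are *differential* when
|ΔPSI| ≥ 0.1 and probability ≥ 0.9 — both thresholds inclusive, recorded
on the object, since the source conventions alternate between strict and
inclusive at the boundary. A node is G4-associated when the nearer of its
boundaries is within 100 bp of a motif midpoint or 45 bp of a
structure-probing peak midpoint. Each (node type × direction) stratum gets
a 2×2 contingency (differential of that direction vs non-differential ×
G4 ±) with the odds ratio, Yates-corrected chi-squared and Bonferroni
adjustment over the testable strata; a zero cell triggers the Haldane
correction (+0.5 to all cells, flagged) for the odds ratio only.

Intron-length comparisons report per-group medians with Mann–Whitney U and
Kolmogorov–Smirnov tests. GC-matched controls pair each short intron
(< 500 nt) with the unused long intron of nearest GC content (whole-intron
GC; greedy, seeded processing order, pairs discarded beyond a 0.01
tolerance). The sQTL track divides ±500 bp around the junctions into 25 bp
bins; per bin, variant density *inside G4 intervals* is normalised by the
mean density across defined bins, and the adjusted value is the sQTL
enrichment over the SNP enrichment. The mean (not median) is the
normaliser — the choice is deliberate and matters: with an uplift *u*
confined to a fraction φ of the bins, the expected adjusted value in
uplifted bins is u/(1 + φ(u−1)), not u, while the uplifted-to-background
*ratio* recovers u exactly. The acceptance suite asserts both the
closed-form levels and the ratio. The track is scale-invariant under
doubling both variant sets.

## eCLIP integration

Splice-site regions (−100..+100 by default) are cut into 10 bp bins. Per
bin, the binding fraction is the share of sites in a group with at least
one peak base pair in the bin — a presence/absence definition chosen
because peaks are calls, not quantitative coverage, and it keeps the
estimate coherent with the per-bin 2×2 chi-squared test (bound/unbound ×
G4-flanked/non-flanked) that gates significance. Non-significant
differentials are set to zero (idempotent masking) before Ward clustering
(`hclust`, "ward.D2", Euclidean distance on the concatenated
non-template ‖ template masked tracks) cut at k = 10. Rows are sorted by
profile id before clustering so assignments do not depend on input order.
High-confidence factors need a significant eCLIP profile and a significant
loss-of-function splicing association in the *same* cell line, plus at
least two replicates sharing a cluster.

## The synthetic-data generators

The generators define the study conditions for every test:

* **Genome** — first-order Markov chains, default four chromosomes of
  1.25 Mb at GC 0.42 with CpG depletion (transition factor 0.4), which is
  the realistic mammalian-like regime for the motif statistics.
* **Genes** — 300 non-overlapping genes, 5–9 exons, log-normal exon
  (median 140 nt) and intron (median 1 kb, sdlog 1 — the heavy tail the
  length analyses rely on) lengths; intron termini overwritten to GT..AG
  on the gene strand.
* **Planted G4s** — per-site Bernoulli (default rate 0.35), offset ~
  N(50, 15) on the intronic side, non-template with probability 2/3 (the
  2:1 asymmetry used in the recovery tests). Motifs are written over the
  background (coordinates stay exact) with an 8 nt A/T buffer on each
  side, because a background G-run within 7 nt would otherwise fuse with
  the planted block and shift the truth coordinates. An optional coupling
  of the rate to intron length generates short-intron enrichment
  scenarios.
* **PSI tables** — differential status from a logistic model whose odds
  multiply by the planted odds ratio at G4-flagged nodes; ΔPSI magnitudes
  straddle the 0.1 threshold by construction; 85% of differential nodes
  are exclusions, emulating depolarisation-style skewing.
* **Variants / peaks / eCLIP** — per-position Bernoulli backgrounds with
  an sQTL uplift inside G4s within ±100 bp of a junction, peaks
  overlapping motifs with jittered edges at probability 0.8, and per-bin
  binding probabilities (0.6 vs 0.3 in the planted bins).

Everything is deterministic in one master seed; each generator derives a
counter-based child seed, so regenerating any single input reproduces it
exactly. What the generators do **not** emulate: real splice-site sequence
grammar beyond GT/AG, nucleotide-level selection, overlapping genes,
alternative transcript structure, and read-level noise. Passing tests
therefore demonstrate that the statistics recover known planted structure
at realistic scales — not that any particular biological genome shows that
structure.

## Numerical choices and degenerate inputs

* Quantile ties go to the lower bin; an all-tied score vector lands in bin
  1 with a warning.
* Zero-median profiles, empty strata, chromosomes without features, bins
  without G4 base pairs and untestable contingency margins are reported as
  missing/flagged, never silently dropped.
* The Eulerian shuffle returns inputs shorter than two characters (and
  single-letter alphabets) unchanged.
* Chromosome-name mismatches between FASTA and annotation are an error;
  `normalize_chrom_names()` is the explicit opt-in fix, because silent
  reconciliation produces empty but plausible-looking results.
* Windows running off a chromosome are clipped (profiles) or dropped with
  a warning (PWM scoring); splice-site windows are deliberately *not*
  trimmed at neighbouring exons, matching the no-trimming reading of the
  windowed analyses.

## Problem sizes used by the test and acceptance suites

Scanner–oracle equivalence runs on 10,000 random sequences up to 200 nt;
null calibration on 100 repetitions of 1600 windows × 1000 permutations;
odds-ratio recovery on 100 repetitions × 2000 nodes for each planted OR in
{1, 2, 4}; the planted-effect and sQTL checks on bundles of 120–400 genes.
These sizes were chosen so each statistic operates in the regime where its
sampling error is small relative to the asserted tolerance.

## Known limitations

* Only the canonical intramolecular consensus motif is scanned; long-loop,
  bulged and intermolecular G4s and thermodynamic scores are out of scope
  (structure-probing peak tracks can be supplied instead).
* The splice-strength score is an independent-position log-odds model, not
  a maximum-entropy model with positional dependencies.
* The per-bin eCLIP statistic is a bound-site fraction; if quantitative
  read densities are available they must be reduced to peak calls first.
* Full-scale reproduction of published genome-wide numbers requires the
  corresponding public assemblies, annotation and consortium tracks;
  nothing in the test suite depends on them.
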