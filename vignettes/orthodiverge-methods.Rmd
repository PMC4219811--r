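---
title: "Methods: codon-level divergence, selection screens and rate calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-level divergence, selection screens and rate calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodiverge)
```

## What the package computes

`orthodiverge` compares two sets of coding sequences — typically the
transcriptomes of two related species, such as a pair of *Crassostrea*
oysters with divergent osmotic ecologies — and asks three questions:

1. Which sequences are putative one-to-one orthologs?
2. For each ortholog pair, what are the synonymous and nonsynonymous
   substitution rates (Ks, Ka), and does their ratio ω = Ka/Ks suggest
   positive selection?
3. What neutral, per-year substitution rate does the transcriptome-wide
   synonymous divergence imply, given a divergence time?

Alongside, it applies the standard post-calling screens to two-group SNP
tables and raw-read QC rules, and — centrally for testing — simulates all
of these inputs under a codon substitution model with known truth.

## The codon substitution model

The simulator (`codon_rate_matrix()`, `evolve_codon_sequence()`) uses the
standard Markov codon model family: states are the 61 sense codons of the
standard genetic code (stops are excluded from the state space), and the
instantaneous rate from codon *i* to codon *j* is

* 0 if *i* and *j* differ at more than one nucleotide position or *j* is a
  stop codon;
* proportional to π<sub>j</sub>, multiplied by κ when the change is a
  transition and by ω when it is nonsynonymous, otherwise.

The generator is rescaled so that one unit of branch length equals one
expected nucleotide substitution per site at stationarity (3 codon-level
expected events per codon). Branch lengths are therefore directly
comparable with the clock distance *d* = 2*t* between two species.
Detailed balance π<sub>i</sub>q<sub>ij</sub> = π<sub>j</sub>q<sub>ji</sub>
holds by construction, and the test suite asserts it on the constructed
matrix.

Sequences are evolved by exact continuous-time simulation — per-codon
exponential waiting times and embedded-chain jumps — rather than by
discretised steps, so recovery tests are free of step-size bias. Codons
with no allowed move (Met and Trp when ω = 0) are absorbing and simply
persist. An ortholog pair is produced by drawing an ancestor from the
equilibrium frequencies and evolving it down two independent branches of
half the pair divergence.

The frequency model is deliberately exposed as a free parameter (default
uniform over sense codons) rather than fixed to F3x4: nothing in the
production data constrains it, and uniform frequencies make analytic
expectations (via the matrix exponential) transparent in tests.

## Ka/Ks estimation

Two counting estimators are implemented, deliberately tiered:

* **NG86** (`estimate_kaks_ng86()`): the classic Nei–Gojobori scheme.
  Sites are counted per codon with equal mutation weights; differences are
  counted by enumerating all orderings of the differing positions (1, 2 or
  6 pathways), discarding pathways through stop codons and averaging the
  survivors with equal weights; Jukes–Cantor corrects for multiple hits.
  Every ingredient is enumerable by brute force, and the test suite checks
  all 61 codons and all 61×61 codon pairs against an independent
  enumerator. This is the reference/oracle method.

* **YN-style** (`estimate_kaks_yn()`, the default in `kaks()`): the
  production method, in the spirit of the Yang–Nielsen approximate method
  that the field's usual calculator implements. It estimates κ from
  four-fold degenerate third positions with the Kimura two-parameter
  model, builds F3x4 codon frequencies from the pair, weights the
  mutational-opportunity site counts by both, and applies the K80
  correction separately to the synonymous and nonsynonymous
  transition/transversion proportions. We make no claim of
  number-for-number agreement with any particular external
  implementation, whose pathway weighting and κ averaging differ in
  detail; the verifiable contract is (a) exact reduction to the NG86
  counting layer when κ = 1 and uniform frequencies are forced, and (b)
  recovery of the generating ω and κ on simulated data. On the test grid
  (ω ∈ {0.2, 0.5, 1.0, 1.5} × κ ∈ {1, 2, 4}, pair divergence 0.16
  substitutions/site, 20 replicates of 10,000 codons) mean ω̂ is within
  15% of truth and mean κ̂ within 10%.

Numerical guards: κ̂ is capped to [0.1, 20] and falls back to 1 (with a
warning) below 10 informative four-fold sites; zero position-specific
nucleotide counts get an add-half pseudocount; saturation (a JC/K80
logarithm argument reaching zero) yields a flagged, undefined estimate
rather than a number; undefined ω (Ks = 0) propagates as missing, never as
infinity; columns whose every mutational pathway crosses a stop codon are
excluded and counted. All estimator outputs are exactly symmetric in
sequence order.

## Orthology, alignment, and their scale

Production ortholog detection consumes precomputed tabular hit files
(`read_blast_hits()`, the 12-column tabular search format), so any search
engine can be used upstream. `reciprocal_best_hits()` applies the
bidirectional unique-best rule at the conventional bit-score threshold of
300; tied best scores disqualify the query — the external tools are silent
on ties, and disqualification is the deterministic, conservative choice.
`annotation_concordance_filter()` keeps only pairs whose members match the
same protein label (case-folded, whitespace-normalised), the usual guard
against paralog pairings.

For self-contained testing, `score_pairs()` aligns CDS translations
globally (BLOSUM62, gap open 11 / extend 1) and reports raw scores times
0.33 on a bit-score-like scale. This is a desk-scale stand-in for a
translated search, not a search tool: with ~300-codon sequences a true
pair scores ≈ 480–500 on this scale while unrelated 34-codon pairs stay
far below 300, so the conventional threshold separates them cleanly.

`align_pair()` replaces a progressive multiple aligner with what it
reduces to for two sequences: global protein alignment, back-translated
onto codons. Columns containing a gap, stop codon, or ambiguous base are
masked individually; a pair is rejected only when nothing survives. We
chose column masking over whole-pair rejection for isolated internal
stops because the upstream convention ("removal of CDSs with unexpected
stop codons") does not define scope; masking retains information while
still guaranteeing a stop-free alignment, and the masked count is
reported per pair.

`extract_cds()` emits the longest ATG-initiated open reading frame across
all six frames, at a 100-bp minimum which codon granularity makes 102 bp
(matching the convention that observed CDS lengths start at 102 bp). ORFs
containing ambiguous bases are rejected; ties break by frame, then
leftmost start.

## The selection screen and its thresholds

`filter_pairs()` excludes, in order and with one logged reason per pair:
Ks > 0.1 (strict; the standard paralog guard), pairs with all-synonymous
or all-nonsynonymous differences (Sd = 0 or Nd = 0, where the ratio is
degenerate), and saturated/undefined estimates. `classify_selection()`
uses ω > 1 for strong positive selection, 0.5 < ω ≤ 1 for moderate
(closed at 1), ω ≤ 0.5 background.

`summarize_screen()` reports the mean Ka, mean Ks and the mean of
per-pair ω. The mean ratio is deliberately a mean of ratios: reported
transcriptome-wide values in this field (e.g. mean Ka 0.0151, mean Ks
0.0802, mean ratio 0.2111) are mutually inconsistent under a
ratio-of-means reading (0.0151/0.0802 ≈ 0.188), so the per-pair mean is
the only coherent interpretation, and the test suite asserts the
distinction on a heterogeneous fixture.

`substitution_rate()` then converts a mean synonymous distance *d* and a
divergence time *t* into *r* = *d*/(2*t*). With the transcriptome-wide
mean Ks of 0.0802 and a 28.8-Myr split this gives 1.39×10⁻⁹
substitutions/site/year, the package's exactly reproducible worked
example.

## SNP and read screens

`filter_variants()` requires a site to be bi-allelic in both groups,
present in both groups with identical position and alleles (discovery in
two groups acts as technical replication), and to pass depth ≥ 5, minor
allele fraction ≥ 0.20 and quality ≥ 30 *in each group*. These thresholds
are inclusive ("at least"), in contrast to the read-trimming rules, which
are strict by their own wording: N fraction > 5%, Q<5 fraction > 50%,
length < 20 remove a read. Per-group MAF from allelic depths is a
documented choice: the two groups are sequenced as separate pools, so
per-group evidence is the natural unit. Transitions (A↔G, C↔T) and the
four transversion types are counted over unordered ref/alt pairs, and
`snp_density()` reports bases per SNP.

## What the simulator does and does not emulate

The generators cover: codon divergence with known ω, κ and branch length;
paralog contamination (fixed at 0.4 substitutions/site — simulated Ks
≈ 0.73 at the default parameters, far above the 0.1 cutoff, without
saturating the K80 correction); two-group variant tables with
independently assigned rule violations (multi-allelic, depth < 5,
MAF < 20%, quality < 30, group-private), built so that a flagged record
is guaranteed to fail its rule after integer rounding of read counts; and
FASTQ reads with controlled defect rates. All outputs are byte-identical
under a fixed seed.

They do **not** emulate: indels (ortholog pairs are generated
gap-free, so the alignment masking path is exercised by constructed
fixtures, not by the simulator), recombination, among-site rate or ω
variation, alignment error, assembly artifacts, allele-frequency spectra
or linkage in the variant tables, or base-composition bias in reads.
Passing recovery tests therefore demonstrates estimator correctness under
the model's assumptions, not robustness to real-data violations of them.

## Default study conditions

The generator defaults encode the transcriptome-pair regime the package
targets: ω = 0.2 and κ = 2 (typical purifying-selection background and
transition bias), 300 codons per CDS (enough for a true pair to clear the
bit-score threshold of 300 under the internal scorer), and pair
divergence 0.031 nucleotide substitutions/site. The divergence default
was solved analytically — `uniroot` on the matrix-exponential expectation
of the NG86 estimator — so that the expected synonymous divergence equals
0.0802, the observed transcriptome-wide mean Ks of the oyster pair this
emulates; at that regime the Ks > 0.1 cutoff removes paralogs while
retaining the background cohort, which is the property the screen is
meant to have. A nominally attractive alternative (divergence 0.1) would
put implied Ks near 0.2 and make the screen vacuously remove everything,
so it was rejected.

Problem sizes in the shipped tests are chosen for thorough coverage at
interactive runtimes: the recovery grid uses 20 replicates of 10,000
codons per cell; the screen cohort uses 500 background + 20 positive +
100 paralog pairs of 500 codons; the SNP screen 10,000 sites; ortholog
recall 60 pairs of 300 codons. The whole suite runs in about two minutes
on one CPU.

## Known limitations

* The YN-style estimator is an approximate counting method; like its
  relatives it loses accuracy as divergence approaches saturation, and it
  does not model among-site ω variation. Full likelihood codon models are
  out of scope.
* κ̂ from four-fold sites conditions on both codons remaining in the same
  four-fold family, a mild ascertainment bias that grows with divergence.
* `score_pairs()` is quadratic in the number of sequences and intended
  only for fixtures; production inputs should come from a real search
  tool via `read_blast_hits()`.
* The screen reports threshold classifications, not significance tests of
  ω > 1.
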