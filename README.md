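# orthodiverge

Comparative molecular evolution for pairs of transcriptomes: ortholog
identification by reciprocal best hit, codon-level Ka/Ks estimation,
positive-selection screening, neutral substitution-rate calibration, and
post-calling SNP filtering — with a codon-model simulator that generates
every input with known truth, so the whole chain is testable end to end
without external data or search binaries.

## Who it is for

The package targets the common comparative design in non-model systems —
two related species (its motivating case is a pair of *Crassostrea*
oysters with different salinity ecologies), each with an assembled
transcriptome, no reference-quality genomes — where the analysis questions
are: which transcripts are orthologous, which protein-coding genes show
elevated Ka/Ks, and what neutral per-year substitution rate the
synonymous divergence implies.

## The statistics at its core

For an aligned pair of coding sequences, the estimators count synonymous
sites *S* and nonsynonymous sites *N* (each codon position split by its
mutational opportunity), and synonymous/nonsynonymous differences
*S<sub>d</sub>*, *N<sub>d</sub>* by averaging over all stop-free
mutational pathways between differing codons. After multiple-hit
correction,

- **Ks** = corrected *S<sub>d</sub>/S* (synonymous substitutions per
  synonymous site),
- **Ka** = corrected *N<sub>d</sub>/N*,
- **ω = Ka/Ks**, with ω > 1 read as strong positive selection,
  0.5 < ω ≤ 1 moderate, lower values purifying/background.

Two tiers are provided: classic Nei–Gojobori counting with Jukes–Cantor
correction (the enumerable reference), and a Yang–Nielsen-style estimator
(the default) that weights site counts by a four-fold-site estimate of
the transition/transversion ratio κ and by F3x4 codon frequencies, with
Kimura two-parameter corrections. The neutral clock is
**r = d / (2t)** for species separated by time *t*, with *d* the mean Ks
over screened ortholog pairs.

## Worked example

Simulate one diverged ortholog pair with known truth (ω = 0.5, κ = 2,
divergence 0.10 substitutions/site), estimate, then calibrate the clock
with the transcriptome-wide mean synonymous divergence:

```r
library(orthodiverge)

cfg <- sim_config(n_pairs = 1, codons_per_seq = 2000, omega = 0.5,
                  kappa = 2, branch_length = 0.10, seed = 7)
sim <- simulate_ortholog_set(cfg)
aln <- codon_alignment(as.character(sim$fasta_a[[1]]),
                       as.character(sim$fasta_b[[1]]), pair_id = "pair0001")
kaks(aln, method = "yn")
#> Pairwise Ka/Ks estimate (YN)
#>   pair:      pair0001
#>   codons:    2000
#>   sites:     S = 1652.19, N = 4347.81
#>   diffs:     Sd = 228.00, Nd = 330.00
#>   kappa_hat: 1.880
#>   Ka = 0.08008, Ks = 0.1542, Ka/Ks = 0.5192

substitution_rate(d = 0.0802, t_years = 28.8e6)
#> Neutral substitution rate calibration
#>   mean synonymous distance d: 0.0802 substitutions/site
#>   divergence time t:          2.88e+07 years
#>   rate r = d / (2t):          1.39e-09 substitutions/site/year
```

The estimate recovers the generating parameters (ω̂ 0.52 vs true 0.5,
κ̂ 1.88 vs true 2; Ks ≈ 0.15 reflects the faster-than-average synonymous
rate at κ = 2). The clock line is the package's exactly reproducible
headline: mean Ks 0.0802 and a 28.8-Myr split give 1.39×10⁻⁹
substitutions/site/year.

The full chain — simulation, read QC, reciprocal-best-hit orthology with
annotation concordance, codon alignment, Ka/Ks, selection screen, clock,
and the two-group SNP screen — runs from one call:

```r
rep <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
rep$screen_summary     # retention ledger, mean Ka/Ks/ratio, class counts
rep$clock_estimate
rep$snp_summary
```

A thin shell wrapper with the same stages is installed at
`inst/scripts/orthodiverge.R` (`run`, `simulate`, `readqc`, `snps`,
`clock` subcommands).

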