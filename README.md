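# runx2reg

Comparative regulatory analysis of the *RUNX2* locus in modern and archaic
humans, as a tested R package plus a small analysis workflow.

*RUNX2* encodes the master transcription factor of bone development; its
dosage and timing shape skull-suture fusion, and its noncoding regulatory
sequence differs between anatomically modern humans (AMH) and the
Neandertal/Denisovan genomes. `runx2reg` implements the quantitative
machinery needed to study those differences end to end, for researchers in
regulatory genomics and molecular evolution who want each step scriptable
and testable rather than spread across genome browsers, web databases and
instrument software:

- **Variant calling from quality-weighted evidence** (`call_variants`): a
  site is called derived when the single most-weighted non-reference
  allele exceeds a strict threshold of the total quality weight,
  `w(alt) / w(total) > 0.79` by default. Direct allele comparison
  (`diff_sequences`) reports all mismatching positions of pre-aligned
  sequences.
- **Region attribution and lineage polarization** (`annotate_variants`,
  `classify_lineage`): BED-defined promoter/UTR/exon/intron/lncRNA
  intervals (overlaps allowed, e.g. a promoter under an antisense
  lncRNA), plus outgroup-unanimity polarization of each change onto the
  modern or archaic branch.
- **PWM delta scoring** (`build_pwm`, `scan_pwm`, `delta_score`):
  log2-odds position weight matrices with a background-distributed
  pseudocount,
  `score(i,b) = log2(((n_ib + p·bg_b)/(N_i + p)) / bg_b)`, additive over
  motif positions, scanned on both strands; a variant's impact is the
  difference of best window scores between alleles.
- **miRNA seed sites** (`find_seed_sites`, `diff_sites`): canonical
  Watson–Crick 6mer / 7mer-A1 / 7mer-m8 / 8mer matches of miRNA seed
  (nucleotides 2–8) complements in a UTR, and the gain/loss diff between
  two alleles.
- **SPR 1:1 kinetics** (`simulate_sensorgram`, `fit_global_1to1`,
  `fit_steady_state`, `classify_interaction`): closed-form Langmuir
  association `R(t) = Req(1 − e^{−(kon·C+koff)t})` with
  `Req = Rmax·C/(C + KD)` and exponential dissociation; global
  shared-parameter least squares across a concentration series with
  `KD = koff/kon`, a steady-state isotherm fit as fallback, and
  interaction triage (interaction / no interaction / not defined).
- **qPCR relative quantification** (`delta_delta_ct`, `unpaired_t`,
  `pearson_cor`, `trajectory_correlation`): `RQ = 2^−ΔΔCt` against a
  reference gene and a day-0 calibrator, pooled-variance t tests, Pearson
  trajectory correlations.
- **Synthetic data with planted truth** (`sim_config`,
  `simulate_fixture_dir`, `make_*`, `plant_*`): seeded generators for
  every input above, so the whole pipeline runs and is validated without
  archaic genomes, motif databases or instrument files.

## Worked example

The two 36-nt probe alleles of the variable distal 3'UTR region ship with
the package:

```r
library(runx2reg)
probes <- runx2_probe_alleles()
diff_sequences(probes[["AMH"]], probes[["archaic"]])
#>   position base_a base_b
#> 1        8      C      A
#> 2       29      A      G
```

Two substitutions separate the modern from the archaic allele. Fitting a
simulated titration of a 1 µM binder (five two-fold dilutions from 10 µM,
1 RU noise) recovers the planted kinetics:

```r
sg  <- simulate_titration(kon = 1e4, koff = 1e-2, Rmax = 100,
                          noise_sd = 1, seed = 42)
fit_global_1to1(sg)
#> 1:1 kinetic fit over 5 concentrations: kon = 1e+04 1/(M*s), koff = 0.01 1/s, Rmax = 100.0 RU
#>   KD = 1e-06 M (1 uM), RSS = 2.47e+03
```

`KD = koff/kon = 1 µM`: the fitted dissociation constant, the
concentration at which half the immobilized probe is bound. A replicated
qPCR table with a planted fold-change trajectory round-trips through
`2^−ΔΔCt`:

```r
ct <- make_expression_table(default_trajectories()$target, sd = 0, seed = 1)
delta_delta_ct(ct, "RUNX2", "ACTB")$summary$mean_rq
#> [1] 1.0 0.5 1.0 2.0 4.0 4.0
```

## Analysis workflow

`analysis/01_simulate.R` … `analysis/07_report.R` run the full study on a
synthetic fixture directory: input generation, variant calling and region
attribution, motif delta scoring, seed-site diffing, kinetic fitting with
a Table-style interaction summary, expression statistics, and a combined
report. Each writes its tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

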