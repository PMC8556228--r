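---
title: "Methods: comparative regulatory analysis of the RUNX2 locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative regulatory analysis of the RUNX2 locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runx2reg)
```

`runx2reg` re-implements, as reusable and tested code, the chain of
analyses used to compare cis-regulation of the *RUNX2* bone master gene
between anatomically modern humans (AMH) and archaic hominins: which
noncoding positions differ, where in the locus they fall and on which
lineage they arose, whether they move transcription-factor binding
scores, whether they create or destroy miRNA seed sites, how strongly
candidate miRNAs bind each allele (SPR kinetics), and how target and
miRNA expression co-evolve during osteogenic differentiation (qPCR).
This vignette records the models, the parameters that matter, the
numerical choices, and what the synthetic data do and do not establish.

## Variant calling from quality-weighted pileups

A site is called derived when the single most-weighted non-reference
allele has weight fraction strictly greater than a threshold (default
0.79) of the total quality weight at the column. Choices worth stating:

* **Strict inequality.** "Greater than 79%" is read literally: an allele
  at exactly 79% is not called (`tests` pin this boundary).
* **Weights.** Any non-negative reals are accepted; the generators use
  the Phred mapping `w = 1 − 10^(−Q/10)`, so a Q30 read contributes
  0.999 and a Q2 read 0.37. Calls are invariant to rescaling all weights
  in a column — only fractions matter.
* **Ties.** Two non-reference alleles with identical top weight yield no
  call; the site is flagged in the `ties` attribute rather than decided
  arbitrarily.
* **Indels.** A deletion is an observed `-`; an insertion an observed
  `+SEQ` anchored at the left-most base. VCF output left-anchors
  deletions at the preceding reference base, the usual convention.
* **Coordinates.** 0-based half-open internally (BED); 1-based inclusive
  in every report, matching how locus positions are quoted in the
  literature.
* The >79% rule is applied per genome comparison, not to evidence merged
  across archaic genomes; merged application would conflate
  genome-specific coverage differences.

## Region attribution and lineage polarization

Region maps are interval sets with categories (promoters P1/P2, proximal
and distal 3'UTRs, exons, introns, the two antisense lncRNAs,
intergenic). Categories may overlap — the proximal promoter lies under
the antisense lncRNA *AL096865.1* — and a variant receives *all*
covering categories, so per-category counts can sum to more than the
variant count. A single primary category per variant uses the precedence
promoter > UTR > exon > lncRNA > intron > intergenic; this precedence is
a reporting convention of this package, not a biological claim. Bases
inside the locus covered by no interval default to `intergenic`
(attributing them to introns would require gene-model intervals the map
may not carry).

Lineage polarization uses outgroup unanimity: a change is modern-derived
only when the AMH allele differs from both archaics (which agree) *and*
every available primate outgroup carries the archaic allele. Any
disagreeing primate demotes the call to `ambiguous`; with no outgroups
the AMH-vs-archaic polarity is still reported but flagged `unpolarized`.
Unanimity is deliberately conservative — a single discordant outgroup
may reflect lineage sorting or alignment error, and the cost of a false
"modern-specific" label exceeds the cost of an `ambiguous` one.

## PWM scoring and allele deltas

Count matrices become additive log2-odds scores with a
background-distributed pseudocount (default p = 0.1, uniform
background), the convention of the standard motif-occurrence scanners:

$$\mathrm{score}(i,b) = \log_2\frac{(n_{ib} + p\,bg_b)/(N_i + p)}{bg_b}$$

Scores are in bits; the consensus path attains the matrix maximum.
Scanning reports every window at or above a threshold on both strands
(windows containing `N` are skipped; ties order left-most first, `+`
before `−`). A variant's delta is the difference of *best* window scores
within a ±(W−1) context around the variant under each allele — wide
enough that every window overlapping the variant is rescanned, on both
strands, so a substitution that shifts the optimal offset is still
scored correctly. `|Δ| < 10⁻⁹` bits reports `unchanged`. Degenerate
IUPAC strings such as the zinc-finger motif `CCYCCCWCCTC` are matched
literally by a separate operation; degenerate matching and PWM scoring
are different questions (presence vs strength).

Bit-exact reproduction of published matrix scores for specific promoter
substitutions requires the exact matrix version used there, which is not
redistributable here; the package asserts score *directions* on planted
motifs instead, and accepts any MEME-format matrix the user supplies.

## miRNA seed sites

Sites are canonical Watson–Crick complements of the seed (mature miRNA
nucleotides 2–8), in the UTR's sense orientation, T≡U: `6mer` matches
rc(m[2..7]); `7mer-m8` adds the position-8 pair; `7mer-A1` adds a
downstream A; `8mer` both. A locus is keyed by its 6mer core, and
overlapping matches of one miRNA collapse to the most specific type
(site-type hierarchy: every 8mer locus is a 7mer-m8 locus is a 6mer
locus — property-tested). The A1 adenine is recognized by the silencing
complex rather than seed-paired, so `variant_in_seed_region` excludes
it from the seed-matched span. No G:U wobble, no thermodynamic or
context scoring, no conservation filtering — these are stated
limitations, matching the seed-complementarity logic of the standard
target-prediction databases rather than their full context models.
Allele diffs are keyed by (miRNA, core position); a gained or lost locus
must contain a changed position in its 6mer core, which the
implementation asserts internally.

The shipped panel lists the assayed miRNA names with a placeholder
mature-sequence column (sequences are a licensing-encumbered database
asset); only the exogenous spike-in control cel-miR-39-3p, whose
sequence is public, is filled in. Placeholder rows are carried but
skipped in scans.

## SPR kinetics

For a 1:1 interaction at constant analyte concentration the response is
closed-form — association
`R(t) = Req(1 − e^{−(kon C + koff)t})`, `Req = Rmax·C/(C + KD)`,
dissociation `R(t) = R(t_assoc)·e^{−koff(t−t_assoc)}` — so the
simulator integrates no ODE and is exact. Default cycle: 180 s
association, 300 s dissociation, 1 s sampling, five two-fold dilutions
from 10 µM, Gaussian noise added per sample; regeneration between cycles
is modeled only as a response reset. Mass transport, bulk shift and
drift are deliberately omitted (plain 1:1 fitting).

The global fit shares kon, koff, Rmax across all cycles, parameterized
on the log scale (positivity for free), Levenberg–Marquardt from a
12-point multi-start grid (kon ∈ 10^{3..6}, koff ∈ 10^{−3..−1}, Rmax
from the data); `KD = koff/kon` with a delta-method standard error. The
steady-state isotherm fit `Req(C) = Rmax·C/(KD + C)` is the fallback
when kinetics are uninformative, flagging saturation (KD at the zero
boundary) and the weak-affinity linear regime (KD far above the tested
range). Interaction triage: `no_interaction` when the equilibrium
response at the top concentration stays below 3× baseline noise;
`interaction` when a fit converges with SE(KD)/KD < 0.5 and KD within
the tested concentration range ±1 decade; otherwise `not_defined`.
These gates are explicit package conventions standing in for unpublished
instrument-software heuristics; `not_defined` is exactly the state where
signal exists but no model passes.

Noise-free parameter recovery is verified over 27 grid points chosen
inside the kinetically identifiable window of a 180 s/300 s cycle
(kon ∈ [10³, 10⁵] with koff ∈ [10⁻³, 10⁻¹] and KD ∈ 0.5–20 µM, three
Rmax levels). Rate constants outside that window (e.g. koff ≫ 1 s⁻¹)
equilibrate within one sampling interval and leave only the ratio
KD identifiable — an information limit of the cycle design, not of the
optimizer — and are therefore not part of the recovery claim.

## qPCR relative quantification

Per replicate, ΔCt = Ct_target − Ct_reference; ΔΔCt subtracts the
calibrator (day 0) ΔCt; RQ = 2^−ΔΔCt. Two calibration conventions are
implemented: the default subtracts the *mean* calibrator ΔCt, so day-0
replicates scatter around 1 (their geometric mean is exactly 1) and
day-0 error bars exist, matching how differentiation time courses are
usually drawn; `per_replicate_calibration = TRUE` pairs each replicate
with its own day-0 ΔCt, pinning every calibrator RQ at exactly 1.
Summaries report mean ± SD of per-replicate RQs (not 2^−mean ΔΔCt).
Group tests use the pooled-variance Student's t (Welch by flag),
two-tailed, with the usual star mapping at 0.05/0.01/0.001/0.0001;
Pearson correlations take p from `t = r√((n−2)/(1−r²))`. No
multiple-testing correction is applied by default, mirroring common
practice for these figure-style panels; `p.adjust` is one line away for
users who want it. Whether a timepoint is tested against day 0 or
against an undifferentiated control at the same timepoint is an explicit
`contrast` argument, because published time courses are annotated both
ways and the choice changes the null.

## Synthetic data: what it emulates, what it does not

Generators are seeded and emit machine-readable planted truth. Defaults
are the study conditions: five replicates per timepoint over days
0/3/6/10/14/21; replicate noise 0.25 Ct (a typical technical-replicate
spread); pileup quality Phred ≈ N(30, 5) discretized and clamped to
[2, 41]; planted derived-allele fraction 0.9 with 1% read error;
SPR noise 1 RU on Rmax 100. The default target trajectory (1, 0.5, 1,
2, 4, 4) encodes early down-regulation followed by induction, the shape
reported for total *RUNX2* during in vitro osteogenesis; the miRNA
trajectory declines monotonically, so their planted correlation is
negative. Planted-pileup recovery tests use depth 120: at the strict
0.79 boundary the binomial spread of a 0.9-fraction allele at depth ~50
crosses the threshold in a fraction of a percent of sites, so shallow
depths make "recall = 1" a statistical accident rather than a property.

What passing tests show: the calling rule, scanners, fitters and
statistics are correct on inputs whose truth is known, including under
realistic noise. What they do not show: performance on ancient-DNA
artifacts (deamination damage, contamination, alignment error), true
miRNA targeting (seed match is necessary, not sufficient), instrument
artifacts (drift, bulk shifts), or biological effect sizes — none of
which the generators model, by design.

## Sizes and determinism

Test-suite problem sizes (1000 scanner property cases ≤ 200 nt, 300
seed-matcher cases, 27 noise-free + 100 noisy kinetic fits, 200
trajectory seeds) were chosen so the whole suite runs in about a minute
while keeping each property's case count large enough to be meaningful.
All stochastic steps take explicit seeds; the pipeline is deterministic
given its inputs, and reports embed the package version, seed and
thresholds for provenance.
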