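---
title: "Methods: probe-level CNV association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-level CNV association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvgwas)
```

# Overview

`cnvgwas` implements a complete probe-level association pipeline for
microarray-called copy-number variants (CNVs) against binary disease
phenotypes, together with a synthetic-cohort generator that reproduces the
statistical structure such analyses face: rare recurrent variants, heavy
case–control imbalance, near-perfectly correlated proxy probes, and
separation-prone regressions. This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic cohorts do and do not establish about real data.

# From calls to genotypes

A CNV call is one event on one sample: an interval (1-based, inclusive — the
PennCNV convention; a call ending exactly at a probe's position covers that
probe), a type (`DUP`/`DEL`), and a quality score `QS ∈ [−1, 1]` whose sign
encodes the type and whose magnitude encodes call confidence.
`encode_probe_matrix()` retains high-confidence calls (`|QS| > 0.5` by
default, the `qs_cut` parameter) and writes a sparse probe-by-sample matrix
with entries `+1` (probe inside a retained duplication), `−1` (retained
deletion), `0` (no confident CNV). Nested calls can place a retained
duplication *and* deletion of one sample over the same probe; the entry is
then set to `0` with a warning — `0` is the conservative "no confident CNV"
state, and no published convention exists for this corner.

Three derived views feed the four association models (`encode_dosage()`):

| model | dosage of −1 / 0 / +1 | interpretation of β |
|---|---|---|
| mirror | −1 / 0 / +1 | per additional copy |
| ushape | +1 / 0 / +1 | any deviation from copy-neutral |
| duponly | NA / 0 / +1 | per duplication (deletion carriers dropped) |
| delonly | +1 / 0 / NA | per deletion (duplication carriers dropped) |

Type-specific models drop masked carriers from the regression rather than
recoding them to 0: zero-imputation would contaminate the copy-neutral
reference class with carriers of the disregarded type. The `delonly`
encoding codes deletions as `+1` so that every reported effect is "the
effect of carrying the CNV", harmonized across models.

# Probe selection and multiplicity

Probes with cohort CNV frequency below `freq_cut = 1e-4` (0.01%) are
excluded (strict `<`: a single carrier among 9,999 samples is retained).
Remaining probes are pruned by windowed greedy `r²` filtering
(`prune_probes()`: window 500 probes, step 250, threshold
`r² > 0.9999`, the `--indep-pairwise` convention), removing the later probe
by position of each offending pair so the retained proxy is the earliest in
a region — a deterministic tie-break.

Per disease, `prefilter_probes()` admits a probe to testing when a 2×3
genotypic Fisher exact test (rows control/case, columns del/neutral/dup;
two-sided by probability-mass ordering, collapsing to 2×2 when a genotype
class is absent) gives `p ≤ 0.001` and at least two cases carry the
model-relevant CNV class. The Fisher test delegates to `stats::fisher.test`;
the test suite cross-checks it against an independent full-enumeration
hypergeometric oracle on all table sizes up to n = 40.

Correlated probes make a raw Bonferroni correction overly strict, so
`effective_tests()` estimates the effective test count per chromosome as the
smallest number of leading eigenvalues of the probe-correlation matrix
(signed CNV genotypes — the same view the pruning operates on) summing to
`var_frac = 99.5%` of the spectrum, and sums chromosomes. Zero-variance
probes are excluded (contributing 0); a single-probe chromosome contributes
1. The genome-wide threshold is `0.05 / N_eff` and the experiment-wide
threshold further divides by the number of assessed traits
(`gwas_thresholds()`); at the published scale (`N_eff` = 6,633, 61 traits)
these evaluate to 7.5 × 10⁻⁶ and 1.2 × 10⁻⁷.

# Association model

`run_gwas()` fits, per probe, disease status on the encoded dosage plus the
disease-relevant covariates. Covariates are chosen once per disease by a
single joint logistic regression of status on all candidates (age, sex,
genotyping array, principal components), retaining those with `p ≤ 0.05`
(`select_covariates()`); a joint model is used rather than univariable
screens because the covariates are themselves correlated.

The fitter (`firth_logistic()`) runs Newton–Raphson maximum likelihood
(tolerance 1e−8, 100 iterations) and falls back to Firth's Jeffreys-prior
penalized likelihood when any of three deterministic triggers fires: ML
non-convergence, any `|β| > 10`, or an empty cell in the
exposure-by-outcome table of the focal dosage (an explicit separation
check — PLINK's firth-fallback triggers only on non-convergence, which is
implementation-dependent; the cell check makes behavior reproducible).
The Firth iteration maximizes the penalized likelihood
`ℓ(β) + ½ log det I(β)` with the modified score
`Σ xᵢ (yᵢ − pᵢ + hᵢ(½ − pᵢ))` and step-halving. P-values are Wald on the
dosage column, matching an odds-ratio-with-95%-CI reporting style.
Rank-deficient designs drop collinear columns deterministically, preferring
earlier columns; the focal dosage is placed last so that a dosage absorbed
by a conditioned lead reports `NA` rather than silently displacing the
conditioning term.

Independent signals per disease and model are isolated by
`stepwise_conditional()`: take the most significant probe at the genome-wide
threshold as a lead, add its numeric dosage as a covariate, rescan, repeat
until nothing passes (guarded at 20 rounds). The quantitative disease-burden
phenotype (diagnosis count across the panel) uses the same machinery with
ordinary least squares (`run_burden_gwas()`).

# Regions, tiers, replication, BMI

`define_cnvr()` spans the most distant probes within ±3 Mb of a lead with
`r² ≥ 0.5` against the lead genotype (U-shape signals correlate `|g|`, the
U-shape dosage). Overlapping regions (≥ 1 bp, inclusive coordinates — two
regions sharing a single base merge; abutting ones do not) merge
transitively into maximal CNV regions (`merge_cnvrs()`, via `IRanges`).
Among an association's significant models the *best* model is the lowest-p
one; the *main* model is the type-specific model when exactly one of
duplication-only/deletion-only is significant (both being significant is
flagged for review), else the best model. Gene counts use ≥ 1 bp interval
overlap; transcript-aware exonic annotation is out of scope and the count is
descriptive only.

Three post-hoc statistics validate each signal at `p ≤ 1e-4`
(`tier_alpha`): the genotypic Fisher test; a residual regression (response
residuals `y − p̂` of the covariate-only logistic model, regressed on each
significant encoding by OLS with homoskedastic Wald inference — response
residuals are used as stated, not deviance or Pearson residuals, and the
lattice structure of two-valued residuals is why the test suite checks
calibration by rejection rate rather than a KS statistic); and a Cox
proportional-hazards model of age at last healthy measurement (cases: age at
diagnosis, the earliest inclusion-code date minus the birth date imputed to
the 15th of the birth month, divided by 365.25; controls: administrative
cutoff 2021-09-30 minus birth date) with Efron tie handling. Passing 3/2/1
of the three yields tier 1/2/3; disease-burden signals are tier 1
unconditionally since quantitative outcomes do not suffer the binary-trait
caveats. A signal passing none is demoted with a warning rather than
silently dropped.

Replication (`replicate_signals()`) matches each lead to the closest
successful replication probe (ties toward the smaller position) and adjusts
two-sided p-values for directional concordance: `p/2` on matching effect
signs, `1 − p/2` otherwise — exactly the one-sided construction, with no
separate one-sided fit. Enrichment over the grid α = 0.1 … 0.005 (step
0.005) is `k/(n·α)`-fold with a one-sided binomial tail
(`replication_enrichment()`).

The BMI-confounding analysis (`bmi_confounding()`) tests eligibility
(BMI–disease at `0.05/n_traits`; dosage–BMI at `0.05/n_signals`, on
inverse-normal-transformed, covariate-residualized BMI), refits the primary
model with BMI as a covariate, and compares coefficients with
`z = (b₁ − b₂)/√(se₁² + se₂²)` against a standard normal — the standard
coefficient-comparison form for a test the source describes only as a
two-sided t-test; assuming independence of the two estimates is
conservative here because they are positively correlated. A signal is
*likely BMI-driven* when the adjusted dosage p no longer meets the
genome-wide threshold. The rank-based inverse normal transform is
`Φ⁻¹((rank − ½)/n)` with average ranks on ties.

# CNV burden

`compute_burden()` yields six metrics per sample: Mb and distinct-gene
counts for deletions, duplications, and their sum. Lengths use
`end − start + 1` (1-based inclusive); a gene hit by two calls of one type
counts once (a property of the genome covered, and double-counting would be
order-dependent), and the CNV gene burden is defined as duplication genes
plus deletion genes so the six-metric identity `cnv = dup + del` holds in
both units. Partitioned burdens (`subset_corrected_burden()`) split each
metric into the part overlapping a genomic partition (either ≥ 1 bp or
reciprocal-50% overlap: the intersection strictly exceeds half of *both*
intervals) and the remainder, with `subset + corrected = total` exact by
construction. A call straddling two partitions contributes to both subset
burdens — exclusivity is deliberately not imposed, and runs log it.
Signal-corrected burdens (`signal_corrected_burden()`) omit calls
overlapping a disease-associated region in a disease- and type-specific
fashion (mirror/U-shape associations remove both types, type-specific ones
only their own). `burden_association()` reports the covariate-adjusted
effect and a covariate-free variance explained: McFadden pseudo-R² for
diseases, adjusted R² for the disease burden.

# The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised; its defaults are fixed once and are not tuned per test.

* **Loci** carry duplication and deletion frequencies in [0, 0.05]
  (rare recurrent CNVs; the published frequency range is 0.01–0.5% and test
  fixtures use 0.4–2% to keep carrier counts informative at simulation
  scale). Each sample carries at most one CNV per locus; breakpoints come
  from weighted categories, with a 5% atypical fraction drawn uniformly
  within the locus — mirroring the recurrent-majority/atypical-minority
  structure seen at real rearrangement hotspots. Overlapping loci on one
  chromosome are rejected at construction.
* **Quality scores**: a `qs_noise` fraction of calls (default 20%) receives
  `|QS| ≤ 0.5` and is removed by the default filter. The real per-locus
  fraction of low-quality calls is not published; 20% is a free parameter
  chosen as a plausible mid-range value.
* **Covariates**: age ~ U(40, 70), sex ~ Bernoulli(0.54), array ~
  Bernoulli(0.1), PCs ~ N(0, 1) — loose matches to a middle-aged volunteer
  cohort, all configurable via `covariate_spec()`.
* **Disease**: logistic liability with an intercept calibrated by
  root-finding so the realized prevalence matches the target; CNV effects
  act on the encoded dosage of the specified mechanism. An optional
  mediation path shifts standardized BMI by `bmi_shift` per dosage unit and
  feeds it into the liability with `bmi_beta`.
* **Onset**: Weibull proportional hazards, shape 4, scale calibrated so the
  median onset is ≈ 65 years (right-skewed, late-onset); per-sample hazard
  scaled by `hazard_ratio^dosage`. Controls are censored at their current
  age. A 5% fraction of controls is relabeled `excluded` to emulate
  exclusion-list screening.
* **Seeds**: one master seed; each stage derives a child seed from the
  stage name (`child_seed()`, a polynomial string hash modulo 2³¹ − 1), so
  fixed seeds give byte-identical artifacts and stages are independently
  reproducible.
* **Replication cohorts** multiply every effect by an attenuation factor
  and thin the probe map systematically (every k-th probe), which emulates a
  sparser platform while guaranteeing each locus keeps a proxy when the
  original map has at least 1/fraction probes per locus.

What the synthetic cohorts do **not** emulate: raw intensity data and the
calling step itself, relatedness and ancestry structure beyond PC
covariates, real ICD-10 ontology complexity beyond prefix/subcode matching,
linkage between CNVs and flanking SNPs, and locus-specific quality-score
distributions. Tests passing on synthetic cohorts therefore establish the
statistical correctness of the machinery — encodings, fallback triggers,
threshold arithmetic, conditional logic, burden algebra, calibration and
power at the simulated effect sizes — not robustness to real-data artifacts
such as batch-correlated call quality or population stratification.

# Numerical choices and problem sizes

* ML tolerance 1e−8, 100 iterations; Firth iterations capped at 200 with
  step-halving down to 1/16,384 of the Newton step.
* Fisher tests collapse to 2×2 on a zero column margin; p-values use the
  exact-test probability-mass ordering with `fisher.test`'s relative tie
  tolerance.
* Eigenvalues are clipped at zero before the cumulative-fraction cut.
* Degenerate inputs fail loudly: constant outcomes, zero-variance burdens,
  saturated covariate models, diagnoses before birth, births after the
  censoring cutoff, and genotypes outside {−1, 0, +1} are all errors, not
  silent NAs.
* The test suite runs its statistical properties at deliberately moderate
  sizes — cohorts of 2,000–20,000 for calibration loops, n = 100,000 for
  the parameter-recovery and mediation checks, 100 runs for the Cox
  hazard-ratio recovery, 20 runs for the global-null type-I sweep — chosen
  as the smallest sizes at which the binomial/KS envelopes used by the
  assertions are meaningfully tight.

# Known limitations

* The residual-regression p-value uses homoskedastic OLS inference on
  two-valued residuals; it is well calibrated in rejection rate at the
  carrier counts tested but its finite-sample distribution is lattice-like.
* The coefficient-change z-test in the BMI analysis assumes independent
  estimates and is conservative.
* Missing covariate values are handled complete-case per disease in the
  covariate-selection regression; no imputation is attempted.
* Gene counting is interval-overlap based, not transcript-aware; counts at
  region boundaries can differ from exonic annotation.
* `run_pipeline()` floors the effective-test count at 1 so that empty or
  degenerate matrices yield a clean zero-signal run rather than an error.
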