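---
title: "Genome-wide aneuploidy scoring for cell-free DNA: models and design"
author: "aneuscore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide aneuploidy scoring for cell-free DNA: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the score

Plasma cell-free DNA (cfDNA) of a cancer patient is a mixture of normal
and tumor-derived fragments. LINE-1 retrotransposons are scattered across
the genome, so a single-primer LINE-1 amplicon library sequenced shallowly
(tens of thousands of reads) yields read counts per chromosome arm whose
relative abundances shift when the tumor fraction `f` and the tumor's
arm-level copy numbers deviate from the diploid male background. The
package turns such counts into a genome-wide aneuploidy (GWA) score:

1. **Arm model.** Arms are derived from cytoband annotations: the p arm
   runs from the telomere to the first centromeric (`acen`) band, the q
   arm from the last `acen` band to the chromosome end; reads inside the
   centromeric gap belong to no arm and are discarded rather than imputed.
   The short arms of chromosomes 13, 14, 15, 21 and 22 (acrocentric,
   LINE-1-poor) and both chrY arms are excluded, leaving 41 scored arms on
   chr1-22 and chrX. chrX stays in because the assay reports Xq signal
   (AR amplification territory) and both the control cohort and the
   intended patients are male, so ploidy matches.
2. **QC.** A sample must reach 90,000 reads over included arms
   (boundary inclusive). The floor is configurable; the default follows
   the assay's design depth.
3. **Normalization.** Counts are divided by the included-arm library
   size, giving fractions `p_a` that sum to 1. The score is therefore
   invariant to sequencing depth re-scaling.
4. **Z-scores.** Against a healthy male control cohort (n = 17 by
   default), `z_a = (p_a - mu_a) / sigma_a` with `mu_a`, `sigma_a` the
   per-arm control mean and SD (denominator n-1).
5. **GWA score.** `S = sum(z_a^2)` over the 41 arms. The published
   dichotomization cutoff is 5, which cannot apply to the raw sum (its
   null expectation is about the number of arms, 41), so the default
   score is `GWA = (S - mu_S) / sigma_S`, standardized against the
   control distribution of `S`; a `raw` mode is retained for inspection.
   Samples with `GWA >= 5` are `high`, below 5 `low` (boundary is high).
6. **Dynamics.** With baseline (BL) and early on-treatment (ET)
   timepoints, patients are `GWAlow` (low/low), `GWAhigh` (high/high) or
   `GWAswitch` (discordant, either direction).

### Leave-one-out control S statistics

`mu_S` and `sigma_S` are estimated by scoring each control against a
reference built from the remaining 16 controls. Resubstitution (scoring a
control against statistics that include itself) shrinks the apparent null
spread of `S` markedly at n = 17 and would inflate standardized scores for
new samples. With leave-one-out statistics, held-out control samples score
near mean 0, SD 1.

Calibration is a property of the *procedure*, not of one reference draw: a
single 17-control reference carries sampling error in `mu_S` of roughly
`sigma_S / sqrt(17)`, so the mean standardized score of samples scored
against one fixed reference jitters with SD near 0.24 around 0. The test
suite therefore checks calibration across many independent reference
draws; against a single reference only the wider behavior (SD, tail mass
above 5) is meaningful.

### The SD floor

Per-arm SDs are floored at 10% of the control mean fraction of the
smallest included arm (a single global value). The floor exists to keep
low-variance arms from exploding the Z-scores; at the generator's default
overdispersion (arm-fraction CV near 3%) it also binds on the smallest
arms (e.g. 17p, 18p), shrinking their Z-scores below unit variance. This
is deliberate and harmless for calibration because the leave-one-out `S`
statistics apply the same floor — it costs a little sensitivity on the
smallest arms and buys robustness against degenerate references (for
example, identical control profiles floor every arm and yield `sigma_S =
0`, which the scorer refuses in standardized mode).

## Tissue concordance

Tissue copy-number segments (purity-adjusted total copy number, as
produced by WGS CN callers) are aggregated per arm by the length-weighted
mean over segment-arm intersections — the simplest aggregator consistent
with an arm-level deviation estimate; arms with less than 50% segment
coverage are flagged missing. Arm values become
`log2(max(cn, 0.1) / expected)` with expected copy number 2 for autosomes
and 1 for chrX (male); the 0.1-copy floor bounds the log for homozygous
deletions. Per-sample concordance with the cfDNA arm Z-scores is
Spearman's rank correlation with average ranks for ties.

A structural note: an integer-copy-number tumor profile ties whole groups
of arms (all single-copy losses sit at log2 = -1, all unaltered arms at
0). Under average ranks those ties cap Spearman's rho strictly below 1
even with noise-free tissue and unbounded sequencing depth — for the
default high-aneuploidy preset the ceiling is about 0.9. "Concordance
approaches 1" therefore means "approaches the tie-capped ceiling".

## Survival models

Failure-free survival (ARSI: start of treatment to end of that treatment)
and time to next treatment (taxanes: start to next line, best supportive
care or death) both enter the estimators as `(time, event)` pairs;
endpoint semantics live in the records, not the estimators. The package
wraps the `survival` package: product-limit (Kaplan-Meier) curves with the
median defined as the earliest time at which survival reaches 0.5 or
below; log-rank tests with a chi-square reference; and Cox proportional
hazards with the Efron tie approximation (no tie method is canonical for
this design; Efron is the least biased common default) and Wald 95% CIs
and p-values, matching the "HR (95% CI), P" reporting shape.

The interaction model codes a taxane-treated GWA-low patient as the
reference and fits three terms: `treatmentARSI`, `gwaHigh` and their
product. The dynamics model fits `GWAswitch` and `GWAhigh` dummies against
the `GWAlow` reference. Fits refuse empty strata by name, flag suspected
complete separation (diverging log-HR) instead of returning garbage, and
warn on single-record groups. Patients appearing in several treatment
lines are treated as independent records — a simplification the models
inherit from the study design, flagged here as a limitation.

## Digital PCR

Partition counts are Poisson-corrected: `lambda = -ln(1 - k/n)` mean
copies per partition for `k` positive of `n` partitions; a saturated well
is an error (no information), an all-negative well is a valid zero. The
AR/AGO1 copy-number ratio is the ratio of Poisson concentrations (equal
partition volumes cancel), with a 95% CI from the delta method on the log
ratio, propagating each well's binomial uncertainty — standard dPCR
practice in the absence of a stated uncertainty model. AGO1 is a diploid
autosomal reference (1p34.3) while AR sits on the single male X, so an
unamplified male sample has an expected raw ratio near 0.5; the package
reports the raw lambda ratio and leaves renormalization to 1 (if desired)
to the analyst, documenting the baseline explicitly because published
ratios do not state which convention they use.

## The synthetic-data generator

The cohort that motivated this package is restricted-access; the
generator replaces it with a stated world whose structure mirrors the
analysis assumptions:

* **Counts.** Arm counts are Dirichlet-multinomial draws with expected
  arm mass `w_a * ((1-f) * N_a + f * T_a)`: LINE-1 weight `w_a` times the
  copy number of a `(1-f):f` mixture of normal male (`N_a`: 2 autosomal,
  1 chrX) and tumor (`T_a`) genomes. `f = 0` reduces exactly to the
  control model. Weights default to arm length — the true per-arm LINE-1
  amplicon densities are not published, so weights are a config-level
  stand-in. Excluded arms are simulated with zero counts; the generator
  does not emulate off-target or residual acrocentric reads.
* **Overdispersion.** Real amplicon libraries are noisier than a pure
  multinomial. The Dirichlet concentration defaults to 1e5, which at the
  default depth of 100,000 reads doubles the multinomial fraction
  variance (arm-fraction CV near 3%). No distributional facts about the
  assay's dispersion are published; this is a modeling choice, exposed
  for sensitivity testing, chosen so that technical replicates of a
  healthy sample vary at the few-percent level per arm, as a
  well-behaved amplicon assay should.
* **Tumor preset.** `prostate_high` is a heavily aneuploid mCRPC genome:
  11 single-copy arm losses (2q, 4p, 5q, 6q, 8p, 10q, 12p, 13q, 16q,
  17p, 18q), 7 broad gains (1q, 2p, 3q, 5p, 7p, 7q, 20q at 3 copies) and
  high-level gains of 8q and Xq (4 copies; Xq models AR amplification on
  the 1-copy male X). About half the arms are altered, consistent with
  the elevated ploidy, whole-genome duplication and structural-variant
  burden that characterize high-aneuploidy mCRPC tumors; a genome this
  extensively altered is also what makes per-sample tissue-cfDNA rank
  concordance uniformly high, as observed in matched cohorts.
* **Tumor fraction mixture.** Baseline `f` is drawn half from
  `U(0, 0.05)` (low burden) and half from `U(0.15, 0.60)` (detectable
  burden), echoing the roughly 48% GWA-high prevalence reported at
  baseline in mCRPC. The two components sit deliberately away from the
  `f = 0.10` decision boundary so that the generated "true status"
  (`f >= 0.10`) is recoverable from counts; boundary behavior is probed
  separately by the threshold and monotonicity properties. At the early
  timepoint, responders (probability 0.5) have `f` multiplied by a
  `U(0, 0.3)` draw and non-responders keep their baseline `f` — this
  yields a switch group that is almost exclusively high-to-low, the
  pattern reported in longitudinal cohorts.
* **Outcomes.** Event times are exponential with
  `log h = log h0 + bTrt * I[ARSI] + bGwa * I[high] + bInt * I[ARSI &
  high]`, defaults `h0 = 1/400` per day (median survival near the
  reported GWA-low ARSI median), `bTrt = log 2.36`, `bGwa = log 1.08`,
  `bInt = log 2.58` — the reported interaction structure, under which
  the implied GWA effect within ARSI is `1.08 * 2.58 = 2.79`, close to
  the reported single-stratum estimate. Censoring is administrative at a
  cutoff solved numerically to give the target censoring fraction
  (default 20%).
* **Reproducibility.** Everything derives from `(config, seed)`; helper
  seeds are derived arithmetically and stay inside 32-bit range. The
  truth table (f values, true statuses, true betas, censoring cutoff) is
  emitted alongside so downstream estimates can be scored without
  reaching into generator internals.

### What a green test does and does not establish

The generator emulates the *statistical* structure the analysis assumes:
compositional counts with overdispersion, arm-level mixture shifts,
noisy segment tables, binomial dPCR wells, proportional hazards with an
interaction. It does not emulate GC or mappability bias, fragment-length
effects, the real (unpublished) LINE-1 density per arm, correlated
technical noise across arms, sub-arm CNA structure, non-proportional
hazards, or informative censoring. Green properties establish that the
implementation is internally correct and calibrated under the stated
world — not that the assay's clinical performance is reproduced.

## Numerical and interface choices

* Arm intervals are half-open in all external formats (BED, cytoband,
  segment tables; 0-based) and closed 1-based `GRanges` internally; a
  read exactly at an arm's (0-based) end coordinate belongs to the next
  interval, and reads are assigned by leftmost aligned position, the
  deterministic convention for single-end reads.
* `min_mapq` defaults to 30: LINE-1-derived amplicons demand confident
  placement; the rule (like duplicate handling) is not published, so it
  is configurable and documented as a choice.
* No outlier trimming or iterative curation is applied to control
  estimates; whether the original pipeline trimmed is unstated, and
  trimming would complicate the leave-one-out S statistics.
* The GWA threshold comparison is `>=` (a score exactly 5 is high); the
  QC comparison is `>=` (exactly 90,000 reads pass).
* Ties in concordance use average ranks; ties in Cox fits use Efron's
  approximation; the KM median uses the earliest-crossing convention.
* Counts on excluded arms are preserved in every container and output
  for auditability but never enter normalization, scoring or totals.

## Known limitations

* Absolute tumor-fraction estimation is out of scope; only the
  qualitative link between `GWA >= 5` and `f` above roughly 10% is
  modeled and tested.
* The control cohort size (17) bounds how well `sigma_S` can be
  estimated; single-reference scores carry that uncertainty.
* Multivariable adjustment (PSA, ECOG, metastatic burden) is absent, as
  in the motivating design.
* The dPCR module starts from partition summaries; droplet gating and
  fluorescence thresholds are upstream of this package.
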