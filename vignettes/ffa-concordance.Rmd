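---
title: "Scoring cross-species concordance of free fatty acid profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cross-species concordance of free fatty acid profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffaconcord)
```

## The problem

Animal models of depression are validated behaviorally, but a model that
reproduces a patient cohort's *molecular* signature is more useful for
mechanistic and pharmacological work. Given targeted GC-MS panels of free
fatty acids (FFAs, quantified in µg/mL) from a human case-control cohort
and from two or more mouse models (each with its own control group), the
question is: **which model's FFA profile lies closest to the patients'?**

The difficulty is that raw concentrations are not commensurable across
species, instruments or batches. `ffaconcord` answers the question with a
chain of two standardizations and a geometric summary:

1. **z-score.** Within each species, every sample is standardized per
   analyte against that species' *control* population:
   \( z = (x - \bar{x}_{\mathrm{ctl}}) / s_{\mathrm{ctl}} \),
   with the sample SD (n − 1). Control z-scores have mean 0 and SD 1 per
   analyte by construction.
2. **S-score.** Each model animal's z-score is then located within the
   *patient* cohort's z-score distribution:
   \( s = (z_{\mathrm{animal}} - \bar{z}_{\mathrm{pat}}) / s_{z,\mathrm{pat}} \).
   An s of 0 means the animal sits exactly at the patient mean for that
   analyte; |s| measures divergence from the patient profile in units of
   patient variability.
3. **AERC.** Per animal, the |s| values are placed on k equally spaced
   radar axes (one per analyte) and the enclosed polygon area
   \( \tfrac{1}{2}\sin(2\pi/k)\sum_i r_i r_{i+1} \) (indices cyclic)
   summarizes whole-panel deviation in one number. Models are ranked by
   the mean AERC of their treated animals — smaller is closer to the
   patients.

Around this core, the package reproduces the supporting statistical layer
of such a study: Shapiro-Wilk-gated test selection per analyte (Welch
t-test when both groups screen normal, Mann-Whitney otherwise),
chi-square and Kruskal-Wallis tests for demographics, linear-model
covariate adjustment, and behavioral endpoints (forced swim immobility,
sucrose preference, social interaction).

## Design choices where the method is underdetermined

Several details of the scoring chain are not fixed by the informal
description above; the package makes them explicit, deterministic and
recorded in every output.

**S-score input.** The statistic is described verbally as using an
"individual's raw value", but a mouse's raw concentration has no place in
a distribution of human z-scores. The default therefore standardizes the
animal against its own species' control group first and applies the
formula to that z-score, which makes the statistic invariant to any
consistent within-species unit change (a property the tests verify). The
literal raw-value reading remains available via `sscore(..., input =
"raw")` for auditability.

**Radius transform.** S-scores can be negative; polygon radii cannot. The
default transform is `abs` — |s| reads as "distance from the patient
mean", consistent with values near zero indicating alignment —
with `shift_min` and `clip_zero` as alternatives. The transform used is
attached to every `aerc()` result. Note the three transforms are *not*
equivalent and AERC is *not* invariant to axis order; whenever an area is
reported, the order and transform that produced it are reported with it.

**Axis order.** Radar axis order defaults to a canonical, reproducible
rule: ascending carbon count, then double-bond count, then suffix
(`order_panel()`). Any explicit order can be supplied and is echoed back
in the result.

**Test selection.** The normality gate is per-group Shapiro-Wilk at
α = 0.05; both groups must pass for the t branch. Welch's unequal-variance
t-test is the parametric default (`var_equal = TRUE` gives Student's).
The Mann-Whitney branch enumerates exactly when both groups have ≤ 8
observations and no ties, and otherwise uses the tie-corrected normal
approximation without continuity correction. No multiple-testing
correction is applied by default, mirroring the single-analyte reporting
convention of this literature; `adjust = "BH"` reports
Benjamini-Hochberg-adjusted p-values alongside.

**Chi-square.** Pearson's statistic without Yates continuity correction is
the default (`correct = TRUE` restores it): on a 2×2 sex-by-group table
with marginal-consistent counts this reproduces the published statistic to
3 decimals. `check_count_consistency()` flags printed cells that
contradict their own published totals instead of silently fixing them.

**Missing data.** Analytes missing in more than 20% of any group's samples
are dropped (logged); remaining missing values are excluded pairwise per
analyte. Analytes with zero reference-group SD are dropped from *both*
species' panels so the polygons stay comparable.

## The synthetic cohort generator

Real panels of this kind live in supplementary spreadsheets without a
public accession, so the package ships a first-class generator that
emulates their statistical structure and makes every downstream stage
testable offline:

- **Log-normal concentrations.** Per analyte,
  \( x = \exp(\mu + \beta^\top c + \varepsilon) \),
  \( \varepsilon \sim N(0, \sigma) \). Concentrations are strictly
  positive and the default 26-analyte panel (`ffa_panel()`) spans about
  three orders of magnitude (log-means −2 to 5.8, log-SDs 0.3–0.6),
  matching the character of targeted FFA GC-MS panels.
- **Multiplicative case effect.** The case group's concentrations are
  multiplied by a per-analyte fold change (additive on the log scale),
  mostly < 1: a general down-regulation, strongest for C16:1, C18:2n6c,
  C19:0, C15:0, C17:0 and C9:0. The fold change acts exactly on the
  median, which the tests verify at n = 10,000 within 2%.
- **Covariates.** Human cohorts draw sex ~ Bernoulli(0.5), age ~
  N(14.7, 1.9) and education ~ N(8.9, 1.8) years (an adolescent cohort);
  optional coefficients add covariate effects on the log scale so the
  adjustment stage can be exercised and recovered.
- **Fidelity scenarios.** `simulate_concordance_scenario()` builds a human
  cohort plus one mouse cohort per model in which a fraction *fidelity* of
  analytes inherit the human fold change (a seeded random subset) and the
  rest are null. The ground-truth fold-change vectors are returned, which
  turns "does the pipeline rank the truer model first?" into a measurable
  parameter-recovery experiment.
- **Determinism.** One integer seed governs everything; per-stream
  sub-seeds (human, each model's subset and cohort, behavior) are derived
  from it, so identical configs give bit-identical tables.

What the generator does **not** emulate: instrument noise, detection
limits and censoring, between-batch drift, correlated analytes (draws are
independent across analytes given covariates), or non-log-normal tails.
Green tests therefore demonstrate internal correctness and statistical
behavior under the stated model, not performance on any particular real
dataset.

## Calibration and recovery: the problem sizes used

Two simulation studies back the statistical layer; their sizes were chosen
to give tight Monte-Carlo error while staying desk-scale.

**Type-I error of the auto-selected test.** 10,000 null replicates at
n = 6 per group, under a N(0,1) null and under log-normal nulls drawn from
the generator's own default panel parameters (cycling the 26 analytes'
log-means and log-SDs). Measured levels are ≈ 0.047 (normal) and ≈ 0.042
(log-normal). The procedure is intrinsically a little conservative at
n = 6: the exact Mann-Whitney branch is discrete (largest attainable
two-sided size 0.0411 at 6/6) and the two-sided t-test loses a little
level under skew. At strong skew (log-SD ≥ 1) the level drifts to ≈ 0.036
— worth knowing if the package is applied to much noisier analytes than
the default panel models.

**Ranking recovery.** 200 replicates of a fidelity-0.8 vs fidelity-0.2
scenario with uniform patient fold change 0.5, human cohorts of 88/116 and
6 + 6 mice per model: the pipeline ranks the truer model first in ≈ 98% of
replicates. At the generator's default *mild* fold changes (0.65–1.0) the
same comparison is underpowered at n = 6 — a single replicate ranks the
truer model first only about two-thirds of the time — which is exactly why
conclusions at this sample size should rest on effect sizes of the
patient-cohort scale, and why the acceptance report averages that scenario
over replicates.

## A worked run

```{r demo}
demo <- make_demo(file.path(tempdir(), "ffa_demo"), seed = 1)
fit <- ffa_concord(demo$human, demo$models,
                   human_groups = c("HC", "alMDD"))
fit
summary(fit)
```

The same analysis runs from files and a config via `run_pipeline()`, which
writes every stage table (z-scores, s-scores, per-analyte comparisons,
AERC, radar vertex coordinates for plotting) plus a manifest; identical
config and seed give a byte-identical bundle.

```{r pipeline, eval = FALSE}
run_pipeline(demo$config_path)
```

## Known limitations

- AERC depends on axis order and on the radius transform; areas are only
  comparable between cohorts scored with the same panel, order and
  transform (the package enforces and records this, but cross-study
  comparisons of absolute areas remain fragile).
- The S-score compares location only; a model matching the patient mean
  with wildly wrong dispersion still scores well per analyte.
- Per-analyte tests are marginal; with 26 correlated analytes and no
  default multiplicity correction, significance counts are descriptive,
  not inferential.
- n = 6 animals per group — the field's norm for blood collection — gives
  the ranking little power at small effect sizes (see above).
- XLSX workbooks are not read directly; export sheets to CSV first.
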