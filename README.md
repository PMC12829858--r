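# ffaconcord

Cross-species concordance scoring of free fatty acid (FFA) profiles.

## What it is for

Targeted GC-MS panels quantify ~26 circulating free fatty acids (µg/mL)
in a human case-control cohort (e.g. adolescent MDD patients vs healthy
controls) and in mouse depression models (e.g. LPS-injected vs saline,
chronic social defeat vs control). `ffaconcord` answers the question
*which animal model best recapitulates the patients' FFA signature?* for
researchers running such panel studies, and ships a log-normal synthetic
cohort generator so every stage is testable without any private data.

## The method

With per-analyte control mean \(\bar x_{ctl}\) and sample SD \(s_{ctl}\):

- **z-score** (within species):
  \(z = (x - \bar x_{ctl}) / s_{ctl}\); control z-scores have mean 0,
  SD 1 per analyte by construction.
- **S-score** (across species): each model animal's z-score is located in
  the patient cohort's z-score distribution,
  \(s = (z_{animal} - \bar z_{pat}) / s_{z,pat}\).
  s = 0 means the animal sits at the patient mean; |s| is divergence in
  units of patient variability.
- **AERC** (area enclosed by the radar chart): the animal's |s| values on
  k equally spaced axes enclose the polygon area
  \(\tfrac12 \sin(2\pi/k) \sum_i r_i r_{i+1}\) (cyclic);
  models are ranked by mean AERC of their treated animals, smaller =
  closer to the patient profile.

Supporting layers: Shapiro-Wilk-gated per-analyte tests (Welch t /
Mann-Whitney with exact small-sample enumeration), chi-square and
Kruskal-Wallis demographics, linear-model covariate adjustment,
behavioral endpoints (immobility, sucrose preference), and CSV/TSV I/O
with fatty-acid-name normalization ("nonanoic acid" → `C9:0`).

## Worked example

```r
library(ffaconcord)

demo <- make_demo(seed = 1)   # writes a documented synthetic dataset
fit  <- ffa_concord(demo$human, demo$models, human_groups = c("HC", "alMDD"))
fit
```

```
Cross-species FFA concordance analysis
  shared panel: 26 analytes
  human cohort: alMDD vs HC (9 significant analytes at alpha = 0.05)
  models ranked by mean_aerc (radius transform: abs):
    1. LPS_like     mean AERC 3.434   mean |s| 0.979
    2. CSDS_like    mean AERC 4.105   mean |s| 1.163
```

The demo scenario generates 30 controls / 40 patients and two 6 + 6 mouse
models, with the `LPS_like` model inheriting 90% of the patient fold
changes and `CSDS_like` 10%. The output reads: 9 of 26 analytes are
significantly lower in the synthetic patients; the `LPS_like` model's
animals enclose the smaller mean radar area (3.43 vs 4.11) and the
smaller mean |s| (0.98 vs 1.16), so it is ranked the closer match to the
patient profile — recovering the known ground truth. `summary(fit)` adds
per-model significant-analyte counts and SEMs; `plot(fit)` draws the mean
|s| radar.

The same analysis runs from CSV files and a YAML/JSON config:

```r
run_pipeline(demo$config_path)   # writes z-/s-score tables, AERC, ranking, manifest
```

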