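# oudcontrols

Control-definition comparison for EHR-based opioid use disorder (OUD)
association studies.

## The problem

In electronic-health-record (EHR) case–control studies of OUD, the
control group is usually "anyone without an OUD diagnosis code". But
opioid exposure is a prerequisite for the disorder, and such *generic*
controls mix never-exposed patients with patients who took prescription
opioids uneventfully. An alternative restricts controls to patients with
documented **minimal opioid exposure** — at least two opioid
prescriptions no more than 90 days apart, no third prescription within 9
months of the second, and no chronic-use pattern (three prescriptions
with consecutive gaps under 90 days). The two definitions imply different
comparisons, and the choice propagates into comorbidity profiles
(PheWAS), genetic associations, and effect-size calibration.

`oudcontrols` implements both definitions as tested phenotyping
algorithms and everything needed to measure their consequences:

* **Cohort builder** — OUD case rule, a medical-home data floor (≥5 ICD
  codes on distinct days within a sliding 3-year window), cancer and
  under-18 exclusions, and the temporal prescription-pattern classifier
  (`unexposed` / `single_rx` / `minimal` / `chronic_pattern` / `other`),
  verified against a brute-force enumeration of the rules.
* **Phecode mapper** — ICD-9/ICD-10 → phecode indicators with a
  minimum-case power filter.
* **Matching** — 4:1 greedy nearest-neighbour matching on median age of
  record within exact race/ethnicity/sex strata.
* **Association engine** — per-site logistic PheWAS (closed-form 2×2
  maximum likelihood, continuity-corrected fallback under separation),
  inverse-variance fixed-effects meta-analysis with Cochran's Q and
  I² (> 0.75 flagged heterogeneous), Bonferroni thresholds, a
  covariate-adjusted variant scan (age, sex, age×sex, age², 20 PCs;
  MAF ≥ 0.05; vectorized score test) with genomic inflation λ, and a
  two-definition comparison report with an attenuation summary.
* **Dilution** — relative effect-size dilution δ of one summary-statistic
  set against a reference via a weighted through-origin
  errors-in-variables slope, with bootstrap CI and a test against δ = 1.
* **Synthetic EHR generator** — longitudinal patients, diagnoses,
  prescriptions and genotypes with a latent truth record (liability-
  threshold case status, exposure propensity shared between prescription
  patterns and comorbidities), so the whole pipeline is testable without
  protected health data.

For whom: methodologists studying phenotype-definition sensitivity in
EHR genomics, and analysts who want executable, tested versions of these
cohort rules.

## The core quantities

For distinct prescription days $d_1 < \dots < d_k$, a patient is a
**minimally exposed** control candidate iff no three consecutive days
have both gaps $< 90$ (chronic veto, dominant) and some pair satisfies
$d_j - d_i \le 90$ with no other prescription in $(d_j, d_j + 270]$.

Per-site PheWAS estimates are pooled by fixed effects
($w_i = 1/se_i^2$), with $Q = \sum w_i (b_i - \bar b)^2$ and
$I^2 = \max(0,(Q - df)/Q)$. The comparison report's **attenuation
share** is the fraction of common significant phecodes with
$|\log OR_{generic}| > |\log OR_{exposed}|$. Dilution solves
$\beta_{study} \approx \beta_{ref}/\delta$ by a Deming slope that is
immune to reference-side regression dilution.

## Worked example

```r
library(oudcontrols)
cfg <- cohort_config()

classify_exposure(c(0, 50), cfg)        # "minimal"  (pair 50 days apart, clean tail)
classify_exposure(c(0, 50, 100), cfg)   # "chronic_pattern"  (consecutive gaps 50, 50)
classify_exposure(c(0, 50, 400), cfg)   # "minimal"  (third rx 350 > 270 days after second)

meta_fixed_effects(c(0.1, 0.5), c(0.1, 0.1))
#> $beta 0.3   $se 0.0707   $q 8   $df 1   $i2 0.875   $het_flag TRUE

res <- run_pipeline(preset_config("smoke", seed = 1), out_dir = "runs/smoke")
res$comparison
#> Control-definition comparison
#>   significant vs A: 5 (threshold 0.0025)
#>   significant vs B: 4 (threshold 0.0025)
#>   common: 4 | A-only: 1 | B-only: 0
#>   attenuation share (|logOR_A| > |logOR_B|): 1.000
res$dilution$generic
#> Effect-size dilution: 0.886 (95% CI 0.779-1.012), p vs 1 = 0.064, 133 variants
```

Reading the output: against generic controls (A) the PheWAS finds more
Bonferroni-significant phecodes than against minimally exposed controls
(B), and every common hit has the larger log-odds magnitude against the
generic group — the attenuation expected when exposed controls share
exposure-linked comorbidity with cases. The dilution of the
generic-control variant scan against the well-powered reference scan is
statistically compatible with 1 (no detectable misclassification bias at
this scale). At the `desk` preset (30 000 patients) the attenuation share
is 1.0 and both dilutions are within a few percent of 1.

The same pipeline runs from a shell:

```sh
Rscript scripts/run_pipeline.R --preset desk --seed 1 --out runs/desk
```

writing cohort, matched-set, per-site and meta PheWAS tables, summary
statistics, a comparison report and a manifest with per-file hashes
(reruns are byte-identical).

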