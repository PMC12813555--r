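---
title: "Generic versus minimally exposed controls in EHR studies of opioid use disorder"
author: "oudcontrols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generic versus minimally exposed controls in EHR studies of opioid use disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case–control studies of opioid use disorder (OUD) built on electronic
health records (EHR) must decide what a *control* is. The conventional
choice — any patient without an OUD diagnosis code ("generic" controls) —
is easy to assemble and maximizes sample size, but mixes patients who were
never exposed to prescription opioids with patients who took them without
developing the disorder. An alternative restricts controls to patients
with documented *minimal* opioid exposure: enough prescriptions to prove
access and use, but a pattern inconsistent with chronic therapy or
undiagnosed dependence. Because exposure is a prerequisite for OUD, the
two definitions answer subtly different questions, and the choice can
change both the comorbidity profile associated with case status and the
genetic associations downstream.

`oudcontrols` implements both definitions as executable phenotyping
algorithms, together with everything needed to measure what the choice
does to an association study: matched phenome-wide association (PheWAS)
with phecode outcomes, cross-site fixed-effects meta-analysis with
heterogeneity flags, a covariate-adjusted variant scan with
genomic-inflation diagnostics, and a summary-statistic effect-size
dilution estimator. Real EHR of this kind are protected and cannot ship
with a package, so the first module is a synthetic-EHR generator whose
latent truth record makes every downstream stage testable end to end.

## Cohort definitions

All dates are integer day offsets from a dataset epoch; calendars enter
only at I/O. This removes time-zone and month-length ambiguity from the
window arithmetic below.

**Cases** carry at least one OUD ICD code. **Both** control groups
exclude any patient with an OUD code or a cancer diagnosis (cancer
implies long-term analgesia that confounds prescription patterns), and
controls must be at least 18 years old at the dataset end date. Everyone
must pass a *medical-home data floor*: at least `floor_min_codes = 5` ICD
codes on distinct days within some `floor_window_days = 1095`-day window,
evaluated as a sliding window anchored at each event day. The sliding
reading is the stricter, more standard one; both parameters are
configurable. The floor is monotone by construction: adding an encounter
can never un-qualify a patient.

The exposure classifier assigns each patient exactly one of five classes
from their distinct opioid-prescription days $d_1 < \dots < d_k$:

* `unexposed` ($k = 0$) and `single_rx` ($k = 1$);
* `chronic_pattern`: some three *consecutive* prescription days have both
  gaps strictly below `chronic_gap_days = 90` — a pattern consistent with
  long-term therapy. This veto dominates every other rule;
* `minimal`: no chronic pattern, and some pair $(d_i, d_j)$ with
  $d_j - d_i \le 90$ has no other prescription in the half-open window
  $(d_j, d_j + 270]$ — two prescriptions at most 90 days apart and no
  third within 9 months of the second;
* `other`: two or more prescriptions matching neither pattern.

Only `minimal` patients are eligible for the exposed control group.
Boundary conventions follow the rules' wording literally: the pair gap
uses $\le 90$ ("no more than"), the chronic veto uses $< 90$ ("less
than"), and 9 months is encoded as 270 days ($9 \times 30$) because no
calendar month is specified; every constant is a `cohort_config()` field.
Same-day duplicate prescriptions collapse before classification so a
refill entered twice cannot fabricate a chronic pattern. The qualifying
pair is *existential* — any pair with a clean 9-month tail counts, with
the chronic veto guarding against over-inclusion. One consequence worth
knowing: gaps of exactly 90 days escape the strict-inequality veto, so
`(0, 90, 180)` is `minimal` via the pair `(90, 180)`. The classifier is
verified against an independent brute-force enumeration of pairs and
triples on tens of thousands of random date lists.

When both control groups are drawn from one dataset they must not
overlap: exposed controls are matched first, and generic controls are
then drawn from the remaining eligible pool. The generic pool retains its
minimal-pattern members — generic controls may or may not have been
exposed, which is the point of the comparison.

## Matching and association

Controls are matched 4:1 to cases within exact strata of race, ethnicity
and sex, greedily taking the unused controls nearest in median age of
record (the median of the patient's age over their distinct diagnosis
days), with case order randomized by a seed and ties broken by smaller
patient id. Greedy nearest-neighbour without replacement is the default
behaviour of the standard matching tools; the caliper is off by default
and configurable. On saturated pools the standardized mean difference in
median age after matching is below 0.1 (tested).

Diagnosis events map to phecodes through a two-dialect map (ICD-9 and
ICD-10 columns, dots stripped, conflicts rejected); a phecode indicator is
true given at least one mapped event, and phecodes with fewer than
`min_phecode_cases` positive patients are dropped — a power filter whose
default of 100 scales down with the preset so it plays the same role at
test sizes. Parent rollup (a child phecode implying its integer prefix)
exists behind a flag but is off by default, and no phecode-family
control-exclusion ranges are applied; neither behaviour is part of the
stated design being reproduced.

The PheWAS model is unconditional logistic regression of each phecode on
case status within the matched sample, mirroring the standard PheWAS
tooling. For a binary outcome and binary predictor with no covariates the
maximum-likelihood estimate is the 2×2 cross-product log odds ratio with
Wald SE $\sqrt{1/a + 1/b + 1/c + 1/d}$, so the package computes it in
closed form (vectorized over thousands of phecodes) and verifies the
identity against `glm` on random tables to $10^{-6}$. Zero cells fall
back to the 0.5-continuity-corrected estimate with a flag; constant
outcomes produce structured skip records.

Per-site estimates are pooled by inverse-variance fixed effects:
$w_i = 1/se_i^2$, $\hat\beta = \sum w_i b_i / \sum w_i$,
$Q = \sum w_i (b_i - \hat\beta)^2$, $I^2 = \max(0, (Q - df)/Q)$, with
$I^2 > 0.75$ flagged as significantly heterogeneous. The implementation
is cross-checked against `metafor::rma(method = "EE")`. Each analysis
applies its own Bonferroni threshold; the comparison report counts the
two significant sets, their overlap, a per-common-phecode
effect-difference test $z = (b_A - b_B)/\sqrt{se_A^2 + se_B^2}$, and the
*attenuation share*: the fraction of common significant phecodes whose
log-odds magnitude is larger against generic than against exposed
controls. The difference test ignores the positive correlation induced by
the shared cases and is therefore anti-conservative; the report says so
in its output.

## The variant scan

The scan adjusts for age, sex, age×sex, age² and the leading 20 genotype
principal components, and drops variants below MAF 0.05. PCs come from an
eigen-decomposition of the standardized dosage Gram matrix on an evenly
spaced subset of at most 500 variants — the usual pruned-subset practice,
adequate for covariate adjustment. The default test is the efficient
score test on the logistic null model (null fitted once, per-variant
statistic $U^2/V$ computed by matrix algebra across all variants), with
the one-step effect estimate $U/V$ and SE $1/\sqrt{V}$; this is the
standard large-scale approach and is accurate in the small-effect regime
a GWAS occupies. A per-variant full Wald fit is available as
`method = "wald"`, and the two agree closely in tests. Calibration is
summarized by the genomic inflation factor
$\lambda = \mathrm{median}(\chi^2_1)/0.4549$, which lies in $[0.9, 1.1]$
under the null at the tested scale.

## Effect-size dilution

Phenotype misclassification attenuates association effect sizes by a
roughly common multiplicative factor. Given two summary-statistic sets
aligned on shared variants (alleles harmonized, strand-ambiguous A/T and
C/G variants dropped), the package models
$\beta_{study} \approx \beta_{ref}/\delta$ and reports $\hat\delta$ with
a percentile-bootstrap CI and a bootstrap test against $\delta = 1$.

Both beta vectors are noisy, so an ordinary weighted through-origin slope
of study on reference is attenuated by the reference-side sampling noise
(classical regression dilution) — with betas of SD 0.02 and SEs of 0.01
the bias is 25%, far from ignorable. The estimator therefore uses the
weighted through-origin errors-in-variables (Deming) slope with the
error-variance ratio taken from the reported SEs:
$$\hat s = \frac{S_{yy} - \lambda S_{xx} + \sqrt{(S_{yy} - \lambda S_{xx})^2 + 4\lambda S_{xy}^2}}{2S_{xy}},\qquad \hat\delta = 1/\hat s,$$
with $S_{xx} = \sum w b_{ref}^2$, $S_{yy} = \sum w b_{study}^2$,
$S_{xy} = \sum w b_{study} b_{ref}$ and weights $w = 1/se_{study}^2$.
This reduces to the ordinary slope as the reference noise vanishes, is
exactly 1 when a study is compared with itself, and is exactly reciprocal
under exchange of the inputs when the error scales match. Simulations at
5 000 variants recover a true $\delta = 1.25$ with bias under 1% and
~95% CI coverage; under $\delta = 1$ the interval excludes 1 at the
nominal rate. This is a deliberately simple estimator of the dilution
quantity — a full misclassification likelihood is a different tool and is
not claimed.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions the package is built
around: two sites; OUD case prevalence 6%; a high background
opioid-prescription prevalence among non-cases (knob default 0.8273,
reflecting tertiary-care hospital populations, and realized within ±2
points at $n \ge 20\,000$); a data floor that 10% of patients are built
to fail; ages uniform over 12–90 years so the under-18 exclusion has
something to exclude; and a 20-year record span.

Three pieces of latent structure drive the analyses:

* **Exposure propensity.** A standard-normal score per patient whose
  within-stratum quantile selects the prescription-pattern class (higher
  propensity → more exposure, with class probabilities configured
  separately for cases and non-cases) and which also enters the
  comorbidity model. This single shared score is the minimal structure
  that makes exposed controls resemble cases on exposure-linked
  comorbidities — and hence produces the attenuation of effect sizes
  against exposed controls that the comparison report measures.
* **Comorbidities.** Each phecode follows
  $\mathrm{logit}(p) = \mathrm{logit}(p_0) + \beta_{case}\,\mathrm{case} +
  \beta_{exp}\,\mathrm{propensity} + s_{site}$, realized as mapped ICD
  events. Configured odds ratios are recovered by the association engine
  within CI coverage in tests.
* **Liability.** Case status thresholds a standardized liability —
  an equal-weight genetic score over the causal variants scaled to the
  configured heritability plus normal noise — at the empirical quantile
  matching the target prevalence. Genotypes are independent binomial
  dosages (no linkage disequilibrium); heritability-based analyses that
  need LD are out of scope.

Pattern realization is exact by construction: `minimal` emits two dates
with a uniform 1–90-day gap, `chronic` three dates with gaps uniform on
1–89 days, so every generated patient classifies into exactly the
intended class (the round-trip contract, asserted over 50 000 patients).
Floor intent is likewise enforced by construction: intended passes get
six strictly increasing filler days inside an 890-day window; intended
failures have *all* their diagnosis events snapped to at most four
distinct anchor days. The paper trail of a real record — visit clustering,
coding drift, site-specific vocabularies, refill noise, informative
missingness — is deliberately absent. Passing tests therefore demonstrate
that the algorithms implement their definitions and that the statistics
are calibrated under the stated generative model, not that the pipeline
is robust to real-EHR messiness. The prescription-date process between
the class constraints is an artifact choice (uniform placement), not a
claim about clinical prescribing.

## Numerical choices and degenerate inputs

* Wald intervals with 1.96 throughout, matching OR/CI reporting
  conventions; p-values floored at the smallest double so they stay in
  $(0, 1]$.
* Dates are integers; age is exact days/365.25.
* Matching ties break on smaller patient id; case order is seeded.
* Single-study meta is forced to $Q = 0$, $I^2 = 0$ (floating-point dust
  in $\sum w(b - \bar b)^2$ would otherwise make $I^2 = 1$ at $df = 0$).
* Empty prescription lists, constant outcomes, zero cells, empty phecode
  matrices, and undersized control pools all return structured results or
  named errors rather than crashing; the eligible-pool shortfall error
  reports the exact deficit.
* One top-level seed expands into fixed per-stage offsets, recorded in
  the manifest, so any stage can be rerun in isolation; reruns of the
  whole pipeline are byte-identical (hashes in the manifest).

## Problem sizes

The packaged presets are `smoke` (2 000 patients, 200 variants; seconds),
`desk` (30 000 patients, 1 000 variants; the scale at which calibration,
effect-recovery and attenuation properties are evaluated, under a
minute), and `full` (80 000 patients, 2 000 variants). Property tests use
the smallest size at which their binomial tolerances are meaningful:
50 000 patients for generator calibration, 2 000 null phecodes for
type-I error, 10 000 individuals × 5 000 variants for null-scan
inflation, 100 seeds for CI-coverage checks.

## Known limitations

* The effect-difference z-test between the two control definitions treats
  the analyses as independent although they share cases.
* The score-test beta is a one-step approximation; use `method = "wald"`
  when per-variant effect sizes at large effects matter.
* Dilution weights are study-side only and the error-variance ratio is
  pooled across variants; heteroskedastic references are handled only
  approximately.
* The exposure classifier's existential pair rule and strict/non-strict
  gap boundaries follow one literal reading of the definitions; both are
  configurable, and the 90-day-gap edge case above is the visible
  consequence.
* Phecode rollup and exclusion ranges are off by default; toy ICD
  vocabularies stand in for the real code systems.
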