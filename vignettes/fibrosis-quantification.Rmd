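---
title: "Quantifying myocardial collagen volume fraction and its prognostic value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial collagen volume fraction and its prognostic value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrosurv)
```

## The problem

In dilated cardiomyopathy (DCM), diffuse interstitial fibrosis — the
accumulation of collagen between cardiomyocytes — stiffens the ventricle,
disturbs electrical coupling, and predicts adverse outcome. The fraction of
tissue area occupied by collagen, the **collagen volume fraction (CVF)**, can
be measured directly on stained endomyocardial biopsy (EMB) fragments:
Masson's trichrome and AFOG stains render collagen blue and muscle
red/orange against a near-white slide background, so fibrosis burden reduces
to a colour-classification problem on scanned slides.

`fibrosurv` implements that measurement and the downstream prognostic
analysis as a single tested toolchain:

1. **Image stage** — region-of-interest (ROI) detection, pixelwise linear
   Bayesian classification in RGB space, morphological clean-up, and the CVF
   formula with per-patient pooling.
2. **Survival stage** — Kaplan–Meier curves and log-rank tests, a
   minimum-p-value cutpoint scan over CVF dichotomisations, Cox
   proportional-hazards model ladders compared by AIC, restricted cubic
   spline nonlinearity tests, and multiple imputation by bootstrap plus
   predictive mean matching (PMM) with Rubin pooling.
3. **Synthetic generators** — slides with planted, exactly known CVF and
   survival cohorts with known hazard structure, so every stage is testable
   with ground truth. No patient data ship with the package.

## The image model

### Linear Bayesian pixel classification

Each pixel's RGB colour $x \in [0,255]^3$ is modelled as Gaussian given its
tissue class $k \in \{\text{background}, \text{muscle}, \text{fibrosis}\}$,
with class mean $\mu_k$ and a **shared** covariance $\Sigma$ (pooled
within-class). Under that model the Bayes rule is linear in $x$ — this is
exactly linear discriminant analysis, and is the canonical reading of a
"linear Bayesian classifier" in a colour space:

$$\delta_k(x) = x^\top \Sigma^{-1}\mu_k
  - \tfrac12 \mu_k^\top \Sigma^{-1} \mu_k + \log \pi_k,$$

with the pixel assigned to $\arg\max_k \delta_k(x)$. Priors $\pi_k$ default
to equal, because annotated training regions have annotator-dependent sizes
that should not tilt the rule; empirical priors are available. The pooled
covariance receives a ridge $10^{-3}\,\mathrm{tr}(\Sigma)/3 \cdot I$ when
near-singular (e.g. training colours with zero variance in a channel).

Two numerical conventions matter and are fixed:

- **Tie rule.** Scores equal up to a $10^{-9}$ relative tolerance are tied
  and resolve to the earlier class in the order background < muscle <
  fibrosis. The tolerance exists because an algebraically exact tie (a pixel
  at the midpoint of two means under isotropic $\Sigma$) differs by
  $\sim 10^{-13}$ in floating point, and a documented deterministic rule
  must not depend on rounding direction.
- **ROI rule.** The background colour is estimated as the per-channel mode
  of the 1-pixel image border; every pixel whose Euclidean RGB distance from
  it exceeds 30 units (default) is tissue. Pixels outside the ROI are never
  classified.

### Morphological post-processing

Classification is pixelwise, so speckle (dust, stain artefacts, detached
micro-fragments) survives it. Post-processing applies, per tissue class, a
morphological opening then closing with a disk of radius 1 px (at the 4
µm/px working resolution), then removes connected tissue components smaller
than 0.01 mm². The open–close composition is idempotent, which the tests
verify end-to-end: cleaning a cleaned mask changes nothing. The stain
vendor's proprietary pipeline does not publish its thresholds or element
sizes; the defaults here are package conventions, exposed as parameters.

### The CVF formula and per-patient pooling

$$\mathrm{CVF}(\%) = 100 \cdot
  \frac{\text{total fibrosis area (mm}^2)}
       {\text{total muscle area (mm}^2) + \text{total fibrosis area (mm}^2)}$$

Background is excluded from the denominator. Areas are summed over **all**
retained fragments of a patient before the ratio is taken (area-weighted
pooling); averaging per-fragment CVFs would over-weight small fragments and
is deliberately not done. Using every available fragment minimises sampling
bias from the heterogeneous spatial distribution of fibrosis. Fragments
below 0.25 mm² of tissue are excluded with a recorded reason; patients whose
total retained tissue is below 2 mm² — the standard adequacy criterion for
biopsy material — are flagged `insufficient_tissue`. The 2 mm² rule is
applied to the per-patient total at aggregation (a fragment-level reading is
available by passing `min_tissue_mm2 = 2` to `quality_filter()`).

## The synthetic slide generator

`generate_fragment()` emulates one 1–2 mm² biopsy fragment: a connected
tissue blob (long-range smoothed noise with a radial penalty, thresholded at
the exact pixel count for the requested area) inside which fibrosis is laid
down by thresholding a short-range Gaussian-smoothed noise field at the
exact pixel count for the planted CVF. This produces spatially correlated,
interstitial-looking fibrosis patches; it makes no anatomical claim, and
does not need to — the classifier is pixelwise, so only colour statistics
and connectedness matter for testing it. Colours are drawn per class from
the palette's Gaussian colour model (trichrome default: muscle ≈ RGB
(180, 60, 70), fibrosis ≈ (70, 90, 170), background ≈ (245, 245, 245),
σ = 12 per channel for tissue). These palette numbers are package
conventions — the source imaging pipeline publishes no colour statistics —
and are parameters, not constants.

Two scale choices keep tests fast without changing the science: generation
runs at 4 µm/px by default (a 1.5 mm² fragment is ~10⁵ tissue pixels;
resolution is a parameter, and 0.46 µm/px — the native scan resolution —
works identically), and areas are always reported in mm² via the stored
resolution. Because fibrosis pixels are planted by exact count, the reported
`true_cvf_percent` matches the target within rounding (≤ 1 percentage point
at ≥ 1 mm²; exactly 0 or 100 at the boundaries). `add_artifacts()` overlays
dark dust specks and sub-threshold tissue flecks on background only, so the
truth mask stays valid and post-processing is genuinely exercised.

What the generator does **not** emulate: stain variation across
laboratories, focus artefacts, tissue folds, colour overlap between classes
beyond Gaussian scatter, or fibrosis that touches the fragment border.
Passing the recovery tests therefore demonstrates the pipeline's
correctness, not its robustness to real-world stain drift.

## The synthetic cohort generator

`cohort_spec()` defaults encode the marginal structure of a 524-patient
tertiary-centre DCM cohort: age ~ N(54.0, 13.4) years, BMI ~ N(27.1, 5.7),
LVEF ~ N(31.3, 12.5) truncated to (5, 70)%, NT-proBNP log-normal calibrated
to median 655 ng/L and IQR [218; 2253] (`calibrate_lognormal()` matches the
median and the IQR *ratio* exactly and reports the implied quartiles, since
a printed median/IQR pair need not be jointly log-normal-consistent),
creatinine log-normal moment-matched to mean 1.0 / SD 0.6 mg/dl, diabetes ~
Bernoulli(0.176), NYHA ~ categorical(0.403, 0.256, 0.171, 0.171), and CVF ~
N(32, 15) truncated to [0, 100] unless measured CVF is supplied.

Event times follow a Weibull proportional-hazards model drawn by the exact
inverse-CDF transform (no root finding): with baseline shape $k$ and scale
$\lambda$, $T = \lambda(-\log U \cdot e^{-\eta})^{1/k}$, where the log
hazard $\eta$ contains a **change-point** effect
$\beta_{\mathrm{cvf}}\,\mathbf{1}[\mathrm{CVF} > \tau]$ (defaults
$\beta_{\mathrm{cvf}} = \log 3$, $\tau = 32$) plus a centred log-NT-proBNP
effect ($\log 1.38$ per unit). The two endpoints arise coherently from two
latent times sharing a normal frailty (SD 0.3) on the log hazard: the
composite endpoint is the first of the heart-failure event and death;
all-cause mortality is death alone. Each endpoint carries its own
observation time in the cohort table, because the composite stops follow-up
at the first event while mortality follow-up continues.

Censoring is exponential dropout (0.16/year) truncated administratively at
8 years. The baseline scales (HF-event 400 y, death 55 y, Weibull shape
1.2) were calibrated once so a default 524-patient cohort reproduces the
intended study conditions — median follow-up ≈ 3.6 years, ≈ 60 composite
events, ≈ 55 deaths — and then frozen. The large HF-event scale is not a
typo: because the composite is the minimum of two latent times, it mainly
tunes the gap between composite and death event counts. The generator is a
test harness with known truth, not a claim about any real cohort's
data-generating process.

Missingness is injected MCAR per variable (`inject_missingness()`), the
favourable case for PMM; follow-up and event fields can never be made
missing.

## The survival stage

**Kaplan–Meier and log-rank** are implemented in-package (they are the
engine of the 91-threshold cutpoint scan and need to be cheap), and are
cross-checked in the tests against `survival::survfit()` /
`survival::survdiff()` to 10⁻¹⁰ as well as against naive risk-set
enumeration oracles.

**Cox models** go through `survival::coxph()` behind `fit_cox()`, with
Efron tie handling by default (the better-behaved choice when event times
are tied). The wrapper reports hazard ratios with
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$ intervals, Wald p-values, the log
partial likelihood, and $\mathrm{AIC} = -2\log PL + 2k$. Convergence
problems (monotone likelihood under separation) are captured as flags on
the result rather than silent warnings.

**The cutpoint scan** (`scan_cutpoints()`) dichotomises CVF at every integer
threshold from 5 to 95 — 91 grouping variables `< t` vs `≥ t` — log-ranks
each, and selects the smallest p-value. Conventions the source analysis
leaves open are fixed here: thresholds where either group is empty *or has
zero events* are degenerate and excluded from the argmin (a log-rank against
an event-free group is formally computable but meaningless for cutpoint
choice); ties at the minimum go to the smallest threshold; with continuous
CVF the `< t`/`≥ t` and `≤ t`/`> t` conventions almost surely coincide at
integer thresholds. Because the minimum over ~91 correlated tests is
optimistic, `minp_null_calibration()` measures the selection inflation: on
null cohorts (CVF independent of outcome) the minimum p dips below 0.05 an
order of magnitude more often than the nominal 5%, while a single fixed
threshold stays at ~5%. Scan p-values are descriptive, never confirmatory.

Under the package's paper-realistic event yield (~12% of patients), the
scan recovers a planted τ = 32 change-point (HR 3, n = 500) to within ±3
points in roughly two-thirds to three-quarters of replicates; the selected
thresholds centre on 32–33 without bias, and the misses are min-p flukes at
sparse extreme thresholds where a handful of high-CVF patients with chance
events produce spuriously small p-values — precisely the instability the
null calibration quantifies. Recovery climbs above 85% when the event count
is ~2.5× higher, so the limit is the information content of a ~57-event
cohort, not the scan.

**Model ladders.** `two_predictor_ladder()` fits, for each candidate
predictor, the single-predictor Cox model and the model additionally
adjusted for CVF, on the multiply-imputed stack with Rubin pooling; the AIC
of a multiply-imputed model is the across-imputation mean of per-imputation
AICs — a convention (flagged as such in the documentation), since no
standard single-number AIC exists under MI. `backward_eliminate()` screens
candidates univariably at the 10% level, then removes the largest Wald p
until all remaining terms pass 5%; Wald (not LR) p-values drive elimination,
with the likelihood-ratio test reserved for the spline nonlinearity check
(`nonlinearity_test()`), where a model-fit comparison is the point.
Elimination runs on a single complete dataset and is deterministic,
including its tie rule (equal p removes the later-declared term).

**Restricted cubic splines** use Harrell's truncated-power basis with
default knots at the 0.05/0.35/0.65/0.95 quantiles (4 knots, 2 nonlinear
degrees of freedom); the basis is linear beyond the boundary knots by
construction, which the tests check via vanishing second differences.

**Multiple imputation** (`impute_pmm_bootstrap()`) combines a bootstrap per
imputation (propagating parameter uncertainty) with PMM: each incomplete
variable is regressed on the other seven imputation variables on the
bootstrap rows where it is observed, predictions are made for everyone, and
each missing entry is filled with the *observed* value of a random donor
among its 5 nearest predicted-mean neighbours. Imputed values are therefore
always members of the observed-value set — the PMM hallmark — so bounded
and categorical variables (NYHA is matched on its numeric predicted score)
stay valid by construction. Variables are visited in order of increasing
missingness, one chained pass by default (`n_passes` raises it), with
missing predictor entries initialised by random observed draws. The default
`m = 50` follows common practice for moderate missingness; tests use
smaller `m` for speed. Pooling follows Rubin's rules with Barnard–Rubin
small-sample degrees of freedom when a complete-data df is supplied.

**Descriptive comparisons** (`compare_groups()`) dispatch strictly by
declared variable type — t-test for mean-scale, Mann–Whitney U for
median-scale, chi-squared for categorical — never by sniffing the data.
`logit_correlation()` correlates a percentage on the logit scale with
another variable (Fisher-z CI), erroring on 0/100 unless an explicit clamp
is given: silently clamping would manufacture data.

## Reporting conventions

Printed percentages use half-up rounding at the stated decimal places
(`round_half_up()`), matching clinical reporting (base R's banker's
rounding would print 2.10% as 2.1% but 6.25% as 6.2%). Event-rate tables
(`event_rate_table()`) show one decimal; complication rates two.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed and touches no global
RNG state (seeds are scoped with `withr::with_seed()`); identical inputs
give bit-identical slides, cohorts, and pipeline output directories, which
`run_pipeline()` makes checkable by writing an MD5 manifest. The test suite
and the acceptance script size their simulations to run on one CPU in a
few minutes: slides of 0.3–1 mm² at 4 µm/px, cohorts of 300–2000 patients,
50–100 replicates per operating characteristic, `m` of 5–10 for MI checks.
These sizes are stated here as the package's validation design; all
thresholds they are checked against are fixed in the tests.

## Known limitations

- The colour palettes and ROI/morphology defaults are conventions standing
  in for an unpublished commercial pipeline's parameters; on real scans
  they would need tuning against annotated slides.
- The cohort generator is MCAR-by-default and Gaussian/log-normal in its
  margins; it does not model informative missingness, competing risks, or
  time-varying covariates (all out of scope of the analysis it supports).
- The minimum-p cutpoint is optimistic by construction; the package
  quantifies but does not correct the optimism (no max-statistic adjusted
  p-values).
- `backward_eliminate()` treats candidates as single numeric/binary
  columns; factor expansion is handled by its worst-coefficient rule, not
  by joint Wald tests per factor.
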