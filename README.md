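# fibrosurv

Automated quantification of left-ventricular **collagen volume fraction
(CVF)** from stained endomyocardial-biopsy images, plus the survival
analysis that turns it into a prognostic marker for dilated cardiomyopathy
(DCM).

Interstitial fibrosis — collagen accumulating between cardiomyocytes — is a
direct histological readout of adverse myocardial remodelling. On
trichrome- or AFOG-stained biopsy scans, collagen is blue and muscle
red/orange, so fibrosis burden reduces to pixel classification. `fibrosurv`
is for researchers who want that measurement and its prognostic evaluation
as one reproducible, fully tested R toolchain, with synthetic ground-truth
generators standing in for patient data (none ship with the package).

## What it computes

**Image stage** (`detect_roi`, `train_classifier`, `classify_pixels`,
`postprocess`, `compute_cvf`, `aggregate_patient`): a three-step pipeline —
RGB thresholding against the border-estimated background colour; pixelwise
linear Bayesian classification (Gaussian class-conditionals, shared pooled
covariance; i.e. linear discriminant analysis) via

δ_k(x) = xᵀΣ⁻¹μ_k − ½ μ_kᵀΣ⁻¹μ_k + log π_k ;

morphological opening/closing and small-component removal; then

CVF(%) = 100 · fibrosis mm² / (muscle mm² + fibrosis mm²),

pooled over **all** of a patient's retained fragments before the ratio is
taken (never a mean of per-fragment CVFs).

**Survival stage** (`km_estimate`, `logrank_test`, `scan_cutpoints`,
`fit_cox`, `two_predictor_ladder`, `backward_eliminate`, `rcs_basis`,
`impute_pmm_bootstrap`, `pool_rubin`): Kaplan–Meier and log-rank
(implemented in-package, oracle-checked against `survival`); the
minimum-p-value cutpoint scan over the 91 CVF dichotomisations `<t` vs `≥t`
for t = 5…95, with `minp_null_calibration()` quantifying the optimism of
min-p selection; Cox proportional-hazards ladders with AIC; restricted
cubic-spline nonlinearity tests; and multiple imputation by bootstrap +
predictive mean matching with Rubin pooling.

**Synthetic generators** (`generate_fragment`, `add_artifacts`,
`simulate_cohort`): slides with exactly known planted CVF, and
Weibull-proportional-hazards cohorts with a change-point CVF effect, two
coherent endpoints (composite heart-failure event; all-cause death), and
realistic censoring — the ground truth every test measures against.

## Worked example

```r
library(fibrosurv)

# a synthetic 1.5 mm2 biopsy fragment with 32% planted CVF, plus artefacts
pal   <- stain_palette("trichrome")
slide <- generate_fragment(1.5, 32, pal, fragment_id = "P0001-F1", seed = 7)
slide <- add_artifacts(slide, n_dust = 4, n_micro_fragments = 2, seed = 8)
slide
#> <synthetic_slide> P0001-F1: 413 x 413 px @ 4 um/px, true CVF 32.00%

# train the classifier from simulated annotations, quantify the slide
clf <- train_classifier(sample_training_pixels(slide, 300, seed = 9))
seg <- quantify_slide(slide, clf)
seg$areas
#>        class pixels      mm2
#> 1 background  76959 1.231344
#> 2     muscle  63729 1.019664
#> 3   fibrosis  29881 0.478096

aggregate_patient("P0001", list(seg))
#> <patient_cvf> P0001: CVF 31.92% from 1 fragment(s) (1.498 mm2 tissue) [insufficient_tissue]
```

The planted 32% is recovered as 31.92% from a single fragment (flagged
`insufficient_tissue` because one 1.5 mm² fragment is below the 2 mm²
per-patient adequacy minimum — real patients contribute 3–5 fragments).

```r
# a simulated cohort whose hazard jumps for CVF > 32%, then the scan
cohort <- simulate_cohort(cohort_spec(n = 2000, seed = 1))
scan   <- scan_cutpoints(cohort, endpoint = "composite")
scan
#> <cutpoint_scan> 91 thresholds (27 degenerate), endpoint 'composite'
#>   optimal cutpoint 32% (log-rank p = 6.79e-17) on n=2000

cohort$high_cvf <- as.integer(cohort$cvf_percent >= scan$optimal_cutpoint)
fit_cox(cohort, c("high_cvf", "log_ntprobnp"))
#> <cox_model> n=2000, events=235, logPL=-1569.256, AIC=3142.5
#>          term            hr_ci        p
#>      high_cvf 3.39 (2.53-4.54) 2.24e-16
#>  log_ntprobnp 1.36 (1.26-1.46) 1.85e-15
```

The scan recovers the planted change-point exactly (32), and the Cox model
recovers the planted hazard ratios (true CVF effect HR 3, true NT-proBNP
effect HR 1.38 per log unit). Scan p-values are descriptive: the minimum
over 91 correlated tests is optimistic, which
`minp_null_calibration()` demonstrates on null cohorts.

Printed-rate helpers reproduce clinical-report arithmetic with half-up
rounding:

```r
proportion_percent(4, 524, 2)   #> 0.76   (major complications)
proportion_percent(11, 524, 2)  #> 2.1    (minor complications)
```

A full run — slides → per-patient CVF table → cohort → scan → KM curves →
model ladder → complication table, with an MD5 manifest for byte-level
reproducibility — is one call: `run_pipeline(run_config(), "out/")`. A thin
command-line front end lives at `inst/cli/fibrosurv.R`.

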