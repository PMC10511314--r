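---
title: "Methods: compositional analysis of 24-h movement behavior change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional analysis of 24-h movement behavior change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coda24)
```

## The problem and the geometry

A person's day divides exhaustively into sleep, sedentary behavior (SED),
light physical activity (LPA) and moderate-to-vigorous physical activity
(MVPA). Because the four parts must sum to 1440 minutes, increasing one
behavior necessarily displaces the others: the data are compositional, and
ordinary Euclidean differences of minutes confound each behavior's change
with everyone else's. `coda24` therefore works in the Aitchison geometry of
the 4-part simplex. Closure rescales a positive vector to unit sum;
perturbation (element-wise product, then closure) is the group operation, and
the perturbation difference post ⊖ pre is the natural "change in
composition" between two measurement waves. The compositional mean is the
closed geometric mean. All internal computation is on proportions; minutes
are a view through the fixed scale `day_minutes = 1440`, so the conversion is
exact in both directions.

Zero parts are rejected with an error naming the offending behavior:
accelerometer-derived daily averages for cohorts of this kind contain no
structural zeros, and silently imputing one would change the log-ratio
geometry. (A replacement strategy would be a research topic of its own and is
deliberately out of scope.)

## Pivot coordinates

The isometric log-ratio (ilr) map sends the 4-part simplex isometrically to
R^3. We use *pivot coordinates*: for a chosen behavior placed first, the
first coordinate is

z_1 = sqrt(3/4) · log( x_(1) / ( x_(2) x_(3) x_(4) )^(1/3) ),

the normalized log-ratio of that behavior against the geometric mean of the
other three, and the remaining coordinates recurse on the tail. Four
behavior-first bases let each behavior be read "versus the remaining
behaviors". The contrast matrix V (4×3, orthonormal zero-sum columns)
satisfies z = V' clr(x), and the first coordinates of all four bases are
sqrt(4/3)·clr(x), which is why they always sum to zero. The ordering of the
non-pivot parts inside each basis is not identifiable from any reported
quantity — first coordinates, fitted values, R² and predictions are all
invariant to it — so the package fixes it to the canonical order
(sleep, SED, LPA, MVPA) and tests that invariance instead of debating it.

## The change-on-change model

For outcome y (BMI in kg/m², or waist circumference in cm) measured at a
pre-retirement and a post-retirement wave about one year apart, the model is

Δy = α + γ_Δ' Δz + γ_0' z_pre + δ·y_pre + covariates + ε,

with Δz the change in pivot coordinates (identically the pivot coordinates
of post ⊖ pre, by ilr linearity), z_pre the baseline composition, and
covariates age (years at the pre wave), a sex dummy (woman = 1), an
occupational-status dummy (manual = 1), optionally season dummies (winter
reference) and follow-up time in days. The codings are the package's own
choice — the adjustment set is standard for this design but dummy coding is
rarely stated, so we fix deterministic, documented codings. Estimation is
ordinary least squares through a QR decomposition, with classical
homoskedastic standard errors and t-based two-sided intervals; no robust or
clustered errors, and no multiple-testing adjustment, matching how such
models are conventionally reported. Rows missing a field required by the
chosen specification are dropped (complete case) with a logged count.

Fitting the same model in each of the four behavior-first bases is an
orthogonal reparameterization: fitted values, residuals, R² and all
non-compositional coefficients agree to numerical precision (tested at
1e-8), while the four first-pivot coefficients — the "vs remaining,
difference" effects — sum to zero. The basis-free summary is the clr
coefficient vector a = (√3/2)·β for 4 parts, used for substitution from
published coefficients.

Two sensitivity specifications are built in: additional adjustment for
measurement season and follow-up days, and exclusion of participants
self-reporting more than 9 h sleep/night at baseline (long sleepers, for whom
further sleep increases plausibly act differently).

## Isotemporal substitution

Predictions for one-to-one time reallocations are made at a reference
composition, by default the cohort's pre-retirement compositional mean:
moving t minutes from one behavior to another, the predicted outcome change
is γ_Δ'(z(new) − z(ref)). The intercept, baseline-composition, and covariate
terms cancel because only the change coordinates move — which is also why
every substitution curve passes exactly through zero at t = 0. The
confidence interval is the delta-method linear form on the 3×3 covariance
block of the change coefficients; whether the published intervals also
propagate covariance with the baseline-composition terms is not stated
anywhere we could check, so the Δ-block-only construction is used and
documented. Grids run from −cap to +cap in 10-minute steps (10/30/60-minute
points are the conventionally reported ones), with caps of 60 min for pairs
involving MVPA and 120 min otherwise — the observed range of one-year
behavior change — skipping grid points that would exhaust the donor
behavior (e.g. taking 80 min from a 77-min MVPA budget).

Because the geometry is logarithmic, substitution is *not* antisymmetric:
losing 60 min of MVPA moves the predicted outcome substantially more than
gaining 60 min does (0.774 vs −0.290 kg/m² against SED with the BMI
coefficients above). This is a property of log-ratio models, not an
artifact.

## The synthetic cohort generator

No public participant-level data exist for this design, so the package ships
a generator whose defaults emulate the study conditions: n = 213; mean
compositions (497, 584, 282, 77) min pre and (520, 572, 272, 76) min post;
BMI 26.3 (SD 4.8) kg/m² with a −0.1 mean drift; waist 91.4 (SD 13.0) cm with
a −0.9 drift; 82% women, 31% manual workers, age 63.5 (SD 1.1), 12% long
sleepers. Compositions are logistic-normal — Gaussian in sleep-first pivot
coordinates — the standard compositional sampling model; baseline
coordinates use SDs (0.20, 0.25, 0.35) and change coordinates
(0.10, 0.12, 0.20), chosen once as plausible dispersions for cohort
heterogeneity and one-year within-person change respectively (changes are
considerably tighter than between-person spread). Outcome changes follow
exactly the linear model the analysis assumes, with clr effect vectors
defaulting to (√3/2) times the first-pivot coefficient vectors
(1.34, −0.09, −0.66, −0.60) for BMI and (1.51, 2.39, −1.76, −2.14) for
waist, centred to remove printed rounding so they sum to zero exactly, and
residual SD 1.0 (BMI) / 3.0 (waist). The intercept is calibrated so the
expected outcome drift matches the requested mean change. Baseline and
change draws are independent by default for test clarity.

What the generator does *not* emulate: correlation between baseline
composition and its change, behavior-dependent covariate effects (defaults
are zero), non-Gaussian outcome noise, measurement error in the clinic
variables, and missing waves. Passing recovery tests on this generator shows
the estimator is correct under its assumed model — not that real
accelerometer cohorts satisfy those assumptions. Daily wear records are
simulated around the wave composition with zero-sum Gaussian jitter
(rescaled to the 1440-min day) and wear-hour draws that make a configurable
fraction of days fail the 10-h validity rule.

## Filtering and descriptive rules

A valid measurement day requires at least 10 h of waking wear time
(boundary inclusive); a participant is excluded when either wave has fewer
than 3 valid days. Wave compositions are arithmetic means of daily minutes
across valid days, then closure — plain averaging, the convention for
accelerometer processing chains, rather than a compositional mean of days.
Outcome change groups use half-open bands: |ΔBMI| < 0.5 kg/m² (or
|ΔWC| < 3.0 cm) is "no change", with ties at the cutpoint classified as
decrease/increase; each outcome is labelled separately rather than jointly.
BMI categories use half-open bins [18.5, 25), [25, 30), [30, ∞), with
underweight (<18.5) folded into the normal-weight row and tallied
separately. Ternary projections place the subcomposition's first part at
(0,0), second at (1,0), third at (1/2, √3/2); the map is affine and exactly
invertible, which the tests exploit.

## Numerical choices and problem sizes

Simplex sums are checked to 1e-9 (double precision with 4 parts leaves
orders of magnitude of headroom); geometry round-trips are tested to 1e-10
over 1000 random compositions; fit invariance to 1e-8. The recovery study
in the test suite uses cohorts of n = 5000 at residual SD 0.5 with 200
seeded replicates for interval coverage, and n = 50 000 for checking the
generator's compositional means — sizes at which Monte-Carlo error is small
relative to the tested tolerances while the full suite still runs in well
under a minute.

## Known limitations

Single-outcome linear models only (no mixed models, robust errors, or >2
waves); reallocations move time between exactly two behaviors; predictions
are made at a single reference composition rather than standardized over the
cohort; the generator's independence assumptions above. The change-group
cutpoints and reallocation caps are study conventions, not package-validated
thresholds — both are parameters.
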