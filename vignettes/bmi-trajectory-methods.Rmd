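---
title: "Modelling childhood BMI trajectories: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling childhood BMI trajectories: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind **bmitraj**, the
choices that were genuinely open when it was built, and what the test
evidence does and does not establish.

## The problem

Well-child-visit records give BMI measurements at irregular ages, dense
in infancy and roughly annual later. Two features of the resulting BMI
curve matter epidemiologically: the **infancy peak** (a local maximum
typically near 7 months) and the **adiposity rebound** (the local
minimum, typically in the fourth year, whose early arrival predicts
later obesity). Estimating them per child requires a smooth,
differentiable fit to noisy, irregular longitudinal data.

## Model

For a child $i$ of one sex with visits at ages $t_{i1},\dots,t_{in_i}$
(months),

$$y_{ij} = \beta_0 + \sum_{k=1}^{m} \beta_k\, t_{ij}^{\,p_k}
  + u_{i0} + \sum_{k=1}^{m} u_{ik}\, t_{ij}^{\,p_k} + \varepsilon_{ij},$$

where the powers $p_k$ are distinct members of
$\{-2,-1,-0.5,0,0.5,1,2,3\}$ with $t^0$ read as $\ln t$, the random
effects $u_i \sim N(0, G)$ with $G$ diagonal, and the within-child
residual vector $\varepsilon_i \sim N(0, \sigma^2 C_i(\rho))$. Children
are independent; sexes are modelled separately. The candidate mean
models are all power subsets of size 3–8 (219 models; size below 3
cannot carry both milestones).

**Residual correlation structures.** The primary structure is *spatial
power*, $\mathrm{corr}(\varepsilon_{ij},\varepsilon_{ik}) =
\rho^{|t_{ij}-t_{ik}|}$ — the continuous-time AR(1), the natural choice
when visits are irregularly spaced. Compound symmetry, order-based
AR(1) and independent residuals are also available. Structures that
require discrete balanced occasions (Toeplitz, unstructured,
heterogeneous variants) are deliberately unsupported: with continuous,
child-specific visit ages they have no well-defined meaning, so the
structure search runs over the four implementable candidates.

**Random effects on all terms, diagonal $G$.** Every basis term
(including the intercept) carries a per-child deviation, which is what
lets individual curves shift their milestones. An unstructured $G$ for
6+ terms is fragile at the cohort sizes the simulator targets and adds
$O(m^2)$ parameters; the diagonal form preserves child-specific
milestone variation while staying estimable. Fixed effects are profiled
out by generalized least squares; the variance parameters are estimated
by bounded quasi-Newton (L-BFGS-B) on $\log$-variance /
$\tanh^{-1}$-correlation transforms. Basis columns are standardized
internally for conditioning; everything reported is on the raw months
scale. Starting values come from the spread of per-child OLS
coefficients (a method-of-moments estimate), with two fixed fallback
starts used on non-convergence; non-convergent fits are returned
flagged, never silently. Convergence uses the L-BFGS-B `factr = 1e7`
objective tolerance with up to 400 iterations.

**Estimation and BIC.** ML is the default (REML available) so that BIC
is comparable across mean structures. $\mathrm{BIC} = -2\ell + q\ln n$
with, by default, $q$ = number of covariance parameters and $n$ =
number of children — the convention of the mixed-model software
tradition in which the fixed effects are profiled; the textbook
convention (all parameters, $n$ = observations) is available and both
are recorded. Model selection is two-stage: structure first under the
richest candidate mean model (the union of all candidate powers), then
the mean model under the winning structure. Exact BIC ties break toward
the lower degree, then the earlier candidate in the canonical
(degree-then-lexicographic) order, making selections reproducible.

## Milestones and characteristics

Individual curves are fixed effects plus BLUPs,
$u_i = G Z_i^{\top} V_i^{-1}(y_i - X_i\hat\beta)$. The first derivative
is evaluated analytically on a grid of 8,632 points 0.025 months apart.
One week is $7/30.4375 = 0.2300$ months; the grid starts at 0.225 — the
nearest multiple of 0.025 below it — so that it ends at exactly 216.0
with the canonical point count. A milestone exists where two
consecutive grid points have opposite derivative signs ($+\to-$ peak in
3–17 months, $-\to+$ rebound in 15–114 months); the point with
$|\text{derivative}|$ closer to zero is the milestone age. Absence of a
sign change is an ordinary outcome (reported with a `found` flag), not
an error. Three conventions cover corner cases the rule leaves open:

* an exact zero at a grid point is the milestone directly (the limit of
  the tie rule) — but only when the derivative genuinely changes sign
  around it, so flat curves have no spurious milestones;
* several qualifying sign changes in one window (wiggly high-degree
  curves) resolve to the largest-BMI candidate for the peak and the
  smallest for the rebound, with a warning;
* a rebound found at or before the peak restarts the rebound search
  just past the peak.

Characteristics per period (1 week → peak → rebound → 18 years): BMI
change, age difference, velocity (change/age difference), and AUC from
the closed-form antiderivative ($x^{p+1}/(p+1)$; $\ln x$ for $p=-1$;
$x\ln x - x$ for the log term). Endpoint BMIs at 0.225 and 216 months
come from the fitted curve, since visits rarely fall exactly there.
Note one asymmetry worth remembering: milestones of the *population*
curve are not the mean of individual milestones (curve-of-averages vs
average-of-curves), which is why population-curve rebound ages sit
below typical cohort means.

## Preprocessing conventions

* Ages are months throughout (1 month = 30.4375 days, 18 years = 216
  months).
* Infant recumbent lengths measured by the paper-and-pencil technique
  are corrected by the validated affine map $0.953 L + 1.8$ cm. The
  correction keys on age < 24 months by default — the recording method
  is often not stored — with an optional method-flag restriction;
  corrected rows are flagged so the affine map is never applied twice.
* Eligibility requires 18 visits spread over 12 closed age intervals
  (2+2+2+2+1+1+1+1+1+3+1+1). Interval bounds are treated as printed,
  closed on both sides; visits in the small gaps between intervals
  count toward no interval.
* Birth-weight z-scores are internal: standardized within sex over the
  analytic sample, sample SD ($n-1$) by default (population SD
  available).
* Duplicate visit ages keep the first record; the rest are dropped
  with a warning.
* Children of unknown race or insurance are kept for descriptives but
  excluded (as missing) from the regression stage's complete-case
  sample.

## The synthetic cohort generator

`simulate_cohort()` draws, per child: covariates (race multinomial,
birth weight $N(3442, 488^2)$ g, Medicaid 3.9%, birth years
1979–1994), diagonal random effects, visit ages (an AAP-style schedule
with targets at 0.25, 1, 2, 4, 6, 9, 12, 15, 18, 24, 30, 36 months and
yearly thereafter; Gaussian jitter SD 0.3 months through the 24-month
visit, 1.5 months later; per-visit attendance 0.998), spatial-power
residuals ($\sigma = 0.9$, $\rho = 0.9$ per month), and the measurement
process (weights rounded to 0.25 lb, lengths to 0.25 in, infant lengths
first distorted by the exact inverse of the correction formula so
preprocessing recovers truth up to rounding). Both the recorded tables
and the truth layer (true coefficients, true milestones) are returned;
identical seeds give bit-identical cohorts.

Default calibration, chosen once and kept: the random-effect SDs
(0.7, 0.02, 0.25, 0.60, 0.10, 0.25 for intercept and powers
$-2,-1,-0.5,\log,0.5$) were set by a linearized sensitivity analysis so
that simulated milestone spreads have the order seen in real cohorts —
peak-age SD ≈ 1 month, rebound-age SD ≈ 10 months. The $\sqrt{t}$ term
does most of the rebound work because its derivative decays slowest;
the intercept moves milestone BMIs but not their ages. The residual
$\sigma = 0.9$ puts per-child residual variances (~0.8) inside the
interquartile range reported for real EHR cohorts. Attendance and
jitter were chosen so ≥ 95% of simulated children meet the eligibility
rule, mirroring an analytic sample that is by construction
eligibility-selected. True BMI is floored at 0.5 kg/m² — far below any
physiologic value — because the steep infancy basis can overshoot in
extreme left-tail draws.

What the generator does **not** emulate: secular trends, informative
dropout, the selection process distinguishing eligible from excluded
children, non-Gaussian BMI skewness at older ages, or real
stature-for-age variation beyond a smooth synthetic median curve with a
per-child scale factor (the bundled stature anchors are synthetic,
existing only to make weight/length pairs plausible). Tests passing on
these cohorts therefore establish internal correctness and recovery
under the stated generative model, not robustness to every EHR
pathology.

## Test problem sizes and numerical choices

The heavier checks run at sizes chosen to exercise the estimator
meaningfully on a single CPU: parameter recovery uses 20 cohorts of 200
children; selection consistency uses 10 low-noise cohorts of 150
children against a reduced 6-model candidate set (two structures) —
the full 219-model sweep is the same code path, just longer; end-to-end
milestone recovery uses one 120-child cohort. "Low noise" in those
experiments means $\sigma$ = 0.15–0.3 with the measurement model off:
the regime where each child's curve is well determined, so the
experiments test pipeline correctness rather than irreducible
estimation error — at realistic noise ($\sigma \approx 0.9$ plus
rounding), individual rebound ages carry a few months of genuine
uncertainty because the curve is nearly flat there.

The likelihood engine is verified against brute-force stacked
multivariate-normal densities on random small instances; those checks
draw random-effect variances scaled per term (each contributing $O(1)$
BMI variance), which is both the realistic regime and the
well-conditioned one — with raw-scale variances on $t^3$ at $t = 200$,
$V$'s condition number reaches $10^{14}$ and no double-precision
implementation could agree with an oracle to $10^{-8}$.

## Downstream analysis

Pearson correlations among characteristics use pairwise-complete
deletion by default (listwise would drop every child missing one
milestone) and pool sexes, with a by-sex option. The regression stage
fits one OLS model per characteristic with all predictors jointly (sex,
race, birth-year category, birth-weight z, insurance), 95% t-intervals,
no multiplicity adjustment, on the complete-case subsample; constant or
collinear predictors are dropped with a warning. Velocities may be
rescaled ×100 for readable coefficients.

## Known limitations

* Fractional polynomials are global: behaviour at the 1-week boundary
  is an extrapolation of the basis, and curve values there (~7 kg/m²)
  are model constructs rather than measurable BMIs; period-1 changes
  and AUCs inherit this convention.
* The diagonal-$G$ default understates covariance between a child's
  level and slope deviations; an unstructured $G$ is a planned
  extension.
* Milestone absence is informative (curves lacking a rebound are
  typically monotone-rising early) and is propagated as missingness,
  not modelled.
* No out-of-cohort prediction: BLUPs exist only for children in the
  fitted sample.
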