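---
title: "Triangulating two-wave cross-lagged effects against spuriousness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating two-wave cross-lagged effects against spuriousness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagtriad)
```

## Why adjusted cross-lagged effects can lie

A two-wave panel measures two constructs X and Y (in the motivating
application, self-esteem and eating pathology) at waves 1 and 2, giving six
zero-order correlations among (X1, X2, Y1, Y2). The conventional evidence
for a prospective effect of X on Y is the adjusted cross-lagged
coefficient: Y2 regressed on X1 with Y1 as covariate. The artifact it is
vulnerable to is simple. If X and Y are negatively correlated, then among
people with the same *measured* Y1, those with higher X1 tend to carry a
more positive measurement residual in Y1. Residuals regress toward zero
between waves, so those same people show a spuriously more negative change
in Y — a negative adjusted cross-lagged coefficient without any direct
effect.

`lagtriad` operationalizes a triangulation: three effect families whose
*sign patterns* differ between a genuine-decreasing-effects world and a
spurious one.

## The three closed forms

All three are pure functions of the correlation sextet. Writing
$r_{12} = r_{X_1 Y_2}$, $r_{11} = r_{X_1 Y_1}$, $r_{yy} = r_{Y_1 Y_2}$:

- adjusted cross-lagged:
  $\beta_{X_1, Y_2 \cdot Y_1} = (r_{12} - r_{11} r_{yy}) / (1 - r_{11}^2)$
  — the two-predictor standardized partial coefficient, identical to
  solving the normal equations on the implied correlation matrix;
- adjusted reverse (conditioning on the *subsequent* outcome):
  $\beta_{X_1, Y_1 \cdot Y_2} = (r_{11} - r_{12} r_{yy}) / (1 - r_{12}^2)$;
- difference score, with unit variances at both waves:
  $\beta_{X_1, Y_2 - Y_1} = (r_{12} - r_{11}) / \sqrt{2 (1 - r_{yy})}$,
  i.e. the correlation of X1 with the standardized change.

The mirror-image Y-on-X effects swap the construct roles (inputs
$r_{X_2 Y_1}$, $r_{X_1 Y_1}$, $r_{X_1 X_2}$). Under genuine reciprocal
decreasing effects the expected signs are (−, +, −) in each direction: a
high X1 should have *counteracted* a high concurrent Y1 (positive reverse
effect) and should predict negative change. Under spuriousness they are
(−, −, 0/+): the reverse-adjusted effect inherits the same
regression-to-the-mean artifact, and the change effect is zero when
concurrent and cross-lagged correlations coincide, positive when the
concurrent correlation is the stronger (more negative) one. "Zero or
positive" is operationalized as the union of significantly-positive and
CI-straddling-zero; the data give no separate numeric band for "zero".
Significance uses 95% CIs only, matching how pooled effects are reported
in this literature; no p-value machinery is involved. Classification is
supported at the pooled level — per-study verdicts would need a CI
convention for single studies that the literature does not fix, so they
are not a first-class path.

## Two-step multilevel pooling

Study collections in this area report several effect-size sets per sample
(different instruments or subscales), so effect sizes cluster within
samples. The pipeline follows the two-step convention:

1. *Within sample*: fixed-effect inverse-variance mean of the Fisher
   z-transformed values, pooled variance $1/\sum 1/v_i$. A full
   three-level random-effects model is a deliberate non-goal; the two-step
   scheme is what the reanalyzed literature uses, and with one record per
   sample it provably collapses to one-step pooling (tested).
2. *Across samples*: random-effects meta-analysis with REML $\tau^2$
   (DerSimonian–Laird behind a flag for comparison), weights
   $1/(v_i + \tau^2)$, normal-quantile 95% CIs on the z scale (no
   Knapp–Hartung adjustment), back-transformed through $\tanh$ for
   reporting. Model fitting is delegated to `metafor::rma()`, with a
   damped Fisher-scoring step so ill-conditioned inputs still converge;
   Cochran's Q is computed from fixed-effect weights, $I^2 = \max(0,
   (Q - df)/Q) \cdot 100$, and the $I^2$ interval comes from the Q-profile
   interval for $\tau^2$.

Everything — correlations *and* standardized regression effects — is
transformed with Fisher's z and weighted by $1/(n-3)$. For betas this
variance is an approximation adopted deliberately: the reanalyzed
literature transforms both identically and states no separate variance
formula. Records with $n \le 3$ are rejected at read time (the variance
would be non-positive), and derived betas with $|\beta| \ge 1$ (possible
in tiny noisy samples) are dropped from pooling with a warning rather than
silently.

## The common-cause generative model

The demonstration that the spurious pattern *can* arise without direct
effects uses a linear latent model: a standard-normal common cause CC with
$gX = a \cdot CC + e$, $gY = -b \cdot CC + e$; each general level loads $c$
on its two occasions; an optional occasion state loads $+s$ on the X
measure and $-s$ on the Y measure of the same wave. All variables are
scaled to unit variance, so correlations and standardized coefficients
coincide and there is no ambiguity about when standardization happens.
Path tracing gives the implied correlations in closed form:
auto-correlations $c^2$, cross-lagged $-abc^2$, concurrent $-abc^2 - s^2$.

Interpretation choices worth recording: the three loadings are assigned as
$a$ = cause-to-X-level, $b$ = magnitude of cause-to-Y-level (negative
sign), $c$ = level-to-occasion, symmetric across constructs and waves —
three parameters suffice to produce every predicted sign, and asymmetric
X- vs Y-side loadings would be observationally equivalent here. A single
common cause stands in for arbitrarily many: independent confounders with
proportional loadings are indistinguishable in a linear model. The
occasion state defaults to off and exists because it is the standard
explanation for concurrent correlations exceeding cross-lagged ones.

With $s = 0$ the implied effect pattern is (−, −, 0, −, −, 0) for *every*
valid $(a, b, c)$ — spurious negative adjusted effects with exactly null
change effects. With $s > 0$ the change effects are strictly positive
(their numerator is $s^2$), and the adjusted lagged effects stay negative
precisely when the confounding dominates the state factor:
$a b (1 - c^2) > s^2$. That regime condition is an algebraic fact about
the model that the package documents and tests on both sides of the
boundary; the published parameter examples and the default synthetic
scenario sit inside it.

## The synthetic meta-analytic scenario

`scenario_config()` emulates the *shape* of the reanalyzed corpus, not its
per-study values: K = 48 samples; sizes log-uniform on [20, 2601]
(right-skewed with mean a few hundred, like the published range); 1–5
effect-size sets per sample (mean 3, reproducing roughly 130–145 effect
sizes across 37–48 samples per association once 8% per-correlation
missingness is applied); per-sample parameters drawn uniformly from
$a, b \in [0.60, 0.76]$, $c \in [0.70, 0.82]$, $s \in [0.20, 0.32]$, chosen
once so the implied population correlations bracket typical pooled values
(auto ≈ 0.58, cross-lagged ≈ −0.27, concurrent ≈ −0.34). Clustering of
repeated effect sizes arises by re-simulating the same sample's population
(shared parameters and n); an overlap knob can additionally share
individuals between sets, since the true dependence structure of repeated
effect sizes is not reported anywhere. Missingness is MCAR per
correlation; real missingness is design-driven (which instruments a study
administered) and is deliberately not modeled.

What passing on these simulations shows — and does not. The generator is
exactly the model under which the spurious hypothesis is true, so the
end-to-end check (the verdict comes out `consistent_with_spurious` in at
least 95 of 100 master seeds at K = 40) validates the *pipeline's ability
to recognize the pattern*, not any claim about real populations. Real data
could be generated by other mechanisms, including models with genuine
paths; a handcrafted genuine-pattern population is therefore also run
through the full pipeline in the tests and classifies as
`consistent_with_genuine`.

## Numerical choices and degenerate inputs

- Closed-form denominators below `1e-10` (collinear predictors,
  zero-variance difference scores) raise named errors; inside
  `effect_sextet()` such effects become `NaN` with a warning so one
  degenerate effect never aborts the other five.
- A fully observed sextet must imply a positive semidefinite 4×4
  correlation matrix (smallest eigenvalue ≥ −1e−8); anything else cannot
  come from real data and is rejected at validation.
- Missing correlations never abort a sextet: each effect uses exactly the
  inputs its formula needs, mirroring per-row variation in K and NE.
- Sign labels in `predicted_signs()` treat |effect| < 1e−12 as zero; the
  null change effects at $s = 0$ are exact cancellations, so this only
  guards floating-point dust.
- REML convergence is metafor's criterion with `stepadj = 0.5`,
  `maxiter = 1000`; the Q-profile CI is attempted and reported as `NA`
  when the profile cannot be bracketed.
- Report files format estimates to 3 decimals and Q/I² to 1 (display
  only); the JSON bundle carries full double precision, and regeneration
  is byte-identical.

## Problem sizes used by the checks

The test suite runs the oracle equivalence on 1,000 random sextets
(normal equations, tolerance 1e−10) and 100 simulated raw datasets (OLS on
standardized scores, tolerance 1e−8); the REML calibration on 200
replicate meta-analyses of K = 40 samples with n = 400; the sign-contract
grid on 1,000 parameter points; and the end-to-end verdict experiment on
100 master seeds at K = 40. These sizes give Monte-Carlo standard errors
small enough for 3-SE acceptance bands while keeping the whole suite in
the minutes range on a laptop.

## Known limitations

- Two waves only; random-intercept cross-lagged panel models need at
  least three waves and are out of scope.
- The Fisher-z variance for standardized betas is the correlation
  approximation, not a derived sampling variance.
- Within-sample aggregation is fixed-effect; a nested random-effects
  level is a documented alternative, not implemented.
- No moderator analysis, meta-regression, or publication-bias
  diagnostics.
- The triangulation classifies *sign-pattern consistency*; it cannot prove
  causal absence, only that the observed pattern is (or is not) what a
  confounding-plus-regression-to-the-mean mechanism predicts.
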