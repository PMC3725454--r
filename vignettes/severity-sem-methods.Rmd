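---
title: "Modeling AUD severity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling AUD severity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevsem)
```

## The model

`sevsem` estimates a four-latent-factor covariance-structure model of
alcohol use disorder (AUD) severity. Twelve observed scores from clinical
instruments load on four factors:

* **Severity** (endogenous) — dependence scale total (ADS), craving (PACS),
  DSM-IV abuse/dependence symptom count (COUNT), drinking consequences
  (DRINC), withdrawal (CIWA);
* **Alcohol Use** — drinks per drinking day (DPDD), percent binge days
  (BINGE_PCT);
* **Affective Symptoms** — anxiety (BAI) and depression (BDI) totals;
* **Motivation** — the SOCRATES subscales STEPS, RECOG, AMBIV.

The three exogenous factors predict Severity and covary freely among
themselves. Scale setting follows the original analysis: exogenous factor
variances are fixed to 1 with all loadings free; Severity is scaled by
fixing its ADS loading to 1, and its *disturbance* (residual) variance is
free. The "freely estimated variance" of an endogenous factor can only be
its disturbance — its total variance is determined by the predictors — and
this is the only reading under which the model has 30 free parameters and
`78 - 30 = 48` degrees of freedom, matching the published fit statistics.

Internally the model is held in RAM form: directed paths in an asymmetric
matrix $A$, variances/covariances of exogenous terms and residuals in a
symmetric $S$, and a filter $F$ selecting the observed block, with

$$\Sigma(\theta) = F\,(I-A)^{-1} S (I-A)^{-\top} F^\top .$$

Estimation minimizes the ML discrepancy

$$F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}\!\left(S_{obs}\Sigma(\theta)^{-1}\right) - \log|S_{obs}| - p,$$

and the test statistic is $T = (n-1)\,\hat F_{ML}$. The $(n-1)$ multiplier
is deliberate: it is the only convention under which the published
(chi-square, df, n, RMSEA) quadruples back-compute exactly.

## Numerical choices

* **Optimizer.** Quasi-Newton (`nlminb`) with the analytic gradient
  $\partial F/\partial\theta_k = \mathrm{tr}[(\Sigma^{-1} -
  \Sigma^{-1} S_{obs} \Sigma^{-1})\,\partial\Sigma/\partial\theta_k]$,
  followed by Newton polishing on the expected information
  $2\Delta^\top W \Delta$ until the gradient infinity-norm is below
  $10^{-10}$. Polishing makes independent routes to the same optimum agree
  to ~1e-8 in the parameters, which the multi-group reduction tests rely on.
* **Parameter scaling.** The raw scores span SDs from 0.3 (BINGE_PCT) to
  22 (DRINC); unscaled quasi-Newton steps can stall in a local basin under
  such conditioning (we observed this when rescaling a variable by 10), so
  iterates are scaled by the inverse magnitude of the start values.
* **Start values.** Residual variances start at half the sample variance;
  loadings at 0.7 of the indicator SD on the factor's scale (marker SD for
  marker-scaled factors); structural paths at 0. Latent covariances start
  at 0.3 on the factor-scale metric rather than 0: with all factor
  covariances at zero a two-indicator factor is locally unidentified and
  the moment Jacobian loses rank at the start point.
* **Convergence.** Relative objective change below 1e-12 in the optimizer,
  gradient norm 1e-6 enforced with up to five perturbed restarts, then the
  Newton polish. Fits are flagged unconverged beyond 1e-4.
* **Heywood cases.** Negative variance estimates are reported and flagged,
  never truncated at zero — truncation would hide misfit. With a 0.97
  standardized loading (BINGE_PCT), study-size samples produce occasional
  small negative residual estimates; tests treat the warning as expected
  sampling behavior.
* **vech ordering.** All moment vectors, Jacobians and weight matrices use
  the column-major lower-triangle ordering, applied consistently by the
  robust module.
* **Degenerate inputs.** Non-PD covariance input fails construction;
  a saturated model reports CFI 1 and refuses the per-df indices
  (relative chi-square, RMSEA) with a named error; `df = 0` scaling is
  likewise refused.

## Fit indices and robust statistics

The baseline for the CFI is the universal independence model with free
variances; its discrepancy has the closed form $-\log|R|$. Published CFI
and RMSEA for this sample are the *robust* versions produced by the
original software. The robust scaling depends on the raw data's fourth
moments, which are not recoverable from a printed correlation table, so
the reproduction reports ML CFI/RMSEA against the printed robust values
with documented tolerances (0.02 and 0.01). On the reconstructed moments
the ML chi-square is 123.4 against a published scaled 103.73 (scaling
factor ~1.19); the ML RMSEA (0.075) accordingly sits just above the
printed robust 0.064, missing the 0.01 band by 0.0006, while the CFI and
every standardized estimate land inside their bands.

From raw data, the package computes the distribution-free fourth-moment
matrix $\Gamma$ (biased $1/n$ central moments — simpler, stable, and
immaterial at these sizes), the normal-theory weight
$W = \tfrac12 D^\top(\hat\Sigma^{-1}\otimes\hat\Sigma^{-1})D$, the
residual weight $U = W - W\Delta(\Delta^\top W\Delta)^{-1}\Delta^\top W$,
and the scaling factor $c = \mathrm{tr}(U\Gamma)/df$, giving the scaled
statistic $T_{SB} = T/c$ and sandwich standard errors. Under
normal-theory $\Gamma = W^{-1}$ the projection identity forces $c = 1$
exactly and the sandwich collapses onto the ML standard errors — both are
exact tests in the suite. The robust CFI scales the independence baseline
with the same $\Gamma$; this matches the behavior family of the original
software but is approximate, and reports flag it as such.

## Multi-group analysis and the LM test

Groups share one specification; the joint fit minimizes
$\sum_g (n_g-1) F_g / (N - G)$ (equivalently $\sum_g (n_g-1)F_g$, which is
the total chi-square). By default all free loadings, structural paths and
factor covariances are constrained equal across groups while residual
variances stay group-specific: "all paths" in the original gender analysis
is read as the measurement and structural coefficients, not the residuals,
and the choice is configurable.

The Lagrange-multiplier release test is the score test at the constrained
optimum: for each equality class the predicted chi-square drop from
releasing it is $\tfrac12 g^\top H^{-1} g$ in the parameterization
augmented with the release direction, with $g$ the chi-square-scale
gradient and $H$ the block-diagonal expected information. Tests are
univariate (one release at a time), matching how the original analysis
reported two releasable paths, and agree with explicit refit
likelihood-ratio drops within 15% on seeded fixtures.

## The synthetic-data generator

The generator exists because the raw study data were never deposited:
every raw-data-dependent stage (robust statistics, subset refits,
multi-group analysis) is exercised on samples that emulate the study's
statistical structure. Margins are Fleishman cubics
$Y = a + bZ + cZ^2 + dZ^3$ of standard normals, solved numerically for
requested skewness and excess kurtosis; multivariate structure comes from
Vale-Maurelli intermediate correlations, solving the cubic relation per
variable pair so the transformed variables hit the target correlations.
Requests violating the feasibility bound (excess kurtosis below
$\mathrm{skew}^2 - 2$) are rejected by construction.

Defaults emulate the study conditions: the published means, SDs and
correlations as targets; n = 283 (or 75 women / 205 men for two-group
samples); right-skewed alcohol-involvement margins (skew 1, excess
kurtosis 1.5 — the study reports only that these variables were
non-normal; the values are plainly non-normal yet comfortably feasible,
and configurable) with normal affect/motivation margins. Margins are
continuous; the symptom count is not integer-rounded by default because
rounding would perturb the targeted moments (a discretization step can be
applied by the caller for realism checks). Gender fixtures offset the
standardized BAI/BDI loadings in the men's group while preserving each
indicator's total variance; the published analysis gives no direction or
magnitude for the difference, and since the fitted standardized loadings
(~0.90) leave no headroom upward, fixtures use downward offsets of 0.2.

What passing tests on such data do show: the engine recovers generating
parameters, the SB statistic is calibrated in mean under non-normality,
and the LM machinery localizes genuinely violated constraints. What they
cannot show: agreement with the study's own robust chi-squares, robust
standard errors or LM values (8.26, 5.07), which depend on unpublished
fourth moments — those quantities are checked only through their
arithmetic identities and through property-based substitutes.

## Problem sizes used in the checks

Deterministic reproduction runs on the bundled 12-variable table in well
under a second. Monte Carlo checks use: 200 replicates at n = 500 for SB
calibration; 100 replicates at 500 per group for LM release power; 500
normal replicates at n = 500 for chi-square calibration of a 6-variable
model; n = 1e5 for parameter recovery and correlation-target checks; and
n = 1e6 for single-margin moment checks.

## Known limitations

* No mean structure, ordinal indicators, FIML, GLS/WLS estimation,
  RMSEA confidence intervals, or bootstrap errors (out of scope).
* The no-COUNT variant computes df = 38 (66 moments, 28 parameters); the
  published table reports df = 35 without documenting which three extra
  parameters were freed. The report surfaces the discrepancy and does not
  guess.
* Printed model-B statistics are internally inconsistent at the last
  digit (76.13/35 = 2.18, published as 2.17; the implied RMSEA rounds to
  0.065, published as 0.064); the package reports the arithmetic truth.
* The equality-constraint machinery covers shared labels and cross-group
  equality only; there are no general linear constraints.

## A worked example

```{r example, eval = FALSE}
fit <- semFit(modelASyntax(), table1Moments())
fitMeasures(fit)
standardizedSolution(fit)
latentRsquared(fit, "Severity")   # 0.684: variance explained in Severity
reproduceStudy()                  # all four analyses + comparison tables
```
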