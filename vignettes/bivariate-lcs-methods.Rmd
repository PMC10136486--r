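---
title: "Bivariate latent change score models with FIML: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate latent change score models with FIML: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilcs)
```

## The model

`bilcs` estimates the coupling between two psychological constructs measured
at two occasions — in the motivating application, eating-disorder
psychopathology (EDE-Q total score) and depressive symptoms (BDI-II total)
in women treated for anorexia or bulimia nervosa. Each construct's change is
captured by a latent change score (LCS): the follow-up score is constrained
to be the baseline score plus a latent change factor (both loadings fixed to
1), so the change factor *is* the true change and can itself be regressed on
predictors.

Writing ΔE and ΔB for the two change factors, the structural equations are

    ΔE = α_E + β_E·E0 + γ_E·B0 + ε_E·ΔB + ζ_E
    ΔB = α_B + β_B·B0 + γ_B·E0 + ε_B·ΔE + ζ_B

with baseline scores (E0, B0) bivariate normal with means μ, variances
φ_EE, φ_BB and covariance φ_EB, and uncorrelated normal disturbances ζ with
variances ψ. Each symbol plays a distinct scientific role:

* **α** — constant change common to all participants (the LCS intercept);
* **β** — proportional (autoregressive) effect: change driven by the
  construct's own baseline. Negative β with improving patients means those
  who start worse improve more;
* **γ** — cross-lagged effect: change driven by the *other* construct's
  baseline;
* **ε** — change-to-change coupling: how much one construct's improvement
  tracks the other's improvement within the same interval;
* **φ_EB** — baseline covariance (comorbidity at intake);
* **ψ** — disturbance variance, the individual variability in change not
  explained by the paths.

The primary ("final") model fixes α_E = α_B = 0 and ε_E = 0, reflecting the
a-priori hypothesis that depression improves *because* ED psychopathology
improves, not the reverse; everything else is free. The observed-variable
model has 4 means and 10 unique covariance elements, i.e. 14 identified
moments; with 12 free parameters the final model has 2 degrees of freedom.

The implied mean vector and covariance matrix are obtained from the
six-variable path system (E0, B0, ΔE, ΔB, E1, B1) via the reduced form
(I − A)⁻¹: this solves the structural equations *exactly*, including the
nonrecursive case in which both ε coefficients are free. The battery of
model variants used in practice never frees both, but the estimator must not
silently fail there, so the algebra handles it and `simulate_lcs_cases()`
mirrors it with a per-case linear solve (the two are checked against each
other by Monte Carlo in the test suite).

Depression totals are divided by 10 before estimation (`run_analysis()` does
this by default). This is purely a numerical conditioning device — the BDI
range (0–63) is an order of magnitude wider than the EDE-Q range (0–6) —
and all depression-related coefficients and variances are interpreted on
that divided scale.

## Estimation

All models are estimated by full-information maximum likelihood (FIML):
each participant contributes the multivariate-normal log-density of their
*observed* subvector under the implied moments, so participants lost to
follow-up still inform the baseline moments and, through the covariance
structure, the change parameters. This is unbiased when dropout is missing
at random given the observed baseline.

Implementation notes, in the order they matter:

* Cases are grouped by missingness pattern and reduced to sufficient
  statistics (count, mean, centered scatter), making one likelihood
  evaluation O(#patterns) instead of O(n). A per-case evaluation path is
  retained (`fiml_loglik(..., casewise = TRUE)`) both for the sandwich
  estimator and as the brute-force oracle in tests.
* Optimisation is quasi-Newton (BFGS) on a working scale in which free
  variances are log-transformed; this keeps the search unconstrained while
  guaranteeing positive variance estimates. Starting values are the
  pattern-available sample moments for the exogenous parameters, zero for
  all regression paths, and half the observed change variance for the
  disturbances — deterministic and inside the admissible region. A second
  BFGS run from the first solution guards against stale curvature
  approximations; convergence requires both the optimizer's own criterion
  and a small gradient norm, and both are reported in the fit object.
* The ML covariance divisor is n throughout (likelihood convention), with n
  counting every case entering FIML, including baseline-only cases.
* Naive standard errors invert the observed information (numerical Hessian
  on the working scale, delta-method-transformed back). Sandwich
  (Huber–White) standard errors are A⁻¹BA⁻¹ with A the observed information
  and B the outer product of per-case scores obtained by central finite
  differences with step 1e-5·(1+|θ|); the observed-information "bread" is a
  deliberate choice (the expected-information variant differs only at
  higher order under correct specification).
* If the implied covariance of some observed subvector leaves the
  positive-definite cone during the search, the likelihood evaluation
  returns a large finite penalty rather than an error, so the line search
  backtracks.

The saturated reference model (all 14 moments free) is closed-form on
complete data and optimised through a log-Cholesky parameterization
otherwise; the independence baseline model (free means and variances, zero
covariances) is closed-form even with missingness because its likelihood
factors per variable.

## Fit assessment and model comparison

The battery follows standard SEM practice: χ² against the saturated model,
CFI and TLI against the independence baseline, RMSEA, SRMR and BIC, with
the usual rule-of-thumb thresholds (CFI/TLI ≥ 0.95, RMSEA ≤ 0.06,
SRMR ≤ 0.08, lower BIC better). Conventions that are genuinely open and the
choices made:

* **SRMR** uses covariance residuals only (mean residuals excluded),
  standardized by the saturated standard deviations — the common software
  default.
* **RMSEA** uses the n − 1 divisor; at n = 157 the alternative n divisor
  differs in the fourth decimal, and a `divisor_n` switch is provided.
* **TLI is not clipped** above 1; a well-fitting model can legitimately
  print values like 1.01.
* **Robust (mean-scaled) χ²** divides the ML statistic by
  c = tr(UΓ)/df, with Γ the asymptotic covariance of the sample mean and
  covariance vector estimated from fourth-order moments of the
  listwise-complete cases and U the normal-theory residual weight
  projection at the fitted point. Estimating Γ from complete cases only is
  a deliberate simplification: the full FIML fourth-moment machinery is out
  of scope, and at ~23% attrition the complete-case Γ is a serviceable
  estimate. Under multivariate normality c → 1 (verified at n = 20000 in
  the acceptance suite); heavy-tailed data push c above 1.
* **Difference tests** default to the unscaled ML statistic. A
  Satorra–Bentler-style scaled difference is available via
  `chi_diff_test(..., scaled = TRUE)`, since reporting robust single-model
  indices while testing with unscaled differences is a common but not
  universal pairing.

`comparison_table()` reproduces the full ten-variant battery: the final
model, three *unconstrained* variants (each fixed parameter freed singly —
does the data demand it?), and six *constrained* variants (each free effect
fixed to zero singly — does the data support it?). The decision column
applies the symmetric retention logic at the configured α (default 0.05):
free a fixed parameter only if freeing it significantly improves fit;
retain a free effect only if constraining it significantly worsens fit.

## The synthetic cohort generator

The patient-level data behind the motivating analysis are not publicly
deposited, so the package ships a generator that emulates the *statistical
frame* of that cohort and serves as the test bed for everything above.
Defaults, fixed once and documented here:

* n = 157 participants, ~22.9% follow-up attrition (36/157), matching the
  reported sample flow; dropout is MCAR by default, with a
  MAR-on-baseline option (logistic in the baseline scores, intercept solved
  numerically to hit the target rate) motivated by the reported pattern
  that non-completers had lower baseline restraint scores.
* Baseline means and SDs 3.43 ± 1.58 (EDE-Q) and 2.278 ± 1.141 (depression
  on the ÷10 scale), the published baseline table. The baseline
  *correlation* is not published; the default 0.5 is a synthetic-only
  choice in the range typical for ED–depression comorbidity and is
  configurable.
* True paths β_E = −0.45, β_B = −0.65, γ_E = 0.25, γ_B = 0.25, ε_B = 0.30,
  ε_E = 0 — *illustrative* values with the signs the clinical account
  implies (improvement proportional to baseline severity, higher baseline
  severity in either domain worsening the other's trend, depression change
  following ED change). The magnitudes were chosen by hand moment algebra
  so the implied mean changes and follow-up SDs reproduce the published
  follow-up table (≈ −1.0 EDE-Q change, ≈ −0.9 depression change on the
  ÷10 scale, follow-up SDs ≈ 1.68 and 1.22); the disturbance variances
  ψ = (1.74, 0.98) complete that calibration. They are not estimates of the
  source study's coefficients, which are not printed in the available text.
* Scores are generated unbounded (the model is a normal model); an optional
  clamp to instrument ranges exists but is off by default, because clamping
  would bias the very moments the estimator targets.

What passing tests on these cohorts shows — and what it does not. The
recovery and calibration suites demonstrate that the estimator is unbiased,
its Wald intervals hold ~95% coverage, and the difference test holds its
nominal size *when the generating process is the model itself* (multivariate
normal, MCAR dropout). Real questionnaire scores are bounded, discrete,
skewed near the instrument floor, and dropout is at best MAR; the robust
machinery (sandwich errors, mean-scaled χ²) is included precisely because of
that gap, but no synthetic study here certifies behaviour under real-data
violations.

## Problem sizes used in the shipped studies

The acceptance studies use: 10⁶ simulated cases for the moment-structure
oracle (Monte-Carlo SE small enough to detect algebra errors at 4 SEs);
200 replicates of n = 1000 with 22.9% MCAR dropout for bias and coverage;
500 replicates of n = 1000 for type-I calibration of the difference test;
and a single n = 20000 complete cohort for the normality limits of the
scaling factor and the sandwich/information agreement. These sizes give
Monte-Carlo error comfortably below each acceptance band (e.g. the binomial
SE of a 0.05 rejection rate over 500 replicates is ≈ 0.010 against a
[0.03, 0.07] band).

## Known limitations

* Two waves and two constructs only; no latent measurement models below the
  scale scores, no categorical-indicator machinery, no multiple groups.
* Γ for the robust scaling comes from listwise-complete cases (see above).
* FIML assumes conditional multivariate normality; with severely
  non-normal scores the point estimates remain consistent under linearity
  but the likelihood-ratio calibration degrades — use the scaled statistics.
* No auxiliary variables in the missingness model: dropout is assumed MAR
  given the modelled baseline scores themselves.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 42)
cohort <- generate_cohort(cfg)            # 157 cases, ~23% missing follow-up
fit <- fit_model(lcs_variants()$final, cohort)
print(fit)
tab <- comparison_table(cohort)           # the ten-variant battery
print(tab)
```
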