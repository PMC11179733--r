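---
title: "Joint latent class modeling of ICU platelet trajectories: methods and design"
author: "trajsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint latent class modeling of ICU platelet trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajsurv)
```

## The model

`trajsurv` studies heterogeneity in longitudinal platelet counts of septic
ICU patients and its link to 28-day in-hospital mortality through a joint
latent class model (JLCM). The population is assumed to consist of G latent
classes; conditionally on class membership, the longitudinal and survival
processes are independent.

**Longitudinal submodel.** For subject $i$ in class $g$, the platelet count
at scaled time $u = t/28$ follows a linear mixed model with class-specific
cubic fixed effects and shared random effects:
$$Y_{ij} = \beta_{g0} + \beta_{g1} u_{ij} + \beta_{g2} u_{ij}^2 +
\beta_{g3} u_{ij}^3 + b_{0i} + b_{1i} u_{ij} + \varepsilon_{ij},$$
with $(b_{0i}, b_{1i}) \sim N(0, B)$ ($B$ unstructured, shared across
classes) and $\varepsilon_{ij} \sim N(0, \sigma^2)$. The random effects are
integrated out analytically, so the class-conditional likelihood of a
subject's measurement vector is a multivariate normal with covariance
$Z_i B Z_i' + \sigma^2 I$.

**Survival submodel.** Each class has a Weibull baseline hazard with shared
proportional effects of z-scored baseline covariates (APS III, Charlson
comorbidity index, baseline platelet):
$$h_g(t \mid x) = \rho_g \lambda_g (\lambda_g t)^{\rho_g - 1}
e^{x^\top \gamma}, \qquad
S_g(t \mid x) = \exp\{-(\lambda_g t)^{\rho_g} e^{x^\top \gamma}\}.$$

**Membership.** Class priors come from an intercept-only multinomial logit,
$\pi_g = e^{\xi_g} / \sum_h e^{\xi_h}$ with $\xi_G = 0$. With degree-3
trajectories, intercept+slope random effects and 3 covariates the model has
$7G + 6$ free parameters, which is exactly the structure implied by the
information-criterion arithmetic of the class-enumeration table the package
reproduces in its tests.

The joint log-likelihood is
$$\ell = \sum_i \log \sum_g \pi_g \, f_g(Y_i) \,
h_g(T_i \mid x_i)^{\delta_i} S_g(T_i \mid x_i),$$
evaluated with log-sum-exp. Posterior class probabilities $p_{ig}$ follow by
Bayes' rule, and classes are relabeled by descending prior after fitting
(labels in a mixture are arbitrary).

### Scaled time

All polynomial bases use $u = t/28$ rather than raw days: a cubic in raw
days spans six orders of magnitude across its monomials over a 28-day
window and conditions the optimization poorly. Raw days are kept in all
data files.

## Estimation

The likelihood is maximized by BFGS over unconstrained transformed
parameters: $\log\sigma$, $\log\lambda_g$, $\log\rho_g$, and a Cholesky
factor of $B$ with logged diagonal. Two implementation choices matter for
speed and reliability:

- **Sufficient-statistic evaluation.** Because the bases are polynomials,
  every class-conditional marginal Gaussian log-density can be computed from
  per-subject moments $\sum_j u_{ij}^m$ ($m \le 6$), $\sum_j y_{ij} u_{ij}^m$
  ($m \le 3$) and $\sum_j y_{ij}^2$, combined through the Woodbury identity
  for $\sigma^2 I + Z B Z'$ with $q = 2$ random effects. One full likelihood
  evaluation is a handful of O(N) vector operations; no per-subject matrix
  factorizations are needed. A dense Cholesky-based routine
  (`gaussian_class_loglik()`) serves single-subject computations and is the
  cross-check in the tests.
- **Multi-start with EM warm-up.** Each start is seeded from k-means on
  per-subject shape features — window means of the biomarker over days 0–3,
  3–9 and 9–28 *centered by the subject's own overall mean* (which removes
  the dominant random-intercept noise), plus the OLS slope — followed by 25
  EM-style iterations (exact posteriors; approximate M-steps:
  posterior-weighted polynomial OLS for trajectories, closed-form Weibull
  scale given shape, prior update) before the exact BFGS maximization.
  Without the warm-up, gradient ascent from crude cluster assignments
  reliably collapses the smallest class into the dominant one; with it, the
  maximized likelihood reaches or exceeds the true-parameter likelihood on
  simulated cohorts within 3 starts at n = 2000. Additional starts are
  random perturbations of the warm start.

Convergence is declared on relative log-likelihood change (`rel_tol`,
default 1e-6, maximum 500 iterations); per-start diagnostics are retained in
the fit object. Failed covariance factorizations fall back to a 1e-8 jitter.

### Model selection

`select_num_classes()` tabulates log-likelihood, AIC ($2k - 2\ell$), BIC
($k \ln N - 2\ell$), SABIC ($k \ln((N+2)/24) - 2\ell$) and the relative
entropy $E = 1 - \sum_{ig}(-p_{ig} \ln p_{ig}) / (N \ln G)$. Information
criteria typically keep improving as G grows in large cohorts, so the
entropy-maximal G is flagged as selected. At $G = 1$ the classification is
perfect by construction and $E$ is defined as 1; that row is treated as a
convention rather than a candidate, so selection is made among the
multi-class fits.

## Piecewise Cox analysis

Follow-up is split at cut points into counting-process `(start, stop]` rows
(exposure is conserved exactly; the event flag rides on the terminal row),
and a Cox model with class-by-interval indicator terms estimates
per-interval hazard ratios against class 1. The partial likelihood is
maximized by `survival::coxph` with Efron tie handling — appropriate for
daily-resolution event times; the grid-search and split-invariance oracles
in the test suite check it against first principles. The cut point is chosen
by profiling the maximized partial likelihood over candidate days (default
1–14), ties toward the smaller day. Proportional hazards are tested with the
Grambsch–Therneau score test on scaled Schoenfeld residuals against time
(identity transform). Hazard ratios are unadjusted by default; an
`adjusters` argument admits the baseline covariates. Only single cut points
are exercised against reference values; multiple cut points are supported
but not calibrated.

## Dynamic prediction

For a subject event-free at landmark $s$ with history $\mathcal{Y}_i(s)$,
$$w_g(s) \propto \pi_g \, f_g(\mathcal{Y}_i(s)) \, S_g(s \mid x_i), \qquad
\hat S(t \mid s) = \sum_g w_g(s) \frac{S_g(t \mid x_i)}{S_g(s \mid x_i)}.$$
The $S_g(s)$ factor — conditioning the class weights on having survived to
the landmark — is the standard choice for JLCM dynamic prediction and is
adopted here. Design rules:

- The risk set at $s$ contains subjects with $T_i > s$ strictly; a subject
  whose event or censoring time equals the landmark is excluded (no
  zero-length prediction windows).
- Subjects with no measurement before $s$ are scored from
  $\pi_g S_g(s \mid x)$ alone rather than dropped: a day-1 landmark may
  precede the first recorded lab under sparse schedules.
- Measurements after the landmark are a hard error (leakage guard); the
  cohort-level scorer truncates internally and is bit-identical whether or
  not post-landmark rows are present.
- If $S_g(s) < 10^{-12}$ the class weight is zeroed before normalization to
  avoid 0/0; if all weights vanish the prior is used.
- Covariates are standardized with the constants stored at training time;
  new data are never re-standardized.

The static comparator is the Weibull proportional-hazards model on the same
covariates (`fit_static_weibull()`), whose conditional prediction
$S(t|x)/S(s|x)$ ignores all longitudinal history. At $G = 1$ the joint model
factorizes, and the tests verify that its survival submodel coincides with
the static fit to 1e-4.

## Evaluation suite

Per landmark day (1–14 by default) and model: cumulative/dynamic
time-dependent AUC with inverse-probability-of-censoring weights from the
censoring-distribution Kaplan–Meier (cases weighted by $1/\hat G(T_i^-)$;
control weights are common and cancel), Harrell's C-index (ties in risk
score count 1/2), and accuracy/sensitivity/specificity at a configurable
risk threshold (default 0.5) among subjects with a determinate 28-day
outcome — subjects censored strictly inside the window are excluded from the
confusion metrics but retained, via IPCW, in the AUC. Confidence intervals
are subject-level percentile bootstrap (default B = 2000); model comparisons
use a paired sign-flip permutation test (each subject's pair of predictions
is swapped with probability 1/2; default 2000 permutations,
$p = (1 + \#\{|\Delta^*| \ge |\Delta|\})/(B+1)$). A `naive` AUC variant that
drops within-window censored subjects is retained for comparison.

## The synthetic cohort generator

`default_cohort_config()` encodes the study conditions the pipeline is
exercised under: four classes in proportions 6.83 / 79.44 / 4.52 / 9.21 %,
28-day window, daily measurement grid. Choices that were genuinely open and
how they were fixed:

- **Trajectory shapes.** The four cubic coefficient sets (on $u = t/28$,
  units $\times 10^9$/L) realize the qualitative shapes: an inverted U
  peaking at ~305 mid-window from 185; a mild monotone increase from 167 to
  ~212; a decline from 178 crossing the thrombocytopenia threshold
  (150) before day 3, bottoming at ~126 and recovering above 150 to level at
  ~178; and a rapid fall from 258 stabilizing slightly below 150 (~147). A
  cubic on the unit interval cannot combine an arbitrarily deep dip in the
  first tenth of the window with a bounded later rise — the integral of the
  required derivative explodes — so the dip class crosses 150 early (day
  ~2.9) with its minimum near day 9; this also reproduces the clinical
  observation that the persistent-decline class reaches thrombocytopenia
  *later* than the transient-dip class.
- **Hazards.** Class Weibull parameters
  $(\lambda, \rho)$ = (0.0075, 1), (0.0165, 1), (0.0104, 0.6), (0.0451, 1.4)
  give 28-day mortality ordered class 1 (0.19) < class 3 (0.38) ≈ class 2
  (0.37) < class 4 (0.75) at mean covariates, with the dip class
  front-loading deaths before day 3 ($\rho < 1$) and the persistent-decline
  class accelerating ($\rho > 1$). Together with exponential discharge
  censoring at rate 0.08/day (median stay ~8.7 days, matching typical
  hospital length of stay) these were calibrated once, by Monte Carlo,
  to an observed in-hospital death fraction of ~18–19%, and then frozen.
- **Covariates.** APS III ~ N(58, 24²) and CCI ~ N(5, 3²) (floored at
  1 and 0), log-hazard effects 0.45 and 0.25 per generating SD; baseline
  platelet is the class intercept plus N(0, 30²) noise (a missing baseline
  is an exclusion criterion, so every subject has one) with protective
  effect −0.2 per 30 units. Tying the baseline to the class makes the
  static comparator honestly competitive at early landmarks, and keeps the
  conditional-independence assumption of the JLCM exactly true.
- **Measurement schedule.** Daily grid with Bernoulli thinning at rate 0.15,
  except that the admission (day 0) lab is always present and a final lab is
  drawn at the end of follow-up, mirroring ICU practice. This also makes the
  two-measurements inclusion filter essentially non-selective: without it,
  redrawing subjects who die before their second lab preferentially removes
  early deaths and visibly biases the fitted Weibull shapes, a selection
  effect the fitted model (like the analyses it emulates) does not model.
- **Random effects.** Intercept SD 32, slope SD 25 (per unit of scaled
  time), correlation −0.2, residual SD 20 — between-subject spread large
  enough that marginal platelet variability matches an IQR of roughly
  110–235, small enough that the classes remain identifiable: the
  Bayes-optimal modal accuracy of the frozen configuration is 0.936
  (n = 20000).

Subjects violating the two-measurement filter (now a negligible fraction)
are redrawn rather than dropped so the cohort size is exact. Values are
floored at $1 \times 10^9$/L. The generator does **not** emulate treatments
(transfusion, vasopressors), competing risks, informative missingness, or
measurement-time clustering; passing tests therefore demonstrate correctness
of the estimators under the stated generating model, not robustness to those
real-data features.

A companion generator, `simulate_piecewise_cohort()`, draws survival-only
cohorts with class-linked piecewise-constant hazards changing at a single
cut point (defaults: hazard ratios 3.90/13.86/2.84 before and 2.32/2.95/6.09
after day 3 against class 1, balanced class sizes, baseline hazard 0.01/day)
for the cut-point-search and hazard-ratio recovery experiments.

## Problem sizes used by the tests

The suite is sized to run comfortably on one CPU: likelihood oracles on
5–50 subjects; one-class recovery at n = 4000; four-class recovery at
n = 2000 with 3 starts; cut-point recovery over 20 seeds at n = 5000;
hazard-ratio recovery at n = 5000; null calibration of the
proportional-hazards test with 200 replicates at n = 2000 and of the
permutation test with 200 replicates at n = 120; the landmark
discrimination-direction experiment trains once at n = 1500 and evaluates on
20 validation cohorts of n = 800 across landmarks 1–14, testing the sign of
the per-seed slope of the C-index advantage. Bootstrap and permutation sizes
default to 2000 in the API and are reduced (40–400) in tests.

## Known limitations

- Class-number recovery of Weibull parameters for rare classes is
  information-limited: a 6.8% class in a cohort of 2000 with ~19% observed
  mortality contributes on the order of a dozen deaths, so its
  $(\lambda, \rho)$ estimates carry log-scale standard errors of ~0.5 and
  cannot be pinned to better than tens of percent regardless of optimizer
  quality. Trajectory and membership recovery are unaffected.
- The membership model is intercept-only; covariates influencing class
  membership are out of scope, as are spline bases, class-specific
  random-effect covariances, frailties and competing risks.
- Dynamic predictions do not carry parameter uncertainty (no prediction
  intervals), and model parameters are never updated at prediction time.
- The entropy-maximal selection rule is a heuristic; with weakly separated
  classes the entropy column can be noisy, and the full table should be
  inspected.
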