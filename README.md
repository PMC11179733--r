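# trajsurv

Joint latent class modeling and dynamic survival prediction for platelet
trajectories in septic ICU patients.

Septic patients admitted to intensive care show markedly heterogeneous
platelet-count dynamics — some recover, some develop persistent
thrombocytopenia — and these dynamics carry prognostic information that a
single baseline measurement cannot. `trajsurv` implements the full analytic
pipeline for studying this heterogeneity and exploiting it for prediction:

1. **Subpopulation identification.** Maximum-likelihood estimation of a
   G-class *joint latent class model* (JLCM). Each latent class g has its own
   mean platelet trajectory — a cubic polynomial in scaled time u = t/28 —
   with shared subject-level random intercept and slope and residual noise,
   and its own Weibull survival submodel with proportional covariate effects:

   - longitudinal: Y_ij | class g ~ N(W_ij' β_g + Z_ij' b_i, σ²),
     b_i ~ N(0, B)
   - survival: h_g(t | x) = ρ_g λ_g (λ_g t)^(ρ_g − 1) exp(x'γ)
   - membership: π_g from an intercept-only multinomial logit

   The number of classes is chosen from AIC / BIC / sample-size-adjusted BIC
   (SABIC) and the relative entropy of the posterior classification,
   E = 1 − Σ_i Σ_g (−p_ig ln p_ig) / (N ln G).

2. **Time-dependent hazard ratios.** Piecewise Cox regression on
   counting-process data with class-by-interval hazard ratios; the cut point
   is selected by maximizing the partial likelihood over candidate days, and
   a Grambsch–Therneau score test flags proportional-hazards violations.

3. **Landmark dynamic prediction.** For a subject alive at landmark day s
   with accumulated history Y(s), the conditional survival to horizon t is
   Ŝ(t|s) = Σ_g w_g(s) S_g(t|x) / S_g(s|x) with Bayes weights
   w_g(s) ∝ π_g f_g(Y(s)) S_g(s|x). A static Weibull model on the same
   baseline covariates (APS III, Charlson comorbidity index, baseline
   platelet) is the comparator.

4. **Evaluation.** Time-dependent AUC (IPCW cumulative/dynamic), Harrell's
   C-index, accuracy, sensitivity and specificity per landmark day, with
   percentile bootstrap confidence intervals and paired sign-flip permutation
   tests comparing the two models.

Because the clinical databases this methodology targets are credentialed, the
package ships a **synthetic-cohort generator** (`simulate_cohort()`) whose
default configuration emulates the structure of a large septic ICU cohort:
four trajectory classes in proportions 6.83 / 79.44 / 4.52 / 9.21 %
(inverted-U, slight-increase, decrease-increase-intermediate, decrease-low),
class-linked Weibull mortality ordered class 1 < class 3 ≈ class 2 < class 4,
daily labs with missingness, exponential discharge censoring and
administrative censoring at day 28.

## Worked example

```r
library(trajsurv)

cohort <- simulate_cohort(default_cohort_config(n_subjects = 2000, seed = 42))
fit <- fit_jlcm(cohort$longitudinal, cohort$subjects,
                jlcm_spec(n_classes = 4, n_starts = 3, seed = 1))
print(fit)
#> Joint latent class model fit: 4 class(es), 2000 subjects, 378 events
#>   log-likelihood -92039.19 (34 parameters), converged: TRUE
#>   class priors: 0.790 0.089 0.083 0.038
#>   modal class sizes: 1664/172/118/46

round(information_criteria(fit$loglik, fit$n_params, fit$n_subjects), 1)
#>      AIC      BIC    SABIC
#> 184146.4 184336.8 184228.8
relative_entropy(fit$posterior)
#> 0.856
```

The fit recovers the four latent trajectory groups (priors 0.790 / 0.089 /
0.083 / 0.038 against the generating 0.794 / 0.092 / 0.068 / 0.045; classes
are labeled by descending prior) with mean posterior probabilities of the
assigned class between 0.80 and 0.96. With 34 free parameters for G = 4
(4 trajectory coefficients per class, G − 1 membership logits, 3
random-effects covariance terms, 1 residual SD, 2 Weibull parameters per
class, 3 covariate effects), the criteria above are the basis of the
class-number selection table produced by `select_num_classes()`.

Time-dependent hazard ratios on a cohort with a genuine hazard change at
day 3 (class 1 is the reference):

```r
pwc <- simulate_piecewise_cohort(5000, seed = 7)
search_cutpoint(pwc, pwc$class, 1:14)$best
#> 3
fit_piecewise_cox(pwc, pwc$class, 3)$hr_table
#>     term interval    HR  lo95  hi95         p
#>   class2    (0,3]  4.54  3.08  6.70  2.70e-14
#>   class2  (3,Inf]  2.23  1.92  2.58  8.26e-27
#>   class3    (0,3] 16.01 11.12 23.06  3.48e-50
#>   class3  (3,Inf]  2.88  2.48  3.34  1.86e-43
#>   class4    (0,3]  3.21  2.14  4.81  1.49e-08
#>   class4  (3,Inf]  5.65  4.93  6.46 3.68e-139
```

The likelihood profile selects the true change point (day 3), and the
hazard-ratio pattern matches the generating regime: the transient-dip class
(class 3) carries the highest early hazard ratio, the persistent-decline
class (class 4) the highest late hazard ratio.

Landmark comparison of the dynamic model against the static Weibull
comparator (C-index, bootstrap 95% CI, paired permutation p):

```r
sw <- fit_static_weibull(cohort$subjects)
rep <- landmark_evaluation(fit, sw, cohort$longitudinal, cohort$subjects,
                           landmarks = c(1, 7, 14), B = 200, n_perm = 200,
                           seed = 1)
subset(as.data.frame(rep), metric == "cindex")
#>  landmark      model metric estimate  lo95  hi95 p_perm
#>         1    dynamic cindex   0.6693 0.637 0.700     NA
#>         1     static cindex   0.6557 0.618 0.689     NA
#>         1 difference cindex   0.0135    NA    NA 0.0647
#>         7    dynamic cindex   0.6581 0.611 0.696     NA
#>         7     static cindex   0.6458 0.602 0.686     NA
#>         7 difference cindex   0.0123    NA    NA 0.2090
#>        14    dynamic cindex   0.6635 0.606 0.722     NA
#>        14     static cindex   0.6520 0.585 0.708     NA
#>        14 difference cindex   0.0115    NA    NA 0.5224
```

`individual_prediction_series()` produces the per-patient view: a prediction
refreshed at successive landmark days using only the labs observed so far.

A thin command-line wrapper over the pipeline stages (simulate / fit /
analyze / predict) is installed at `inst/cli/trajsurv.R`.

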