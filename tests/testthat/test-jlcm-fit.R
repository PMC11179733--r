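test_that("information criteria reproduce the standard arithmetic", {
  # frozen selection-table arithmetic: printed log-likelihoods and the
  # k = 7G + 6 parameter count at N = 11016 reproduce the printed AIC, BIC
  # and SABIC to the rounding of the log-likelihood (1 decimal)
  printed <- data.frame(
    G = 1:6,
    loglik = c(-368180.9, -361110.7, -357940.8, -356005.9, -354668.9,
               -353406.6),
    AIC = c(736387.7, 722261.5, 715935.5, 712079.8, 709419.7, 706909.2),
    BIC = c(736482.7, 722407.6, 716132.8, 712328.3, 709719.3, 707259.9),
    SABIC = c(736441.4, 722344.0, 716047.0, 712220.2, 709589.0, 707107.4))
  for (r in seq_len(nrow(printed))) {
    k <- 7 * printed$G[r] + 6
    ic <- information_criteria(printed$loglik[r], k, 11016)
    expect_lt(abs(ic["AIC"] - printed$AIC[r]), 0.2)
    expect_lt(abs(ic["BIC"] - printed$BIC[r]), 0.2)
    expect_lt(abs(ic["SABIC"] - printed$SABIC[r]), 0.2)
  }
  expect_equal(unname(information_criteria(0, 0, 10)), c(0, 0, 0))
  expect_error(information_criteria(0, 0, 0), "n_subjects")
})

test_that("parameter counts follow the model structure", {
  for (G in 1:6)
    expect_equal(jlcm_n_params(jlcm_spec(n_classes = G)), 7 * G + 6)
  expect_equal(jlcm_n_params(jlcm_spec(n_classes = 2, poly_degree = 1,
                                       random_effects = "intercept")),
               2 * 2 + 1 + 1 + 1 + 4 + 3)
})

test_that("relative entropy follows its conventions and oracle", {
  onehot <- diag(4)[c(1, 2, 3, 4, 1), ]
  expect_equal(relative_entropy(onehot), 1)
  expect_equal(relative_entropy(matrix(0.25, 5, 4)), 0)
  p <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  ent <- -sum(p * log(p))
  expect_equal(relative_entropy(p), 1 - ent / (2 * log(2)))
  # single-class convention
  expect_equal(relative_entropy(matrix(1, 7, 1)), 1)
  expect_error(relative_entropy(matrix(0.4, 3, 2)), "sum to 1")
})

test_that("a one-class fit recovers the generating parameters", {
  cfg <- default_cohort_config(n_subjects = 4000, seed = 19)
  cfg$classes <- list(class_spec(1, c(180, 40, -30, 0),
                                 weibull_scale = 0.02, weibull_shape = 1.2,
                                 label = "single"))
  cfg$discharge_rate <- 0.02
  co <- simulate_cohort(cfg)
  fit <- fit_jlcm(co$longitudinal, co$subjects,
                  jlcm_spec(n_classes = 1, n_starts = 2, seed = 8))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$sigma / cfg$resid_sd - 1), 0.1)
  expect_lt(abs(fit$params$weibull[1, "lambda"] / 0.02 - 1), 0.1)
  expect_lt(abs(fit$params$weibull[1, "rho"] / 1.2 - 1), 0.1)
  # the individual cubic coefficients are collinear; the identified object
  # is the mean trajectory, compared as relative RMSE over the window
  u <- seq(0, 1, length.out = 57)
  Wg <- cbind(1, u, u^2, u^3)
  curve_true <- drop(Wg %*% c(180, 40, -30, 0))
  curve_fit <- drop(Wg %*% fit$params$beta[, 1])
  expect_lt(sqrt(mean((curve_fit / curve_true - 1)^2)), 0.1)
  # covariate effects on the generator's standardization scale
  expect_lt(max(abs(fit$params$gamma - cfg$covariate_effects)), 0.1)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, 4000))
})

test_that("refitting with the same seed reproduces the likelihood
           exactly and posteriors are row-stochastic", {
  co <- small_cohort(n = 150, seed = 55)
  spec <- jlcm_spec(n_classes = 2, n_starts = 2, seed = 12)
  f1 <- fit_jlcm(co$longitudinal, co$subjects, spec)
  f2 <- fit_jlcm(co$longitudinal, co$subjects, spec)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params$beta, f2$params$beta)
  expect_true(all(abs(rowSums(f1$posterior) - 1) < 1e-9))
  # classes are labeled by descending prior
  pri <- class_prior(f1$params$xi)
  expect_true(all(diff(pri) <= 1e-12))
})

test_that("fit preconditions are enforced", {
  co <- small_cohort(n = 12, seed = 5)
  expect_error(fit_jlcm(co$longitudinal, co$subjects,
                        jlcm_spec(n_classes = 4)), "at least 20 subjects")
  lon <- co$longitudinal[!duplicated(co$longitudinal$subject_id), ]
  expect_error(fit_jlcm(lon, co$subjects, jlcm_spec(n_classes = 1)),
               ">= 2")
})

test_that("select_num_classes tabulates nested fits with increasing
           log-likelihood", {
  co <- small_cohort(n = 300, seed = 71)
  sel <- select_num_classes(co$longitudinal, co$subjects, 1:2,
                            jlcm_spec(n_starts = 2, seed = 6))
  expect_equal(nrow(sel), 2L)
  expect_false(any(sel$failed))
  expect_true(diff(sel$loglik) > 0)      # nesting: more classes fit better
  expect_equal(sel$k, 7 * (1:2) + 6)
  expect_equal(sel$entropy[sel$G == 1], 1)
  expect_equal(attr(sel, "selected"), 2L)
  expect_equal(sel$prop_1[1], 1)

  sel1 <- select_num_classes(co$longitudinal, co$subjects, 1,
                             jlcm_spec(n_starts = 1, seed = 6))
  expect_equal(sel1$entropy, 1)
  expect_equal(attr(sel1, "selected"), 1L)
})

test_that("posterior_quality summarizes modal-class assignment sharpness", {
  onehot <- diag(3)[rep(1:3, times = c(5, 3, 2)), ]
  q <- posterior_quality(onehot)
  expect_equal(q$n, c(5, 3, 2))
  expect_equal(q$mean_posterior, rep(1, 3))
  expect_true(all(q$frac_gt_0.9 == 1))

  p <- rbind(c(0.6, 0.4), c(0.8, 0.2))
  q2 <- posterior_quality(p, thresholds = 0.7)
  expect_equal(q2$n, c(2, 0))
  expect_equal(q2$mean_posterior[1], 0.7)
  expect_equal(q2$frac_gt_0.7[1], 0.5)
  expect_true(is.na(q2$mean_posterior[2]))

  q3 <- posterior_quality(p, thresholds = numeric(0))
  expect_named(q3, c("class", "n", "mean_posterior"))
})

test_that("the static Weibull comparator recovers a Weibull PH law and
           matches the G = 1 joint fit", {
  set.seed(99)
  n <- 2000
  x <- cbind(aps3 = rnorm(n), cci = rnorm(n), platelet_baseline = rnorm(n))
  gam <- c(0.5, -0.3, 0.2)
  lam <- 0.03; rho <- 1.4
  e <- rexp(n)
  Tm <- (e / exp(drop(x %*% gam)))^(1 / rho) / lam
  cen <- pmin(rexp(n, 0.02), 28)
  sub <- data.frame(subject_id = 1:n, aps3 = x[, 1], cci = x[, 2],
                    platelet_baseline = x[, 3],
                    time_days = pmin(Tm, cen),
                    event = as.integer(Tm <= cen))
  sw <- fit_static_weibull(sub)
  expect_true(sw$converged)
  expect_lt(abs(sw$lambda / lam - 1), 0.1)
  expect_lt(abs(sw$rho / rho - 1), 0.1)
  expect_lt(max(abs(sw$gamma - gam)), 0.1)

  # exponential special case: with pure-noise covariates, lambda is close
  # to the events/exposure rate
  set.seed(100)
  T2 <- rexp(500, 0.05)
  sub2 <- data.frame(subject_id = 1:500, aps3 = rnorm(500),
                     cci = rnorm(500), platelet_baseline = rnorm(500),
                     time_days = T2, event = 1L)
  sw2 <- fit_static_weibull(sub2)
  expect_lt(abs(sw2$lambda / (500 / sum(T2)) - 1), 0.05)
  expect_lt(abs(sw2$rho - 1), 0.1)

  # internal consistency: G = 1 joint fit yields the same survival
  # submodel parameters (the likelihood factorizes)
  co <- small_cohort(n = 400, seed = 9)
  f1 <- fit_jlcm(co$longitudinal, co$subjects,
                 jlcm_spec(n_classes = 1, n_starts = 1, rel_tol = 1e-12,
                           seed = 2))
  swj <- fit_static_weibull(co$subjects)
  expect_lt(abs(f1$params$weibull[1, "lambda"] / swj$lambda - 1), 1e-4)
  expect_lt(abs(f1$params$weibull[1, "rho"] / swj$rho - 1), 1e-4)
  expect_lt(max(abs(f1$params$gamma - swj$gamma)), 1e-4)

  expect_error(fit_static_weibull(sub2[1:5, ]), "at least 10")
  sub0 <- sub2; sub0$event <- 0L
  expect_error(fit_static_weibull(sub0), "at least one event")
})

test_that("shifting a survival covariate changes the stored
           standardization but not the fitted likelihood", {
  co <- small_cohort(n = 200, seed = 13)
  f_a <- fit_static_weibull(co$subjects)
  shifted <- co$subjects
  shifted$aps3 <- shifted$aps3 + 100
  f_b <- fit_static_weibull(shifted)
  expect_equal(f_a$loglik, f_b$loglik, tolerance = 1e-6)
  expect_equal(f_b$covariate_standardization$mean[["aps3"]],
               f_a$covariate_standardization$mean[["aps3"]] + 100)
  expect_equal(f_a$gamma, f_b$gamma, tolerance = 1e-4)
})
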