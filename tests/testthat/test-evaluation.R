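test_that("Kaplan-Meier estimator matches the product over risk sets", {
  expect_error(km_estimator(numeric(0), numeric(0)), "empty")
  km0 <- km_estimator(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  km <- km_estimator(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  set.seed(8)
  tt <- round(rexp(40, 0.1), 2)
  ev <- rbinom(40, 1, 0.6)
  km2 <- km_estimator(tt, ev)
  # brute-force product over event times
  s_or <- 1
  oracle <- vapply(km2$time, function(u) {
    s_loc <- 1
    for (d in sort(unique(tt[ev == 1 & tt <= u]))) {
      n_risk <- sum(tt >= d)
      n_ev <- sum(tt == d & ev == 1)
      s_loc <- s_loc * (1 - n_ev / n_risk)
    }
    s_loc
  }, numeric(1))
  expect_equal(km2$survival, oracle, tolerance = 1e-12)
})

test_that("log-rank test matches hand computation and degenerates to zero
           on cloned groups", {
  tt <- c(3, 1, 4, 7, 2, 9)
  ev <- c(1, 0, 1, 1, 0, 0)
  lr <- logrank_test(c(tt, tt), c(ev, ev), rep(1:2, each = 6))
  expect_lt(lr$statistic, 1e-10)

  # two subjects, one per group, one event: O - E = 0.5, V = 0.25
  lr2 <- logrank_test(c(1, 2), c(1, 0), c("a", "b"))
  expect_equal(lr2$statistic, 1, tolerance = 1e-12)
  expect_equal(lr2$p, pchisq(1, 1, lower.tail = FALSE))
  expect_error(logrank_test(c(1, 2), c(1, 0), c("a", "a")), "two groups")

  # strongly separated Weibull groups
  set.seed(3)
  t1 <- rweibull(250, 1.2, 30); t2 <- rweibull(250, 1.2, 8)
  tt <- pmin(c(t1, t2), 28)
  ev <- as.integer(c(t1, t2) <= 28)
  expect_lt(logrank_test(tt, ev, rep(1:2, each = 250))$p, 0.001)
})

test_that("concordance index equals exhaustive pair enumeration", {
  # perfect inverse ordering, no censoring
  tt <- c(5, 3, 9, 1, 7)
  expect_equal(concordance_index(-tt, tt, rep(1, 5))$c_index, 1)
  # constant risk: all ties
  expect_equal(concordance_index(rep(2, 5), tt, rep(1, 5))$c_index, 0.5)

  set.seed(12)
  n <- 30
  tt <- round(rexp(n, 0.1), 1)
  ev <- rbinom(n, 1, 0.7)
  r <- rnorm(n)
  got <- concordance_index(r, tt, ev)
  conc <- disc <- tied <- 0
  for (i in 1:n) for (j in 1:n) {
    if (ev[i] == 1 && tt[i] < tt[j]) {
      if (r[i] > r[j]) conc <- conc + 1
      else if (r[i] < r[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  expect_equal(got$n_concordant, conc)
  expect_equal(got$n_discordant, disc)
  expect_equal(got$n_tied, tied)
  expect_equal(got$c_index, (conc + 0.5 * tied) / (conc + disc + tied))
  # cross-check against the survival package on uncensored data
  cs <- survival::concordance(survival::Surv(tt, rep(1, n)) ~ r,
                              reverse = TRUE)
  expect_equal(concordance_index(r, tt, rep(1, n))$c_index,
               unname(cs$concordance), tolerance = 1e-12)

  expect_error(concordance_index(1, 5, 0), "usable")
})

test_that("time-dependent AUC equals the Mann-Whitney oracle without
           censoring and is calibrated for random scores", {
  set.seed(9)
  n <- 120
  tt <- runif(n, 1, 27.9)
  ev <- rep(1L, n)
  r <- -tt + rnorm(n, 0, 3)
  s <- 0.5; t <- 14
  case <- ev == 1 & tt <= t & tt > s
  ctrl <- tt > t
  mw <- mean(outer(r[case], r[ctrl],
                   function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(time_dependent_auc(r, tt, ev, s, t), mw, tolerance = 1e-12)
  expect_equal(time_dependent_auc(r, tt, ev, s, t, method = "naive"), mw,
               tolerance = 1e-12)
  # perfectly separating scores
  expect_equal(time_dependent_auc(-tt, tt, ev, s, t), 1)

  set.seed(10)
  n <- 4000
  tt <- runif(n, 1, 28)
  r <- runif(n)
  auc <- time_dependent_auc(r, tt, rep(1L, n), 0.5, 14)
  expect_lt(abs(auc - 0.5), 0.03)

  expect_error(time_dependent_auc(r, tt, rep(0L, n), 0.5, 14), "cases")
})

test_that("confusion metrics implement the 2x2 table", {
  cm <- confusion_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(cm$accuracy, 1)
  cm2 <- confusion_metrics(c(0.9, 0.8, 0.1), 1 - c(1, 1, 0))
  expect_equal(cm2$sensitivity, 0)
  expect_equal(cm2$specificity, 0)
  # TP=3, FN=1, FP=2, TN=4
  risk <- c(rep(0.9, 3), 0.1, rep(0.9, 2), rep(0.1, 4))
  out <- c(rep(1, 4), rep(0, 6))
  cm3 <- confusion_metrics(risk, out)
  expect_equal(cm3$sensitivity, 0.75)
  expect_equal(cm3$specificity, 2 / 3)
  expect_equal(cm3$accuracy, 0.7)
  cm4 <- confusion_metrics(c(0.9, 0.1), c(1, 1))
  expect_true(is.na(cm4$specificity))
})

test_that("bootstrap confidence intervals are reproducible and match the
           CLT width for a sample mean", {
  x <- rnorm(50)
  cc <- bootstrap_ci(function(i) 3, length(x), B = 50, seed = 1)
  expect_equal(cc$lo95, 3)
  expect_equal(cc$hi95, 3)

  set.seed(77)
  x <- rnorm(200)
  bc <- bootstrap_ci(function(i) mean(x[i]), 200, B = 2000, seed = 2)
  width <- bc$hi95 - bc$lo95
  expect_lt(abs(width / (2 * 1.96 * sd(x) / sqrt(200)) - 1), 0.2)
  bc2 <- bootstrap_ci(function(i) mean(x[i]), 200, B = 2000, seed = 2)
  expect_identical(bc, bc2)
  expect_true(bc$lo95 <= bc$point && bc$point <= bc$hi95)

  expect_error(bootstrap_ci(function(i) mean(x[i]), 200, B = 5), "B must")
  # resamples with duplicated subjects make the metric undefined
  degen <- function(i) if (anyDuplicated(i)) NA_real_ else 1
  expect_error(bootstrap_ci(degen, 20, B = 20, seed = 1), "degenerate")
})

test_that("paired permutation comparison is exact under identity, powerful
           under separation and calibrated under exchangeability", {
  cmetric <- function(r, t_, e_) concordance_index(r, t_, e_)$c_index
  set.seed(5)
  n <- 200
  tt <- rexp(n, 0.1)
  ev <- rep(1L, n)
  rA <- -tt + rnorm(n, 0, 1)
  pc <- permutation_compare(rA, rA, tt, ev, cmetric, n_perm = 50, seed = 1)
  expect_equal(pc$p_value, 1)
  expect_error(permutation_compare(rA[-1], rA, tt, ev, cmetric),
               "paired")

  rB <- rnorm(n)
  pc2 <- permutation_compare(rA, rB, tt, ev, cmetric, n_perm = 400,
                             seed = 2)
  expect_lt(pc2$p_value, 0.01)

  # type-I error for exchangeable noisy copies
  rej <- 0L
  for (r in 1:200) {
    set.seed(6000 + r)
    m <- 120
    t2 <- rexp(m, 0.1)
    base <- -t2 + rnorm(m, 0, 2)
    a <- base + rnorm(m)
    b <- base + rnorm(m)
    p <- permutation_compare(a, b, t2, rep(1L, m), cmetric, n_perm = 99,
                             seed = r)$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.09)
})

test_that("landmark evaluation emits a tidy, order-invariant report", {
  co <- small_cohort(n = 300, seed = 91, discharge_rate = 0)
  fit <- fit_jlcm(co$longitudinal, co$subjects,
                  jlcm_spec(n_classes = 2, n_starts = 1, seed = 4))
  sw <- fit_static_weibull(co$subjects)
  rep1 <- landmark_evaluation(fit, sw, co$longitudinal, co$subjects,
                              landmarks = 1, B = 50, n_perm = 50, seed = 3)
  # no censoring before day 28: every metric defined
  est <- rep1[rep1$model %in% c("dynamic", "static"), ]
  expect_equal(nrow(est), 10L)
  expect_false(any(is.na(est$estimate)))
  expect_true(all(est$estimate >= 0 & est$estimate <= 1))
  cis <- est[est$metric %in% c("cindex", "auc"), ]
  expect_true(all(cis$lo95 <= cis$estimate + 1e-12 &
                    cis$estimate <= cis$hi95 + 1e-12))
  expect_true(all(rep1$p_perm[rep1$model == "difference"] > 0))

  # shuffling subject order leaves the report unchanged
  perm <- sample(nrow(co$subjects))
  rep2 <- landmark_evaluation(fit, sw,
                              co$longitudinal,
                              co$subjects[perm, ],
                              landmarks = 1, B = 50, n_perm = 50, seed = 3)
  expect_equal(rep1$estimate, rep2$estimate, tolerance = 1e-12)

  # landmark counting
  rep3 <- landmark_evaluation(fit, sw, co$longitudinal, co$subjects,
                              landmarks = c(1, 7), B = 50, n_perm = 50,
                              seed = 3)
  expect_equal(unique(rep3$landmark), c(1, 7))
  expect_equal(sum(rep3$model == "dynamic"), 10L)
})
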