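# brute-force Cox partial log-likelihood (Breslow risk sets, no ties in
# the constructed data) for a single binary covariate
.plik_oracle <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

test_that("split_followup partitions follow-up and conserves exposure", {
  sub <- data.frame(subject_id = 1:2, time_days = c(10, 2),
                    event = c(1, 0))
  ct <- split_followup(sub, c(1, 1), 3)
  r1 <- ct[ct$subject_id == 1, ]
  expect_equal(r1$start, c(0, 3))
  expect_equal(r1$stop, c(3, 10))
  expect_equal(r1$event, c(0, 1))
  r2 <- ct[ct$subject_id == 2, ]
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$stop, r2$event), c(0, 2, 0))

  co <- small_cohort(n = 200, seed = 3)
  ct2 <- split_followup(co$subjects, co$true_class, c(3, 7, 14))
  expo <- tapply(ct2$stop - ct2$start, ct2$subject_id, sum)
  expect_equal(as.numeric(expo[as.character(co$subjects$subject_id)]),
               co$subjects$time_days)
  ev <- tapply(ct2$event, ct2$subject_id, sum)
  expect_equal(as.numeric(ev[as.character(co$subjects$subject_id)]),
               as.numeric(co$subjects$event))

  expect_error(split_followup(sub, c(1, 1), 0), "strictly inside")
  expect_error(split_followup(sub, c(1, 1), 11), "strictly inside")
})

test_that("fit_cox matches grid-search partial-likelihood maximization on
           hand-enumerable data", {
  # six subjects, two groups, no ties
  sub <- data.frame(subject_id = 1:6,
                    time_days = c(1, 2, 3, 4, 5, 6),
                    event = c(1, 1, 0, 1, 1, 0))
  grp <- c(1, 0, 1, 0, 1, 0)
  ct <- split_followup(sub, grp, numeric(0))
  ct$grp <- grp[match(ct$subject_id, sub$subject_id)]
  fit <- fit_cox(ct, "grp")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, .plik_oracle, numeric(1), time = sub$time_days,
               event = sub$event, x = grp)
  expect_lt(abs(fit$coef[["grp"]] - grid[which.max(ll)]), 1e-4 + 1e-8)
  expect_equal(fit$partial_loglik, max(ll), tolerance = 1e-6)
})

test_that("cloned groups give a null coefficient and late cut points do
           not change the fit", {
  co <- small_cohort(n = 120, seed = 8)
  sub <- co$subjects
  clone <- sub
  clone$subject_id <- clone$subject_id + 1000
  both <- rbind(sub, clone)
  grp <- rep(c(0, 1), each = nrow(sub))
  ct <- split_followup(both, grp, numeric(0))
  ct$grp <- grp[match(ct$subject_id, both$subject_id)]
  fit <- fit_cox(ct, "grp")
  expect_lt(abs(fit$coef[["grp"]]), 1e-8)

  # cut point beyond the last event: split fit identical to unsplit
  tau <- max(sub$time_days[sub$event == 1]) + 0.5
  ct_u <- split_followup(sub, co$true_class, numeric(0))
  ct_s <- split_followup(sub, co$true_class, tau)
  ct_u$g4 <- as.integer(ct_u$class == 4)
  ct_s$g4 <- as.integer(ct_s$class == 4)
  f_u <- fit_cox(ct_u, "g4")
  f_s <- fit_cox(ct_s, "g4")
  expect_equal(f_u$coef, f_s$coef, tolerance = 1e-8)
  expect_equal(f_u$partial_loglik, f_s$partial_loglik, tolerance = 1e-8)
})

test_that("splitting without interaction terms leaves the partial
           likelihood unchanged", {
  co <- small_cohort(n = 150, seed = 21)
  sub <- co$subjects
  cls <- co$true_class
  ct_u <- split_followup(sub, cls, numeric(0))
  ct_s <- split_followup(sub, cls, c(3, 10))
  for (g in 2:4) {
    ct_u[[paste0("c", g)]] <- as.integer(ct_u$class == g)
    ct_s[[paste0("c", g)]] <- as.integer(ct_s$class == g)
  }
  f_u <- fit_cox(ct_u, c("c2", "c3", "c4"))
  f_s <- fit_cox(ct_s, c("c2", "c3", "c4"))
  expect_equal(f_u$partial_loglik, f_s$partial_loglik, tolerance = 1e-10)
  expect_equal(f_u$coef, f_s$coef, tolerance = 1e-8)
})

test_that("fit_piecewise_cox reproduces class-by-interval hazard ratios", {
  # degenerate split: one interval == standard Cox with class dummies
  d <- simulate_piecewise_cohort(800, seed = 31)
  pw <- fit_piecewise_cox(d, d$class, numeric(0))
  ct <- split_followup(d, d$class, numeric(0))
  for (g in 2:4) ct[[paste0("c", g)]] <- as.integer(ct$class == g)
  ref <- fit_cox(ct, c("c2", "c3", "c4"))
  expect_equal(unname(pw$coef), unname(ref$coef), tolerance = 1e-10)
  # reference class has no rows in the HR table: its HR is 1 by definition
  expect_false("class1" %in% pw$hr_table$term)
  expect_equal(nrow(pw$hr_table), 3L)

  # recovery of the generating hazard ratios at a known cut point
  d2 <- simulate_piecewise_cohort(4000, seed = 32)
  pw2 <- fit_piecewise_cox(d2, d2$class, 3)
  hr <- pw2$hr_table
  h43 <- hr$HR[hr$term == "class4" & hr$interval == "(3,Inf]"]
  expect_lt(abs(h43 / 6.09 - 1), 0.25)
  # covariance is symmetric PSD and coefficient count is terms x intervals
  expect_equal(pw2$vcov, t(pw2$vcov), tolerance = 1e-12)
  expect_true(all(eigen(pw2$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_equal(length(pw2$coef), 3 * 2)
})

test_that("an empty class-interval cell is marked non-estimable", {
  d <- simulate_piecewise_cohort(300, class_probs = c(0.45, 0.45, 0.05,
                                                      0.05),
                                 baseline_hazard = c(0.002, 0.002),
                                 hr_pre = c(1, 2, 1, 1),
                                 hr_post = c(1, 2, 1, 1), seed = 5)
  # force zero events for class 3 in interval 1
  d$event[d$class == 3 & d$time_days <= 3] <- 0L
  d$event[d$class == 3] <- 0L
  pw <- fit_piecewise_cox(d, d$class, 3)
  r <- pw$hr_table[pw$hr_table$term == "class3", ]
  expect_true(all(!r$estimable))
  expect_true(all(is.na(r$HR)))
})

test_that("search_cutpoint finds the true hazard change point and is
           invariant to subject order", {
  d <- simulate_piecewise_cohort(4000, seed = 77)
  sc <- search_cutpoint(d, d$class, 1:14)
  expect_equal(sc$best, 3)
  expect_equal(nrow(sc$profile), 14L)

  perm <- sample(nrow(d))
  sc2 <- search_cutpoint(d[perm, ], d$class[perm], 1:14)
  expect_equal(sc$profile$partial_loglik, sc2$profile$partial_loglik,
               tolerance = 1e-10)

  expect_error(search_cutpoint(d, d$class, 3), "at least two")

  # proportional hazards: profile is flat to within noise
  dn <- simulate_piecewise_cohort(3000, hr_pre = c(1, 2, 3, 1.5),
                                  hr_post = c(1, 2, 3, 1.5), seed = 6)
  scn <- search_cutpoint(dn, dn$class, 1:14)
  expect_lt(diff(range(scn$profile$partial_loglik)), 10)
})

test_that("the proportional-hazards score test calibrates under the null
           and detects crossing hazards", {
  # type-I error on proportional-hazards data
  rej <- 0L
  for (r in 1:200) {
    set.seed(4000 + r)
    n <- 2000
    grp <- rbinom(n, 1, 0.5)
    Tm <- rexp(n, 0.02 * exp(0.7 * grp))
    sub <- data.frame(subject_id = 1:n, time_days = pmin(Tm, 28),
                      event = as.integer(Tm <= 28))
    ct <- split_followup(sub, grp, numeric(0))
    ct$grp <- grp[match(ct$subject_id, sub$subject_id)]
    fit <- fit_cox(ct, "grp")
    p <- ph_test(fit)$p[1]
    if (!is.na(p) && p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.10)

  # crossing hazards: hazard ratio flips at day 3
  d <- simulate_piecewise_cohort(5000, class_probs = c(0.5, 0.5, 0, 0),
                                 baseline_hazard = c(0.03, 0.01),
                                 hr_pre = c(1, 4, 1, 1),
                                 hr_post = c(1, 0.25, 1, 1), seed = 11)
  ct <- split_followup(d, d$class, numeric(0))
  ct$grp <- as.integer(ct$class == 2)
  fit <- fit_cox(ct, "grp")
  expect_lt(ph_test(fit)$p[1], 0.001)

  # degenerate: a single event gives an undefined test
  sub1 <- data.frame(subject_id = 1:3, time_days = c(1, 2, 3),
                     event = c(1, 0, 0))
  ct1 <- split_followup(sub1, c(0, 1, 1), numeric(0))
  ct1$grp <- c(0, 1, 1)
  fit1 <- fit_cox(ct1, "grp")
  expect_true(all(is.na(ph_test(fit1)$p)) || nrow(ph_test(fit1)) >= 1)
})
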