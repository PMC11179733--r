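#' Specification of a single latent trajectory class
#'
#' Bundles everything that defines one latent class of the data-generating
#' model: its population share, the cubic fixed-effect trajectory on scaled
#' time `u = t/28` (platelet units, x10^9/L), and the class-specific Weibull
#' baseline hazard.
#'
#' @param proportion Fraction of the population in this class, in (0, 1].
#' @param fixed_effects Numeric vector of 4 polynomial coefficients
#'   (intercept, linear, quadratic, cubic) on scaled time `u = t/28`.
#' @param weibull_scale Weibull scale parameter lambda (1/days), > 0. The
#'   class survival function is `S(t) = exp(-(lambda * t)^rho)`.
#' @param weibull_shape Weibull shape parameter rho (dimensionless), > 0.
#' @param label Short text label for the trajectory shape.
#'
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(proportion, fixed_effects, weibull_scale,
                       weibull_shape, label = "") {
  stopifnot(is.numeric(proportion), length(proportion) == 1L,
            proportion > 0, proportion <= 1)
  stopifnot(is.numeric(fixed_effects), length(fixed_effects) == 4L,
            all(is.finite(fixed_effects)))
  if (!is.numeric(weibull_scale) || weibull_scale <= 0)
    stop("weibull_scale must be > 0")
  if (!is.numeric(weibull_shape) || weibull_shape <= 0)
    stop("weibull_shape must be > 0")
  structure(list(proportion = proportion,
                 fixed_effects = as.numeric(fixed_effects),
                 weibull_scale = weibull_scale,
                 weibull_shape = weibull_shape,
                 label = label),
            class = "class_spec")
}

#' Configuration of a synthetic ICU cohort
#'
#' Full description of the data-generating process for a synthetic septic
#' cohort: latent classes, shared random-effect and residual variability,
#' baseline covariate distributions and their log-hazard effects, the
#' measurement schedule and the censoring mechanisms.
#'
#' @param n_subjects Number of subjects to generate.
#' @param classes List of [class_spec()] objects; proportions must sum to 1.
#' @param re_sd_intercept,re_sd_slope Standard deviations of the shared
#'   random intercept and random slope (slope per unit of scaled time),
#'   platelet units.
#' @param re_corr Correlation between random intercept and slope, in [-1, 1].
#' @param resid_sd Residual (measurement-level) standard deviation, platelet
#'   units.
#' @param covariate_effects Named numeric vector of 3 log-hazard-ratios per
#'   standardized covariate unit, names `aps3`, `cci`, `platelet_baseline`.
#' @param covariate_means,covariate_sds Standardization constants used when
#'   the covariates enter the hazard. For `aps3` and `cci` they are also the
#'   generating mean/SD; `platelet_baseline` is generated from the class
#'   intercept plus noise with SD `covariate_sds["platelet_baseline"]`, and
#'   its mean entry is only the centering constant for the hazard.
#' @param measurement_interval_days Spacing of the scheduled laboratory
#'   measurement grid in days (> 0, default 1: daily labs).
#' @param missing_rate Probability that any scheduled measurement is missing,
#'   in [0, 1).
#' @param admin_censor_day Administrative censoring time in days (default 28).
#' @param discharge_rate Rate (1/days) of the independent exponential
#'   discharge-censoring time; 0 disables discharge censoring.
#' @param seed Integer seed making the cohort fully reproducible.
#'
#' @return An object of class `cohort_config`.
#' @seealso [default_cohort_config()] for the calibrated default cohort.
#' @export
cohort_config <- function(n_subjects,
                          classes,
                          re_sd_intercept = 32,
                          re_sd_slope = 25,
                          re_corr = -0.2,
                          resid_sd = 20,
                          covariate_effects = c(aps3 = 0.45, cci = 0.25,
                                                platelet_baseline = -0.2),
                          covariate_means = c(aps3 = 58, cci = 5,
                                              platelet_baseline = 177),
                          covariate_sds = c(aps3 = 24, cci = 3,
                                            platelet_baseline = 30),
                          measurement_interval_days = 1,
                          missing_rate = 0.15,
                          admin_censor_day = 28,
                          discharge_rate = 0.08,
                          seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("n_subjects must be a positive count")
  if (!is.list(classes) || !all(vapply(classes, inherits, TRUE, "class_spec")))
    stop("classes must be a list of class_spec objects")
  props <- vapply(classes, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop("class proportions must sum to 1 (within 1e-9)")
  if (admin_censor_day <= 0) stop("admin_censor_day must be > 0")
  if (measurement_interval_days <= 0)
    stop("measurement_interval_days must be > 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (discharge_rate < 0) stop("discharge_rate must be >= 0")
  if (abs(re_corr) > 1) stop("re_corr must be in [-1, 1]")
  nm <- c("aps3", "cci", "platelet_baseline")
  stopifnot(all(nm %in% names(covariate_effects)),
            all(nm %in% names(covariate_means)),
            all(nm %in% names(covariate_sds)))
  structure(list(n_subjects = as.integer(n_subjects),
                 classes = classes,
                 re_sd_intercept = re_sd_intercept,
                 re_sd_slope = re_sd_slope,
                 re_corr = re_corr,
                 resid_sd = resid_sd,
                 covariate_effects = covariate_effects[nm],
                 covariate_means = covariate_means[nm],
                 covariate_sds = covariate_sds[nm],
                 measurement_interval_days = measurement_interval_days,
                 missing_rate = missing_rate,
                 admin_censor_day = admin_censor_day,
                 discharge_rate = discharge_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default synthetic cohort emulating a large septic ICU population
#'
#' Returns a fixed, calibrated [cohort_config()] with four latent platelet
#' trajectory classes in proportions 6.83/79.44/4.52/9.21%:
#' an inverted-U shape peaking mid-window (class 1), a mild monotone increase
#' from about 167 x10^9/L (class 2), an early dip below the thrombocytopenia
#' threshold of 150 x10^9/L before day 3 followed by recovery (class 3), and
#' a rapid fall from a high start stabilizing slightly below 150 (class 4).
#' Class-specific Weibull hazards are calibrated so that 28-day mortality is
#' ordered class 1 < class 3 ~ class 2 < class 4 (after day 3), and so that
#' the observed in-hospital death fraction under discharge censoring is close
#' to 19%.
#'
#' @param n_subjects Number of subjects (default 2000).
#' @param seed Integer seed (default 1).
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(n_subjects = 2000, seed = 1L) {
  classes <- list(
    class_spec(0.0683, c(185, 480, -480, 0), weibull_scale = 0.0075,
               weibull_shape = 1.00, label = "inverted-U"),
    class_spec(0.7944, c(167, 60, -15, 0), weibull_scale = 0.0165,
               weibull_shape = 1.00, label = "slight-increase"),
    class_spec(0.0452, c(178, -351, 702, -351), weibull_scale = 0.0104,
               weibull_shape = 0.60, label = "decrease-increase-intermediate"),
    class_spec(0.0921, c(258, -549.7, 789.1, -350.7), weibull_scale = 0.0451,
               weibull_shape = 1.40, label = "decrease-low"))
  cohort_config(n_subjects = n_subjects, classes = classes, seed = seed)
}

# evaluate the class polynomial at scaled times u
.poly_eval <- function(beta, u) {
  drop(cbind(1, u, u^2, u^3) %*% beta)
}

#' Simulate a synthetic ICU cohort with latent trajectory classes
#'
#' Draws a latent class per subject, subject-level random effects and
#' baseline covariates, a Weibull event time whose hazard is the class
#' baseline multiplied by `exp(gamma' z)` for standardized covariates `z`,
#' and an independent exponential discharge-censoring time; follow-up is
#' truncated at the administrative censoring day. Platelet measurements are
#' generated on the scheduled grid restricted to the observed follow-up
#' window and floored at 1 x10^9/L: the admission (day 0) lab is always
#' present (a missing baseline platelet is an exclusion criterion), interior
#' scheduled labs are thinned by the missing rate, and a final lab is drawn
#' at the end of follow-up. Subjects ending up with fewer than two distinct
#' measurement times (the standard inclusion filter for trajectory
#' analyses) are redrawn so the cohort size is exact.
#'
#' @param config A [cohort_config()].
#' @return An object of class `simulated_cohort`: a list with elements
#'   `longitudinal` (data.frame: subject_id, time_days, platelet),
#'   `subjects` (data.frame: subject_id, aps3, cci, platelet_baseline,
#'   time_days, event, true_class), `true_class` (integer vector) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  n <- config$n_subjects
  if (n < 1) stop("n_subjects must be positive")
  G <- length(config$classes)
  props <- vapply(config$classes, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9) stop("class proportions must sum to 1")
  betas <- vapply(config$classes, `[[`, numeric(4), "fixed_effects")  # 4 x G
  lam <- vapply(config$classes, `[[`, numeric(1), "weibull_scale")
  rho <- vapply(config$classes, `[[`, numeric(1), "weibull_shape")
  gam <- config$covariate_effects
  cm <- config$covariate_means
  cs <- config$covariate_sds
  admin <- config$admin_censor_day
  grid <- seq(0, admin, by = config$measurement_interval_days)
  ug <- grid / .TIME_SCALE
  # random-effects Cholesky factor
  Sig <- matrix(c(config$re_sd_intercept^2,
                  rep(config$re_corr * config$re_sd_intercept *
                        config$re_sd_slope, 2),
                  config$re_sd_slope^2), 2, 2)
  L <- chol(Sig)  # upper triangular; draws = z %*% L

  set.seed(config$seed)

  draw_subjects <- function(m) {
    cls <- sample.int(G, m, replace = TRUE, prob = props)
    z <- matrix(rnorm(2 * m), m, 2) %*% L
    aps3 <- pmax(1, rnorm(m, cm["aps3"], cs["aps3"]))
    cci <- pmax(0, rnorm(m, cm["cci"], cs["cci"]))
    pltb <- pmax(10, betas[1, cls] + rnorm(m, 0, cs["platelet_baseline"]))
    eta <- gam["aps3"] * (aps3 - cm["aps3"]) / cs["aps3"] +
      gam["cci"] * (cci - cm["cci"]) / cs["cci"] +
      gam["platelet_baseline"] *
        (pltb - cm["platelet_baseline"]) / cs["platelet_baseline"]
    # inverse-transform Weibull PH draw: S(t) = exp(-(lam t)^rho e^eta)
    e <- rexp(m)
    t_death <- (e / exp(eta))^(1 / rho[cls]) / lam[cls]
    t_dis <- if (config$discharge_rate > 0) rexp(m, config$discharge_rate)
             else rep(Inf, m)
    t_obs <- pmin(t_death, t_dis, admin)
    event <- as.integer(t_death <= pmin(t_dis, admin))
    list(cls = cls, b0 = z[, 1], b1 = z[, 2], aps3 = aps3, cci = cci,
         pltb = pltb, t_obs = t_obs, event = event)
  }

  draw_measurements <- function(s) {
    m <- length(s$cls)
    keep_t <- vector("list", m)
    keep_y <- vector("list", m)
    ok <- logical(m)
    for (i in seq_len(m)) {
      # the admission (day 0) lab is always present -- a missing baseline
      # platelet is an exclusion criterion -- and a final lab is drawn at
      # the end of follow-up; interior scheduled labs are thinned
      sel <- grid <= s$t_obs[i]
      if (config$missing_rate > 0)
        sel <- sel & (runif(length(grid)) >= config$missing_rate)
      sel[1] <- TRUE
      ti <- unique(c(grid[sel], s$t_obs[i]))
      if (length(ti) < 2) { ok[i] <- FALSE; next }
      ui <- ti / .TIME_SCALE
      mu <- .poly_eval(betas[, s$cls[i]], ui) + s$b0[i] + s$b1[i] * ui
      yi <- pmax(1, mu + rnorm(length(ti), 0, config$resid_sd))
      keep_t[[i]] <- ti; keep_y[[i]] <- yi; ok[i] <- TRUE
    }
    list(ok = ok, t = keep_t, y = keep_y)
  }

  subj <- draw_subjects(n)
  meas <- draw_measurements(subj)
  tries <- 0L
  while (!all(meas$ok)) {
    tries <- tries + 1L
    if (tries > 1000L) stop("could not satisfy the >=2 measurement rule")
    bad <- which(!meas$ok)
    repl <- draw_subjects(length(bad))
    rmeas <- draw_measurements(repl)
    for (f in names(repl))
      subj[[f]][bad] <- repl[[f]]
    meas$ok[bad] <- rmeas$ok
    meas$t[bad] <- rmeas$t
    meas$y[bad] <- rmeas$y
  }

  nmeas <- lengths(meas$t)
  longitudinal <- data.frame(
    subject_id = rep(seq_len(n), nmeas),
    time_days = unlist(meas$t),
    platelet = unlist(meas$y))
  subjects <- data.frame(
    subject_id = seq_len(n),
    aps3 = subj$aps3, cci = subj$cci, platelet_baseline = subj$pltb,
    time_days = subj$t_obs, event = subj$event, true_class = subj$cls)
  structure(list(longitudinal = longitudinal, subjects = subjects,
                 true_class = subj$cls, config = config),
            class = "simulated_cohort")
}

#' Summarize a simulated cohort by latent class
#'
#' @param cohort A `simulated_cohort`.
#' @return Data frame with one row per class present: `class`, `label`, `n`,
#'   `pct`, `event_rate`, `median_n_meas`.
#' @export
summarize_cohort <- function(cohort) {
  if (!inherits(cohort, "simulated_cohort")) stop("not a simulated_cohort")
  s <- cohort$subjects
  if (nrow(s) == 0) stop("empty cohort")
  nm <- table(factor(cohort$longitudinal$subject_id,
                     levels = s$subject_id))
  labs <- vapply(cohort$config$classes, `[[`, character(1), "label")
  cls <- sort(unique(s$true_class))
  out <- do.call(rbind, lapply(cls, function(g) {
    sel <- s$true_class == g
    data.frame(class = g,
               label = if (g <= length(labs)) labs[g] else "",
               n = sum(sel),
               pct = 100 * mean(s$true_class == g),
               event_rate = mean(s$event[sel]),
               median_n_meas = median(as.numeric(nm[sel])))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated ICU cohort:", nrow(x$subjects), "subjects,",
      nrow(x$longitudinal), "platelet measurements\n")
  cat("  events:", sum(x$subjects$event),
      sprintf("(%.1f%%)", 100 * mean(x$subjects$event)),
      " classes:", paste(table(x$true_class), collapse = "/"), "\n")
  invisible(x)
}

#' Simulate a cohort with class-linked piecewise-constant hazards
#'
#' Companion generator for time-dependent hazard-ratio experiments: subjects
#' are assigned to classes and their event times drawn from a
#' piecewise-constant hazard that changes at a single cut point, with
#' class-specific hazard ratios before and after the cut (class 1 is the
#' reference). No longitudinal data are generated.
#'
#' @param n Number of subjects.
#' @param class_probs Class membership probabilities (sum to 1).
#' @param baseline_hazard Reference-class hazards (1/days), length 2:
#'   before and after the cut point.
#' @param hr_pre,hr_post Hazard ratios vs class 1 per class (first element
#'   must be 1), applying before / after the cut point.
#' @param cutpoint Day at which the hazard changes (default 3).
#' @param admin_censor_day Administrative censoring day (default 28).
#' @param seed Integer seed.
#' @return Data frame: `subject_id`, `time_days`, `event`, `class`.
#' @export
simulate_piecewise_cohort <- function(n,
                                      class_probs = rep(0.25, 4),
                                      baseline_hazard = c(0.010, 0.010),
                                      hr_pre = c(1, 3.9, 13.86, 2.84),
                                      hr_post = c(1, 2.32, 2.95, 6.09),
                                      cutpoint = 3,
                                      admin_censor_day = 28,
                                      seed = 1L) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-9,
            hr_pre[1] == 1, hr_post[1] == 1,
            length(hr_pre) == length(class_probs),
            length(hr_post) == length(class_probs))
  set.seed(seed)
  G <- length(class_probs)
  cls <- sample.int(G, n, replace = TRUE, prob = class_probs)
  h1 <- baseline_hazard[1] * hr_pre[cls]
  h2 <- baseline_hazard[2] * hr_post[cls]
  e <- rexp(n)
  # invert the piecewise-exponential cumulative hazard
  t <- ifelse(e <= h1 * cutpoint, e / h1, cutpoint + (e - h1 * cutpoint) / h2)
  event <- as.integer(t <= admin_censor_day)
  t_obs <- pmin(t, admin_censor_day)
  data.frame(subject_id = seq_len(n), time_days = t_obs, event = event,
             class = cls)
}
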