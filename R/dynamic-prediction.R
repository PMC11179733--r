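#' Landmark prediction query
#'
#' @param s Landmark day (>= 0).
#' @param t Horizon day, `s <= t <= 28` (equality gives the trivial
#'   prediction 1).
#' @return List with validated `s`, `t`.
#' @export
landmark_query <- function(s, t = 28) {
  if (s < 0) stop("landmark must be >= 0")
  if (t < s) stop("horizon must be at or after the landmark")
  if (t > 28) stop("horizon must be within the 28-day window")
  list(s = s, t = t)
}

# class-specific conditional survival S_g(t | x) for a fitted JLCM
.jlcm_class_surv <- function(params, t, x) {
  std <- params$covariate_standardization
  nm <- names(params$gamma)
  z <- (x[nm] - std$mean[nm]) / std$sd[nm]
  eta <- sum(z * params$gamma)
  G <- nrow(params$weibull)
  vapply(seq_len(G), function(g)
    exp(-(params$weibull[g, 1] * t)^params$weibull[g, 2] * exp(eta)),
    numeric(1))
}

#' Posterior class weights conditional on history up to a landmark
#'
#' Bayes weights `w_g(s)` proportional to
#' `pi_g * f_g(history) * S_g(s | x)`: the class prior, the marginal
#' longitudinal density of the measurements observed up to the landmark, and
#' the probability of remaining event-free at the landmark. With empty
#' history the weights reduce to `pi_g * S_g(s | x)` renormalized.
#'
#' @param fit A `jlcm_fit`.
#' @param history Data frame with `time_days`, `platelet`; all times must be
#'   at or before `s` (a measurement after the landmark is a leakage error).
#' @param x Named covariate vector on the raw scale.
#' @param s Landmark day.
#' @return Simplex of length G.
#' @export
conditional_class_weights <- function(fit, history, x, s) {
  params <- fit$params
  spec <- fit$spec
  G <- spec$n_classes
  if (!is.null(history) && nrow(history) > 0 &&
      any(history$time_days > s))
    stop("history contains measurements after the landmark (leakage)")
  logpi <- log(class_prior(params$xi))
  llg <- numeric(G)
  if (!is.null(history) && nrow(history) > 0) {
    t <- history$time_days
    o <- order(t)
    t <- t[o]; y <- history$platelet[o]
    keep <- !duplicated(t)
    t <- t[keep]; y <- y[keep]
    u <- t / .TIME_SCALE
    W <- outer(u, 0:spec$poly_degree, `^`)
    q <- if (identical(spec$random_effects, "intercept")) 1L else 2L
    Z <- W[, seq_len(q), drop = FALSE]
    B <- params$B[seq_len(q), seq_len(q), drop = FALSE]
    for (g in seq_len(G))
      llg[g] <- gaussian_class_loglik(y, W, Z, params$beta[, g], B,
                                      params$sigma)
  }
  Ss <- .jlcm_class_surv(params, s, x)
  logw <- logpi + llg + ifelse(Ss < 1e-12, -Inf, log(Ss))
  if (all(!is.finite(logw))) logw <- logpi
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Dynamic conditional survival probability from a fitted JLCM
#'
#' `S_hat(t | s) = sum_g w_g(s) * S_g(t | x) / S_g(s | x)`, with the class
#' weights conditioned on the biomarker history up to the landmark and on
#' being event-free at the landmark. Non-increasing in `t` and equal to 1
#' at `t = s`.
#'
#' @inheritParams conditional_class_weights
#' @param query A [landmark_query()] (or list with `s`, `t`).
#' @return Scalar survival probability.
#' @export
dynamic_survival <- function(fit, history, x, query) {
  s <- query$s; t <- query$t
  if (t < s) stop("horizon must be >= landmark")
  w <- conditional_class_weights(fit, history, x, s)
  Ss <- .jlcm_class_surv(fit$params, s, x)
  St <- .jlcm_class_surv(fit$params, t, x)
  ratio <- ifelse(Ss < 1e-12, 0, St / Ss)
  sum(w * ratio)
}

#' Conditional survival from the static Weibull comparator
#'
#' `S(t | x) / S(s | x)` from [fit_static_weibull()]; by construction it
#' ignores all longitudinal history.
#'
#' @param model A `static_weibull`.
#' @param x Named covariate vector on the raw scale.
#' @param query A [landmark_query()].
#' @return Scalar survival probability.
#' @export
static_conditional_survival <- function(model, x, query) {
  s <- query$s; t <- query$t
  if (t < s) stop("horizon must be >= landmark")
  if (t == s) return(1)
  Ss <- static_survival(model, s, x)
  St <- static_survival(model, t, x)
  if (Ss < 1e-12) return(0)
  St / Ss
}

# per-subject history moments truncated at the landmark (subjects with no
# history get zero rows and contribute a flat longitudinal likelihood)
.history_moments <- function(longitudinal, subject_ids, s, d) {
  lon <- longitudinal[longitudinal$subject_id %in% subject_ids &
                        longitudinal$time_days <= s, , drop = FALSE]
  key <- paste(lon$subject_id, lon$time_days)
  lon <- lon[!duplicated(key), , drop = FALSE]
  n <- length(subject_ids)
  U <- matrix(0, n, 2 * d + 1)
  UY <- matrix(0, n, d + 1)
  SY2 <- numeric(n)
  n_i <- integer(n)
  if (nrow(lon)) {
    idx <- match(lon$subject_id, subject_ids)
    u <- lon$time_days / .TIME_SCALE
    y <- lon$platelet
    Upow <- outer(u, 0:(2 * d), `^`)
    M <- rowsum(cbind(Upow, y * Upow[, 1:(d + 1), drop = FALSE], y^2), idx)
    rows <- as.integer(rownames(M))
    U[rows, ] <- M[, 1:(2 * d + 1)]
    UY[rows, ] <- M[, (2 * d + 2):(3 * d + 2)]
    SY2[rows] <- M[, 3 * d + 3]
    n_i <- tabulate(idx, nbins = n)
  }
  list(U = U, UY = UY, SY2 = SY2, n_i = n_i, d = d)
}

#' Landmark predictions for all at-risk subjects of a cohort
#'
#' Builds the landmark-`s` risk set (subjects whose event or censoring time
#' strictly exceeds `s`), scores each at-risk subject with history truncated
#' at the landmark, and returns one prediction record per subject. Methods
#' exist for fitted joint latent class models (`jlcm_fit`; dynamic
#' prediction) and static Weibull comparators (`static_weibull`).
#'
#' @param model A `jlcm_fit` or `static_weibull`.
#' @param longitudinal,subjects Cohort tables (see [fit_jlcm()]).
#' @param s Landmark day.
#' @param horizon Prediction horizon in days (default 28).
#' @return Data frame: `subject_id`, `landmark`, `horizon`, `p_survive`,
#'   `risk`, class weights `w_1..w_G` (dynamic only), `model_tag`.
#' @export
predict_cohort <- function(model, longitudinal, subjects, s, horizon = 28) {
  UseMethod("predict_cohort")
}

#' @export
predict_cohort.jlcm_fit <- function(model, longitudinal, subjects, s,
                                    horizon = 28) {
  if (horizon <= s) stop("horizon must exceed the landmark")
  at_risk <- subjects[subjects$time_days > s, , drop = FALSE]
  if (!nrow(at_risk)) stop("empty risk set at landmark ", s)
  params <- model$params
  spec <- model$spec
  G <- spec$n_classes
  q <- if (identical(spec$random_effects, "intercept")) 1L else 2L
  mom <- .history_moments(longitudinal, at_risk$subject_id, s,
                          spec$poly_degree)
  prep <- list(n = nrow(at_risk), d = spec$poly_degree, q = q,
               n_i = mom$n_i, U = mom$U, UY = mom$UY, SY2 = mom$SY2)
  std <- params$covariate_standardization
  nm <- names(params$gamma)
  X <- as.matrix(at_risk[, nm, drop = FALSE])
  Xstd <- sweep(sweep(X, 2, std$mean[nm], "-"), 2, std$sd[nm], "/")
  eta <- drop(Xstd %*% params$gamma)
  logpi <- log(class_prior(params$xi))
  logw <- matrix(0, nrow(at_risk), G)
  Ss <- St <- matrix(0, nrow(at_risk), G)
  for (g in seq_len(G)) {
    lam <- params$weibull[g, 1]; rho <- params$weibull[g, 2]
    Ss[, g] <- exp(-(lam * s)^rho * exp(eta))
    St[, g] <- exp(-(lam * horizon)^rho * exp(eta))
    llg <- .gauss_loglik_class(prep, params$beta[, g], params$chol_B,
                               params$sigma)
    logw[, g] <- logpi[g] + llg + ifelse(Ss[, g] < 1e-12, -Inf,
                                         log(Ss[, g]))
  }
  mx <- apply(logw, 1, max)
  bad <- !is.finite(mx)
  w <- exp(logw - mx)
  w[bad, ] <- rep(exp(logpi - max(logpi)), each = sum(bad))
  w <- w / rowSums(w)
  ratio <- ifelse(Ss < 1e-12, 0, St / Ss)
  p_surv <- rowSums(w * ratio)
  out <- data.frame(subject_id = at_risk$subject_id, landmark = s,
                    horizon = horizon, p_survive = p_surv,
                    risk = 1 - p_surv)
  colnames(w) <- paste0("w_", seq_len(G))
  out <- cbind(out, w)
  out$model_tag <- "dynamic"
  out
}

#' @export
predict_cohort.static_weibull <- function(model, longitudinal, subjects, s,
                                          horizon = 28) {
  if (horizon <= s) stop("horizon must exceed the landmark")
  at_risk <- subjects[subjects$time_days > s, , drop = FALSE]
  if (!nrow(at_risk)) stop("empty risk set at landmark ", s)
  X <- as.matrix(at_risk[, model$covariates, drop = FALSE])
  Ss <- static_survival(model, s, X)
  St <- static_survival(model, horizon, X)
  p_surv <- ifelse(Ss < 1e-12, 0, St / Ss)
  data.frame(subject_id = at_risk$subject_id, landmark = s,
             horizon = horizon, p_survive = p_surv, risk = 1 - p_surv,
             model_tag = "static")
}

#' Individual dynamic prediction series across landmarks
#'
#' One leakage-guarded prediction per requested landmark for a single
#' subject, using only the measurements observed up to each landmark;
#' suitable for trajectories-plus-prediction panels.
#'
#' @param fit A `jlcm_fit`.
#' @param longitudinal,subjects Cohort tables containing the subject.
#' @param subject_id Subject to predict for.
#' @param landmark_days Landmark days (all strictly before the subject's
#'   event/censoring time).
#' @param horizon Horizon day (default 28).
#' @return Data frame with one row per landmark: `subject_id`, `landmark`,
#'   `horizon`, `p_survive`, `risk`, `n_meas_used`, class weights.
#' @export
individual_prediction_series <- function(fit, longitudinal, subjects,
                                         subject_id, landmark_days,
                                         horizon = 28) {
  row <- subjects[subjects$subject_id == subject_id, , drop = FALSE]
  if (!nrow(row)) stop("unknown subject id: ", subject_id)
  if (any(landmark_days >= row$time_days))
    stop("landmark at or after the subject's event/censoring time")
  hist_all <- longitudinal[longitudinal$subject_id == subject_id, ,
                           drop = FALSE]
  x <- unlist(row[1, names(fit$params$gamma)])
  G <- fit$spec$n_classes
  out <- lapply(sort(landmark_days), function(s) {
    h <- hist_all[hist_all$time_days <= s, , drop = FALSE]
    w <- conditional_class_weights(fit, h, x, s)
    p <- dynamic_survival(fit, h, x, landmark_query(s, horizon))
    r <- data.frame(subject_id = subject_id, landmark = s,
                    horizon = horizon, p_survive = p, risk = 1 - p,
                    n_meas_used = nrow(h))
    wm <- matrix(w, nrow = 1, dimnames = list(NULL, paste0("w_", 1:G)))
    cbind(r, as.data.frame(wm))
  })
  do.call(rbind, out)
}
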