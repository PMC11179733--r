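#' Build per-subject design matrices for the latent class mixed model
#'
#' For each subject the fixed-effect design `W` holds powers of scaled time
#' `u = t/28` up to `poly_degree`; the random-effect design `Z` is the first
#' `q` columns of `W` (`q = 1` for a random intercept, `q = 2` for random
#' intercept + slope).
#'
#' @param longitudinal Data frame with `subject_id`, `time_days`.
#' @param spec A [jlcm_spec()] (or list with `poly_degree`,
#'   `random_effects`).
#' @return Named list (by subject id) of lists with elements `W`, `Z`, and
#'   row indices `rows` into the (deduplicated, time-ordered) table.
#' @export
build_design <- function(longitudinal, spec = jlcm_spec()) {
  d <- spec$poly_degree
  q <- if (identical(spec$random_effects, "intercept")) 1L else 2L
  if (!nrow(longitudinal)) stop("empty longitudinal table")
  split_t <- split(longitudinal$time_days, longitudinal$subject_id)
  lapply(split_t, function(t) {
    if (!length(t)) stop("subject with 0 measurements")
    t <- sort(unique(t))
    u <- t / .TIME_SCALE
    W <- outer(u, 0:d, `^`)
    colnames(W) <- paste0("u", 0:d)
    list(W = W, Z = W[, seq_len(q), drop = FALSE], time_days = t)
  })
}

#' Marginal Gaussian log-likelihood of one subject's measurements in a class
#'
#' Log-density of `Y_i` under the latent class mixed model with the random
#' effects integrated out analytically: `Y_i ~ N(W_i beta_g, V_i)` with
#' `V_i = Z_i B Z_i' + sigma^2 I`. Computed through a Cholesky factorization
#' of `V_i`; a small jitter is added once if the factorization fails.
#'
#' @param y Numeric vector of measurements.
#' @param W Fixed-effect design matrix (n_i x (degree+1)).
#' @param Z Random-effect design matrix (n_i x q).
#' @param beta Fixed-effect coefficients for the class.
#' @param B Random-effects covariance matrix (q x q, PSD).
#' @param sigma Residual standard deviation (> 0).
#' @return Scalar log-likelihood.
#' @export
gaussian_class_loglik <- function(y, W, Z, beta, B, sigma) {
  n <- length(y)
  stopifnot(nrow(W) == n, nrow(Z) == n, length(beta) == ncol(W),
            nrow(B) == ncol(Z), sigma > 0)
  V <- Z %*% B %*% t(Z) + diag(sigma^2, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    ch <- tryCatch(chol(V + diag(1e-8, n)),
                   error = function(e) stop("covariance not PSD after jitter"))
  r <- y - drop(W %*% beta)
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Weibull proportional-hazards hazard and survival
#'
#' Class-specific Weibull baseline with a log-linear covariate effect:
#' `h(t) = rho * lambda * (lambda t)^(rho-1) * exp(eta)` and
#' `S(t) = exp(-(lambda t)^rho * exp(eta))` where `eta = x_std' gamma`.
#' At `t = 0` with `rho < 1` the hazard is infinite and returned as `Inf`.
#'
#' @param t Non-negative time(s) in days.
#' @param lambda Weibull scale (1/days), > 0.
#' @param rho Weibull shape, > 0.
#' @param x_std Standardized covariate vector (or matrix, subjects in rows);
#'   may be `NULL` for `eta = 0`.
#' @param gamma Covariate log-hazard-ratio coefficients.
#' @return List with elements `hazard` and `survival`.
#' @export
weibull_survival <- function(t, lambda, rho, x_std = NULL, gamma = NULL) {
  if (any(t < 0)) stop("t must be >= 0")
  stopifnot(lambda > 0, rho > 0)
  eta <- if (is.null(x_std) || is.null(gamma)) 0
         else if (is.matrix(x_std)) drop(x_std %*% gamma)
         else sum(x_std * gamma)
  lt <- lambda * t
  haz <- rho * lambda * lt^(rho - 1) * exp(eta)   # Inf at t=0 when rho<1
  surv <- exp(-lt^rho * exp(eta))
  list(hazard = haz, survival = surv)
}

#' Class-membership prior from multinomial logits
#'
#' Intercept-only multinomial logit with the last class as reference
#' (`xi_G = 0`): `pi_g = exp(xi_g) / sum_h exp(xi_h)`.
#'
#' @param xi Numeric vector of G-1 logits (length 0 gives G = 1).
#' @return Probability simplex of length G.
#' @export
class_prior <- function(xi) {
  if (length(xi) && any(!is.finite(xi))) stop("xi must be finite")
  x <- c(xi, 0)
  x <- x - max(x)
  exp(x) / sum(exp(x))
}

# ---------------------------------------------------------------------------
# internal vectorized machinery
#
# The marginal likelihood is computed from per-subject sufficient statistics
# of the polynomial basis (sums of u^m and y*u^m), using the Woodbury
# identity for V = sigma^2 I + Z L L' Z' with q = 2 random effects, so that a
# full likelihood evaluation costs O(N) vector arithmetic and no per-subject
# matrix factorizations.

# prepare data structures shared by all likelihood evaluations
.jlcm_prepare <- function(longitudinal, subjects, spec,
                          standardization = NULL) {
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject ids in subject table")
  if (!all(longitudinal$subject_id %in% subjects$subject_id))
    stop("longitudinal table contains subjects absent from subject table")
  if (!all(subjects$subject_id %in% longitudinal$subject_id))
    stop("subject table contains subjects with no measurements")
  if (any(!is.finite(longitudinal$time_days)) ||
      any(!is.finite(longitudinal$platelet)))
    stop("non-finite longitudinal values")
  if (any(subjects$time_days <= 0)) stop("survival times must be > 0")
  if (!all(subjects$event %in% c(0, 1))) stop("event must be 0/1")

  # dedup measurement times within subject, order by time
  key <- paste(longitudinal$subject_id, longitudinal$time_days)
  lon <- longitudinal[!duplicated(key), , drop = FALSE]
  lon <- lon[order(match(lon$subject_id, subjects$subject_id),
                   lon$time_days), , drop = FALSE]
  idx <- match(lon$subject_id, subjects$subject_id)
  n_i <- tabulate(idx, nbins = nrow(subjects))
  if (any(n_i < 2))
    stop("every subject must have >= 2 platelet measurements")

  u <- lon$time_days / .TIME_SCALE
  y <- lon$platelet
  d <- spec$poly_degree
  # per-subject moments: sums of u^m (m = 0..2d) and y*u^m (m = 0..d), y^2
  Upow <- outer(u, 0:(2 * d), `^`)
  M <- rowsum(cbind(Upow, y * Upow[, 1:(d + 1), drop = FALSE], y^2),
              idx, reorder = TRUE)
  U <- M[, 1:(2 * d + 1), drop = FALSE]
  UY <- M[, (2 * d + 2):(3 * d + 2), drop = FALSE]
  SY2 <- M[, 3 * d + 3]

  covars <- spec$survival_covariates
  if (!all(covars %in% names(subjects)))
    stop("missing survival covariates: ",
         paste(setdiff(covars, names(subjects)), collapse = ", "))
  X <- as.matrix(subjects[, covars, drop = FALSE])
  if (is.null(standardization)) {
    standardization <- list(mean = colMeans(X),
                            sd = apply(X, 2, sd))
    standardization$sd[standardization$sd == 0] <- 1
  }
  Xstd <- sweep(sweep(X, 2, standardization$mean, "-"), 2,
                standardization$sd, "/")

  list(n = nrow(subjects), d = d,
       q = if (identical(spec$random_effects, "intercept")) 1L else 2L,
       u = u, y = y, idx = idx, n_i = n_i,
       U = U, UY = UY, SY2 = SY2,
       T = subjects$time_days, delta = subjects$event,
       Xstd = Xstd, standardization = standardization,
       subject_id = subjects$subject_id)
}

# vectorized marginal Gaussian loglik for one class over all subjects
# theta_l: list(beta, l11, l21, l22, sigma); q=1 uses l11 only
.gauss_loglik_class <- function(prep, beta, L, sigma) {
  d <- prep$d
  s2 <- sigma^2
  # residual aggregates from moments
  c2 <- outer(beta, beta)
  conv <- vapply(0:(2 * d), function(m) {
    i <- pmax(0, m - d):min(d, m)
    sum(c2[cbind(i + 1, m - i + 1)])
  }, numeric(1))
  rr <- prep$SY2 - 2 * drop(prep$UY %*% beta) + drop(prep$U %*% conv)
  Zr1 <- prep$UY[, 1] - drop(prep$U[, 1:(d + 1), drop = FALSE] %*% beta)
  n_i <- prep$n_i
  if (prep$q == 1L) {
    l11 <- L[1, 1]
    Cm <- l11^2 * n_i
    M11 <- 1 + Cm / s2
    t1 <- l11 * Zr1
    quad <- t1^2 / M11
    logdetM <- log(M11)
  } else {
    Zr2 <- prep$UY[, 2] - drop(prep$U[, 2:(d + 2), drop = FALSE] %*% beta)
    Szz11 <- prep$U[, 1]; Szz12 <- prep$U[, 2]; Szz22 <- prep$U[, 3]
    l11 <- L[1, 1]; l21 <- L[2, 1]; l22 <- L[2, 2]
    C11 <- l11^2 * Szz11 + 2 * l11 * l21 * Szz12 + l21^2 * Szz22
    C12 <- l11 * l22 * Szz12 + l21 * l22 * Szz22
    C22 <- l22^2 * Szz22
    M11 <- 1 + C11 / s2; M12 <- C12 / s2; M22 <- 1 + C22 / s2
    detM <- M11 * M22 - M12^2
    t1 <- l11 * Zr1 + l21 * Zr2
    t2 <- l22 * Zr2
    quad <- (M22 * t1^2 - 2 * M12 * t1 * t2 + M11 * t2^2) / detM
    logdetM <- log(detM)
  }
  rVr <- (rr - quad / s2) / s2
  -0.5 * (n_i * log(2 * pi * s2) + logdetM + rVr)
}

# vectorized Weibull survival loglik contribution for one class
.surv_loglik_class <- function(prep, lambda, rho, gamma) {
  eta <- drop(prep$Xstd %*% gamma)
  logT <- log(prep$T)
  loglam <- log(lambda)
  cumh <- exp(rho * (loglam + logT) + eta)
  prep$delta * (log(rho) + rho * loglam + (rho - 1) * logT + eta) - cumh
}

# row-wise log-sum-exp
.row_lse <- function(M) {
  m <- do.call(pmax, c(as.data.frame(M), na.rm = FALSE))
  m + log(rowSums(exp(M - m)))
}

#' Joint log-likelihood of a G-class joint latent class model
#'
#' Sum over subjects of
#' `log sum_g pi_g f_g(Y_i) h_g(T_i|X_i)^delta_i S_g(T_i|X_i)`,
#' computed with log-sum-exp; the longitudinal density has the random effects
#' integrated out analytically.
#'
#' @param params A `jlcm_params` object (see [fit_jlcm()]); its stored
#'   covariate standardization is applied to `subjects`.
#' @param longitudinal,subjects Data tables as described in [fit_jlcm()].
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(params, longitudinal, subjects) {
  spec <- attr(params, "spec")
  prep <- .jlcm_prepare(longitudinal, subjects, spec,
                        standardization = params$covariate_standardization)
  parts <- .jlcm_parts(params, prep)
  sum(.row_lse(parts$total))
}

# compute log pi + longitudinal + survival loglik matrix (N x G)
.jlcm_parts <- function(params, prep) {
  G <- ncol(params$beta)
  logpi <- log(class_prior(params$xi))
  llg <- matrix(0, prep$n, G)
  lls <- matrix(0, prep$n, G)
  for (g in seq_len(G)) {
    llg[, g] <- .gauss_loglik_class(prep, params$beta[, g], params$chol_B,
                                    params$sigma)
    lls[, g] <- .surv_loglik_class(prep, params$weibull[g, 1],
                                   params$weibull[g, 2], params$gamma)
  }
  total <- sweep(llg + lls, 2, logpi, "+")
  list(logpi = logpi, llgauss = llg, llsurv = lls, total = total)
}

# posterior class probabilities from the parts
.jlcm_posterior <- function(total) {
  lse <- .row_lse(total)
  p <- exp(total - lse)
  p / rowSums(p)
}
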