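#' Specification of a joint latent class model
#'
#' @param n_classes Number of latent classes G (1..10).
#' @param poly_degree Degree of the polynomial trajectory basis on scaled
#'   time (1, 2 or 3; default 3).
#' @param random_effects `"intercept"` or `"intercept_slope"` (default):
#'   shared random-effects structure of the longitudinal submodel.
#' @param survival_covariates Column names of the subject table entering the
#'   Weibull proportional-hazards submodel (standardized internally).
#' @param n_starts Number of optimizer initializations (default 10): one
#'   k-means-based start plus seeded random perturbations.
#' @param max_iter Maximum quasi-Newton iterations per start (default 500).
#' @param rel_tol Relative log-likelihood convergence tolerance
#'   (default 1e-6).
#' @param seed Integer seed controlling initialization randomness.
#' @return An object of class `jlcm_spec`.
#' @export
jlcm_spec <- function(n_classes = 1L,
                      poly_degree = 3L,
                      random_effects = c("intercept_slope", "intercept"),
                      survival_covariates = c("aps3", "cci",
                                              "platelet_baseline"),
                      n_starts = 10L,
                      max_iter = 500L,
                      rel_tol = 1e-6,
                      seed = 1L) {
  random_effects <- match.arg(random_effects)
  if (n_classes < 1 || n_classes > 10) stop("n_classes must be in 1..10")
  if (!poly_degree %in% 1:3) stop("poly_degree must be 1, 2 or 3")
  structure(list(n_classes = as.integer(n_classes),
                 poly_degree = as.integer(poly_degree),
                 random_effects = random_effects,
                 survival_covariates = survival_covariates,
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 rel_tol = rel_tol,
                 seed = as.integer(seed)),
            class = "jlcm_spec")
}

#' Number of free parameters of a joint latent class model
#'
#' Class-specific polynomial fixed effects, G-1 membership logits, the
#' shared random-effects covariance, the residual SD, class-specific Weibull
#' scale and shape, and shared survival coefficients.
#'
#' @param spec A [jlcm_spec()].
#' @return Integer parameter count (for degree 3, intercept+slope random
#'   effects and 3 covariates this is `7G + 6`).
#' @export
jlcm_n_params <- function(spec) {
  G <- spec$n_classes
  q <- if (identical(spec$random_effects, "intercept")) 1L else 2L
  p <- length(spec$survival_covariates)
  as.integer((spec$poly_degree + 1) * G + (G - 1) + q * (q + 1) / 2 + 1 +
               2 * G + p)
}

# --- parameter packing --------------------------------------------------
# layout: xi (G-1) | beta (d+1 per class) | log sigma | chol (log l11
# [, l21, log l22]) | per class (log lambda, log rho) | gamma (p)
.theta_layout <- function(spec) {
  G <- spec$n_classes; d <- spec$poly_degree
  q <- if (identical(spec$random_effects, "intercept")) 1L else 2L
  p <- length(spec$survival_covariates)
  nb <- (d + 1) * G
  nch <- q * (q + 1) / 2
  i <- 0
  lay <- list(
    xi = if (G > 1) i + seq_len(G - 1) else integer(0))
  i <- i + G - 1
  lay$beta <- i + seq_len(nb); i <- i + nb
  lay$logsigma <- i + 1L; i <- i + 1L
  lay$chol <- i + seq_len(nch); i <- i + nch
  lay$weib <- i + seq_len(2 * G); i <- i + 2 * G
  lay$gamma <- i + seq_len(p); i <- i + p
  lay$total <- i
  lay$G <- G; lay$d <- d; lay$q <- q; lay$p <- p
  lay
}

.unpack_theta <- function(theta, lay) {
  G <- lay$G; d <- lay$d; q <- lay$q
  beta <- matrix(theta[lay$beta], d + 1, G)
  L <- matrix(0, q, q)
  if (q == 1L) {
    L[1, 1] <- exp(theta[lay$chol[1]])
  } else {
    L[1, 1] <- exp(theta[lay$chol[1]])
    L[2, 1] <- theta[lay$chol[2]]
    L[2, 2] <- exp(theta[lay$chol[3]])
  }
  wb <- matrix(exp(theta[lay$weib]), G, 2, byrow = TRUE)  # lambda, rho
  list(xi = theta[lay$xi], beta = beta, L = L,
       sigma = exp(theta[lay$logsigma]),
       weibull = wb, gamma = theta[lay$gamma])
}

.pack_theta <- function(par, lay) {
  th <- numeric(lay$total)
  th[lay$xi] <- par$xi
  th[lay$beta] <- as.numeric(par$beta)
  th[lay$logsigma] <- log(par$sigma)
  if (lay$q == 1L) th[lay$chol] <- log(par$L[1, 1])
  else th[lay$chol] <- c(log(par$L[1, 1]), par$L[2, 1], log(par$L[2, 2]))
  th[lay$weib] <- as.numeric(t(log(par$weibull)))
  th[lay$gamma] <- par$gamma
  th
}

# loglik from cached component matrices
.ll_from_parts <- function(logpi, llg, lls) {
  sum(.row_lse(sweep(llg + lls, 2, logpi, "+")))
}

# full component computation for a theta vector
.compute_parts <- function(theta, lay, prep) {
  par <- .unpack_theta(theta, lay)
  G <- lay$G
  llg <- matrix(0, prep$n, G); lls <- matrix(0, prep$n, G)
  for (g in seq_len(G)) {
    llg[, g] <- .gauss_loglik_class(prep, par$beta[, g], par$L, par$sigma)
    lls[, g] <- .surv_loglik_class(prep, par$weibull[g, 1], par$weibull[g, 2],
                                   par$gamma)
  }
  list(par = par, logpi = log(class_prior(par$xi)), llg = llg, lls = lls)
}

.jlcm_negloglik <- function(theta, lay, prep) {
  # out-of-range trial points can produce NaN in logs; they are mapped to a
  # large penalty so the line search backtracks
  ll <- suppressWarnings({
    p <- .compute_parts(theta, lay, prep)
    .ll_from_parts(p$logpi, p$llg, p$lls)
  })
  if (!is.finite(ll)) return(1e12)
  -ll
}

# central-difference gradient that only recomputes the component a
# parameter touches (class-specific columns, or the survival block)
.jlcm_neggrad <- function(theta, lay, prep) {
  base <- suppressWarnings(.compute_parts(theta, lay, prep))
  G <- lay$G; d <- lay$d
  grad <- numeric(lay$total)
  eval_at <- function(j, h) {
    th <- theta; th[j] <- th[j] + h
    par <- .unpack_theta(th, lay)
    if (j %in% lay$xi) {
      .ll_from_parts(log(class_prior(par$xi)), base$llg, base$lls)
    } else if (j %in% lay$beta) {
      g <- ((match(j, lay$beta) - 1) %/% (d + 1)) + 1
      llg <- base$llg
      llg[, g] <- .gauss_loglik_class(prep, par$beta[, g], par$L, par$sigma)
      .ll_from_parts(base$logpi, llg, base$lls)
    } else if (j == lay$logsigma || j %in% lay$chol) {
      llg <- base$llg
      for (g in seq_len(G))
        llg[, g] <- .gauss_loglik_class(prep, par$beta[, g], par$L, par$sigma)
      .ll_from_parts(base$logpi, llg, base$lls)
    } else if (j %in% lay$weib) {
      g <- ((match(j, lay$weib) - 1) %/% 2) + 1
      lls <- base$lls
      lls[, g] <- .surv_loglik_class(prep, par$weibull[g, 1],
                                     par$weibull[g, 2], par$gamma)
      .ll_from_parts(base$logpi, base$llg, lls)
    } else {
      lls <- base$lls
      for (g in seq_len(G))
        lls[, g] <- .surv_loglik_class(prep, par$weibull[g, 1],
                                       par$weibull[g, 2], par$gamma)
      .ll_from_parts(base$logpi, base$llg, lls)
    }
  }
  for (j in seq_len(lay$total)) {
    h <- 1e-5 * (1 + abs(theta[j]))
    grad[j] <- suppressWarnings(
      -(eval_at(j, h) - eval_at(j, -h)) / (2 * h))
  }
  grad
}

# --- initialization ------------------------------------------------------

.ols_int_slope <- function(prep) {
  n <- prep$U[, 1]; Su <- prep$U[, 2]; Suu <- prep$U[, 3]
  Sy <- prep$UY[, 1]; Suy <- prep$UY[, 2]
  den <- n * Suu - Su^2
  den[den < 1e-12] <- 1e-12
  slope <- (n * Suy - Su * Sy) / den
  int <- (Sy - slope * Su) / n
  cbind(int, slope)
}

# clustering features: per-subject mean platelet in early/middle/late
# windows (these capture dips and peaks that an overall intercept+slope
# summary cannot) plus the OLS slope; empty windows fall back to the
# subject mean
.shape_features <- function(prep) {
  t_days <- prep$u * .TIME_SCALE
  win <- cbind(t_days <= 3, t_days > 3 & t_days <= 9, t_days > 9)
  sums <- rowsum(prep$y * win, prep$idx, reorder = TRUE)
  cnts <- rowsum(win * 1, prep$idx, reorder = TRUE)
  means <- sums / cnts
  overall <- prep$UY[, 1] / prep$U[, 1]
  for (j in 1:3) means[cnts[, j] == 0, j] <- overall[cnts[, j] == 0]
  cbind(means, .ols_int_slope(prep)[, 2])
}

.init_start <- function(prep, spec, lay, start_index) {
  G <- spec$n_classes; d <- spec$poly_degree
  set.seed(spec$seed + 7L * start_index)
  feat <- .shape_features(prep)
  fs <- scale(feat)
  fs[!is.finite(fs)] <- 0
  if (G == 1L) {
    cl <- rep(1L, prep$n)
  } else {
    km <- tryCatch(kmeans(fs, centers = G, nstart = 20, iter.max = 50),
                   error = function(e) NULL)
    cl <- if (is.null(km)) sample.int(G, prep$n, replace = TRUE)
          else km$cluster
  }
  W <- outer(prep$u, 0:d, `^`)
  beta <- matrix(0, d + 1, G)
  sig2 <- numeric(G)
  gfit_all <- lm.fit(W, prep$y)
  for (g in seq_len(G)) {
    rows <- prep$idx %in% which(cl == g)
    bg <- tryCatch({
      f <- lm.fit(W[rows, , drop = FALSE], prep$y[rows])
      if (any(is.na(f$coefficients))) stop("singular")
      f$coefficients
    }, error = function(e) gfit_all$coefficients + rnorm(d + 1, 0, 5))
    beta[, g] <- bg
    rg <- prep$y[rows] - drop(W[rows, , drop = FALSE] %*% beta[, g])
    sig2[g] <- mean(rg^2)
  }
  sigma0 <- sqrt(mean(sig2))
  # split pooled residual variation between random effects and noise
  L <- diag(c(0.6, 0.4)[seq_len(lay$q)] * sigma0, lay$q)
  pi0 <- pmax(tabulate(cl, nbins = G) / prep$n, 0.02)
  pi0 <- pi0 / sum(pi0)
  xi0 <- log(pi0[-G] / pi0[G])
  wb <- matrix(0, G, 2)
  for (g in seq_len(G)) {
    sel <- cl == g
    wb[g, 1] <- (sum(prep$delta[sel]) + 0.5) / (sum(prep$T[sel]) + 1)
    wb[g, 2] <- 1
  }
  par <- list(xi = xi0, beta = beta, L = L, sigma = 0.8 * sigma0,
              weibull = wb, gamma = rep(0, lay$p))
  th <- .pack_theta(par, lay)
  if (start_index > 1) {
    th[lay$xi] <- th[lay$xi] + rnorm(length(lay$xi), 0, 0.3)
    th[lay$beta] <- th[lay$beta] + rnorm(length(lay$beta), 0, 8)
    th[lay$logsigma] <- th[lay$logsigma] + rnorm(1, 0, 0.15)
    th[lay$chol] <- th[lay$chol] + rnorm(length(lay$chol), 0, 0.2)
    th[lay$weib] <- th[lay$weib] + rnorm(length(lay$weib), 0, 0.3)
    th[lay$gamma] <- th[lay$gamma] + rnorm(length(lay$gamma), 0, 0.15)
  }
  th
}

# EM-style warm-up: alternate exact posterior computation with fast
# approximate M-steps (posterior-weighted polynomial OLS for the class
# trajectories, closed-form Weibull scale given shape, prior update) before
# handing over to the exact quasi-Newton maximization. This pulls crude
# cluster-based starts into the basin of the maximum and keeps small classes
# from collapsing.
.em_warmup <- function(theta, lay, prep, n_iter = 25L) {
  G <- lay$G; d <- lay$d
  W <- outer(prep$u, 0:d, `^`)
  for (it in seq_len(n_iter)) {
    par <- .unpack_theta(theta, lay)
    llg <- matrix(0, prep$n, G); lls <- matrix(0, prep$n, G)
    for (g in seq_len(G)) {
      llg[, g] <- .gauss_loglik_class(prep, par$beta[, g], par$L, par$sigma)
      lls[, g] <- .surv_loglik_class(prep, par$weibull[g, 1],
                                     par$weibull[g, 2], par$gamma)
    }
    post <- .jlcm_posterior(sweep(llg + lls, 2, log(class_prior(par$xi)),
                                  "+"))
    pi_new <- pmax(colMeans(post), 1e-4)
    pi_new <- pi_new / sum(pi_new)
    eta <- drop(prep$Xstd %*% par$gamma)
    for (g in seq_len(G)) {
      wr <- post[prep$idx, g]
      if (sum(wr) > d + 1) {
        bg <- tryCatch(stats::lm.wfit(W, prep$y, wr)$coefficients,
                       error = function(e) NULL)
        if (!is.null(bg) && all(is.finite(bg))) par$beta[, g] <- bg
      }
      rho <- par$weibull[g, 2]
      den <- sum(post[, g] * prep$T^rho * exp(eta))
      num <- sum(post[, g] * prep$delta)
      if (num > 0 && den > 0) par$weibull[g, 1] <- (num / den)^(1 / rho)
    }
    if (G > 1) par$xi <- log(pi_new[-G] / pi_new[G])
    theta <- .pack_theta(par, lay)
  }
  theta
}

# --- main fitting routine ------------------------------------------------

#' Fit a joint latent class model by maximum likelihood
#'
#' Maximizes the joint likelihood of the latent class mixed longitudinal
#' submodel (class-specific polynomial trajectories of scaled time, shared
#' random effects, shared residual variance) and the class-specific Weibull
#' proportional-hazards survival submodel, over unconstrained transformed
#' parameters (log residual SD, log Weibull parameters, log-diagonal
#' Cholesky factor of the random-effects covariance) using quasi-Newton
#' (BFGS) iterations from multiple initializations. Classes are relabeled by
#' descending prior probability.
#'
#' @param longitudinal Data frame: `subject_id`, `time_days`, `platelet`.
#' @param subjects Data frame: `subject_id`, survival covariates,
#'   `time_days` (follow-up), `event` (0/1).
#' @param spec A [jlcm_spec()].
#' @return An object of class `jlcm_fit`: list with `spec`, `params`
#'   (including `covariate_standardization`), `loglik`, `posterior` (N x G
#'   row-stochastic), `modal_class`, `n_params`, `converged`, diagnostics
#'   per start and `subject_id`.
#' @export
fit_jlcm <- function(longitudinal, subjects, spec = jlcm_spec()) {
  G <- spec$n_classes
  if (nrow(subjects) < 5 * G)
    stop("need at least ", 5 * G, " subjects to fit ", G, " classes")
  prep <- .jlcm_prepare(longitudinal, subjects, spec)
  lay <- .theta_layout(spec)
  parscale <- rep(1, lay$total)
  parscale[lay$beta] <- 10
  parscale[lay$xi] <- 0.5
  parscale[c(lay$logsigma, lay$chol, lay$weib)] <- 0.25
  parscale[lay$gamma] <- 0.25

  best <- NULL
  diags <- vector("list", spec$n_starts)
  for (s in seq_len(spec$n_starts)) {
    th0 <- .init_start(prep, spec, lay, s)
    if (G > 1) th0 <- .em_warmup(th0, lay, prep)
    res <- tryCatch(
      optim(th0, fn = .jlcm_negloglik, gr = .jlcm_neggrad,
            lay = lay, prep = prep, method = "BFGS",
            control = list(maxit = spec$max_iter, reltol = spec$rel_tol,
                           parscale = parscale)),
      error = function(e) NULL)
    if (is.null(res)) {
      diags[[s]] <- list(start = s, ok = FALSE)
      next
    }
    diags[[s]] <- list(start = s, ok = TRUE, loglik = -res$value,
                       convergence = res$convergence)
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$start <- s
    }
  }
  if (is.null(best))
    stop("all optimizer starts failed; diagnostics: ",
         paste(vapply(diags, function(d) paste0("start", d$start, ":failed"),
                      ""), collapse = " "))

  par <- .unpack_theta(best$par, lay)
  pi_hat <- class_prior(par$xi)
  ord <- order(pi_hat, decreasing = TRUE)
  pi_s <- pi_hat[ord]
  par$beta <- par$beta[, ord, drop = FALSE]
  par$weibull <- par$weibull[ord, , drop = FALSE]
  par$xi <- if (G > 1) log(pi_s[-G] / pi_s[G]) else numeric(0)

  B <- par$L %*% t(par$L)
  params <- structure(
    list(xi = par$xi, beta = par$beta, chol_B = par$L, B = B,
         sigma = par$sigma,
         weibull = matrix(par$weibull, G, 2,
                          dimnames = list(NULL, c("lambda", "rho"))),
         gamma = setNames(par$gamma, spec$survival_covariates),
         covariate_standardization = prep$standardization),
    class = "jlcm_params")
  attr(params, "spec") <- spec

  parts <- .jlcm_parts(params, prep)
  posterior <- .jlcm_posterior(parts$total)
  loglik <- sum(.row_lse(parts$total))

  structure(list(
    spec = spec,
    params = params,
    loglik = loglik,
    posterior = posterior,
    modal_class = max.col(posterior),
    n_params = jlcm_n_params(spec),
    converged = best$convergence == 0,
    n_starts_used = spec$n_starts,
    best_start = best$start,
    start_diagnostics = diags,
    n_subjects = prep$n,
    n_events = sum(prep$delta),
    subject_id = prep$subject_id),
    class = "jlcm_fit")
}

#' @export
print.jlcm_fit <- function(x, ...) {
  G <- x$spec$n_classes
  cat("Joint latent class model fit:", G, "class(es),",
      x$n_subjects, "subjects,", x$n_events, "events\n")
  cat(sprintf("  log-likelihood %.2f (%d parameters), converged: %s\n",
              x$loglik, x$n_params, x$converged))
  pi_hat <- class_prior(x$params$xi)
  cat("  class priors:", paste(sprintf("%.3f", pi_hat), collapse = " "), "\n")
  cat("  modal class sizes:",
      paste(tabulate(x$modal_class, nbins = G), collapse = "/"), "\n")
  invisible(x)
}
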