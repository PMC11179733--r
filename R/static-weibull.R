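#' Fit a single-class Weibull proportional-hazards comparator
#'
#' Maximum-likelihood Weibull regression with
#' `h(t|x) = rho lambda (lambda t)^(rho-1) exp(x_std' gamma)` on z-scored
#' covariates. This is the static baseline-covariates-only comparator for the
#' dynamic prediction model: it never sees longitudinal history.
#'
#' @param subjects Data frame with the covariates, `time_days` and `event`.
#' @param covariates Covariate column names (default APS III, CCI and
#'   baseline platelet).
#' @return Object of class `static_weibull`: list with `lambda`, `rho`,
#'   `gamma` (per standardized covariate), `loglik`,
#'   `covariate_standardization`, `converged`.
#' @export
fit_static_weibull <- function(subjects,
                               covariates = c("aps3", "cci",
                                              "platelet_baseline")) {
  if (nrow(subjects) < 10) stop("need at least 10 subjects")
  if (sum(subjects$event) < 1) stop("need at least one event")
  if (any(subjects$time_days <= 0)) stop("survival times must be > 0")
  X <- as.matrix(subjects[, covariates, drop = FALSE])
  std <- list(mean = colMeans(X), sd = apply(X, 2, sd))
  std$sd[std$sd == 0] <- 1
  Xstd <- sweep(sweep(X, 2, std$mean, "-"), 2, std$sd, "/")
  Tm <- subjects$time_days
  delta <- subjects$event
  logT <- log(Tm)
  p <- ncol(Xstd)

  negll <- function(th) {
    lam <- exp(th[1]); rho <- exp(th[2]); gam <- th[-(1:2)]
    eta <- drop(Xstd %*% gam)
    ll <- sum(delta * (log(rho) + rho * log(lam) + (rho - 1) * logT + eta) -
                exp(rho * (log(lam) + logT) + eta))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  th0 <- c(log(sum(delta) / sum(Tm)), 0, rep(0, p))
  fit <- optim(th0, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  structure(list(lambda = exp(fit$par[1]),
                 rho = exp(fit$par[2]),
                 gamma = setNames(fit$par[-(1:2)], covariates),
                 loglik = -fit$value,
                 covariate_standardization = std,
                 covariates = covariates,
                 converged = fit$convergence == 0),
            class = "static_weibull")
}

# standardized linear predictor for new subjects (raw covariate scale in)
.static_eta <- function(model, x) {
  std <- model$covariate_standardization
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  x <- x[, model$covariates, drop = FALSE]
  z <- sweep(sweep(x, 2, std$mean, "-"), 2, std$sd, "/")
  drop(z %*% model$gamma)
}

#' Survival function of a fitted static Weibull model
#'
#' @param model A `static_weibull`.
#' @param t Time(s) in days.
#' @param x Named covariate vector (raw scale) or matrix with subjects in
#'   rows.
#' @return Survival probabilities (vector, or matrix subjects x times).
#' @export
static_survival <- function(model, t, x) {
  eta <- .static_eta(model, x)
  cumh <- outer(exp(eta), (model$lambda * t)^model$rho)
  s <- exp(-cumh)
  if (length(eta) == 1L) drop(s) else s
}

#' @export
print.static_weibull <- function(x, ...) {
  cat(sprintf("Static Weibull PH model: lambda=%.4g, rho=%.3f, loglik=%.2f\n",
              x$lambda, x$rho, x$loglik))
  cat("  gamma (per SD):",
      paste(sprintf("%s=%.3f", names(x$gamma), x$gamma), collapse = ", "),
      "\n")
  invisible(x)
}
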