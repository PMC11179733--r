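# shared fixtures: all data are generated in code at test time

small_cohort <- function(n = 60, seed = 1, ...) {
  cfg <- default_cohort_config(n_subjects = n, seed = seed)
  extra <- list(...)
  for (f in names(extra)) cfg[[f]] <- extra[[f]]
  simulate_cohort(cfg)
}

# hand-constructed jlcm_fit with fully specified parameters (no fitting),
# identity covariate standardization and zero covariate effects by default
make_toy_fit <- function(beta, weibull, pi = NULL, sigma = 10,
                         B = diag(c(100, 25)), gamma = c(aps3 = 0, cci = 0,
                                                         platelet_baseline = 0)) {
  G <- ncol(beta)
  spec <- jlcm_spec(n_classes = G, survival_covariates = names(gamma))
  if (is.null(pi)) pi <- rep(1 / G, G)
  xi <- if (G > 1) log(pi[-G] / pi[G]) else numeric(0)
  L <- t(chol(B))
  params <- structure(list(
    xi = xi, beta = beta, chol_B = L, B = B, sigma = sigma,
    weibull = matrix(weibull, G, 2,
                     dimnames = list(NULL, c("lambda", "rho"))),
    gamma = gamma,
    covariate_standardization = list(
      mean = setNames(rep(0, length(gamma)), names(gamma)),
      sd = setNames(rep(1, length(gamma)), names(gamma)))),
    class = "jlcm_params")
  attr(params, "spec") <- spec
  structure(list(spec = spec, params = params, loglik = NA_real_,
                 posterior = NULL, modal_class = NULL,
                 n_params = jlcm_n_params(spec), converged = TRUE),
            class = "jlcm_fit")
}

# dense per-subject joint log-likelihood oracle (explicit matrices, no
# shared code with the vectorized implementation path)
dense_joint_loglik <- function(params, longitudinal, subjects) {
  spec <- attr(params, "spec")
  G <- spec$n_classes
  d <- spec$poly_degree
  q <- if (identical(spec$random_effects, "intercept")) 1L else 2L
  std <- params$covariate_standardization
  pi_g <- class_prior(params$xi)
  ll <- 0
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    sel <- longitudinal$subject_id == id
    t <- longitudinal$time_days[sel]
    y <- longitudinal$platelet[sel][order(t)]
    t <- sort(t)
    keep <- !duplicated(t)
    t <- t[keep]; y <- y[keep]
    u <- t / 28
    W <- outer(u, 0:d, `^`)
    Z <- W[, seq_len(q), drop = FALSE]
    xr <- unlist(subjects[i, names(params$gamma)])
    z <- (xr - std$mean) / std$sd
    eta <- sum(z * params$gamma)
    Ti <- subjects$time_days[i]
    di <- subjects$event[i]
    terms <- vapply(seq_len(G), function(g) {
      V <- Z %*% params$B[seq_len(q), seq_len(q)] %*% t(Z) +
        diag(params$sigma^2, length(y))
      r <- y - drop(W %*% params$beta[, g])
      lg <- -0.5 * (length(y) * log(2 * pi) + log(det(V)) +
                      drop(t(r) %*% solve(V) %*% r))
      lam <- params$weibull[g, 1]; rho <- params$weibull[g, 2]
      ls <- di * (log(rho) + rho * log(lam) + (rho - 1) * log(Ti) + eta) -
        (lam * Ti)^rho * exp(eta)
      log(pi_g[g]) + lg + ls
    }, numeric(1))
    m <- max(terms)
    ll <- ll + m + log(sum(exp(terms - m)))
  }
  ll
}

# accuracy of modal classification under the best label permutation
best_permutation_accuracy <- function(modal, true, G) {
  perms <- expand.grid(rep(list(seq_len(G)), G))
  best <- 0
  best_perm <- seq_len(G)
  for (r in seq_len(nrow(perms))) {
    p <- as.integer(perms[r, ])
    if (length(unique(p)) < G) next
    acc <- mean(p[modal] == true)
    if (acc > best) { best <- acc; best_perm <- p }
  }
  list(accuracy = best, perm = best_perm)
}
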