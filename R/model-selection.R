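#' Information criteria for class-number selection
#'
#' `AIC = 2k - 2 loglik`, `BIC = k ln(N) - 2 loglik`, and the
#' sample-size-adjusted BIC `SABIC = k ln((N + 2)/24) - 2 loglik`, with `N`
#' the number of subjects.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters k.
#' @param n_subjects Number of subjects N (> 0).
#' @return Named numeric vector `c(AIC, BIC, SABIC)`.
#' @export
information_criteria <- function(loglik, n_params, n_subjects) {
  if (n_subjects <= 0) stop("n_subjects must be > 0")
  m2ll <- -2 * loglik
  c(AIC = 2 * n_params + m2ll,
    BIC = n_params * log(n_subjects) + m2ll,
    SABIC = n_params * log((n_subjects + 2) / 24) + m2ll)
}

#' Relative entropy of a posterior classification
#'
#' `E = 1 - sum_i sum_g (-p_ig ln p_ig) / (N ln G)`, with `0 ln 0 = 0`;
#' 1 indicates perfectly separated classes, 0 uninformative posteriors. For
#' a single class the classification is perfect by construction and the
#' convention `E = 1` applies.
#'
#' @param posterior N x G row-stochastic matrix of posterior class
#'   probabilities (or a `jlcm_fit`).
#' @return Scalar in [0, 1].
#' @export
relative_entropy <- function(posterior) {
  if (inherits(posterior, "jlcm_fit")) posterior <- posterior$posterior
  p <- as.matrix(posterior)
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("posterior rows must sum to 1 (within 1e-6)")
  G <- ncol(p)
  if (G == 1L) return(1)
  plogp <- ifelse(p > 0, p * log(p), 0)
  ent <- -sum(plogp)
  1 - ent / (nrow(p) * log(G))
}

#' Fit a range of class numbers and tabulate selection metrics
#'
#' Fits the joint latent class model for each G in `G_range` and reports the
#' log-likelihood, parameter count, AIC, BIC, SABIC, relative entropy and
#' modal-class proportions. Criteria decrease steadily with G on rich data,
#' so the entropy-maximal G is flagged as selected.
#'
#' @param longitudinal,subjects Data tables as in [fit_jlcm()].
#' @param G_range Integer vector of class numbers to fit.
#' @param spec Base [jlcm_spec()]; its `n_classes` field is overridden.
#' @return Data frame of class `jlcm_selection` with one row per G and an
#'   attribute `fits` (list of `jlcm_fit` or `NULL` for failed rows);
#'   attribute `selected` holds the entropy-maximal G.
#' @export
select_num_classes <- function(longitudinal, subjects, G_range,
                               spec = jlcm_spec()) {
  if (!length(G_range)) stop("G_range must be non-empty")
  G_range <- as.integer(G_range)
  fits <- vector("list", length(G_range))
  rows <- vector("list", length(G_range))
  maxG <- max(G_range)
  for (i in seq_along(G_range)) {
    G <- G_range[i]
    sp <- spec
    sp$n_classes <- G
    fit <- tryCatch(fit_jlcm(longitudinal, subjects, sp),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(G = G, loglik = NA_real_, k = NA_integer_,
                              AIC = NA_real_, BIC = NA_real_,
                              SABIC = NA_real_, entropy = NA_real_,
                              failed = TRUE)
      rows[[i]][paste0("prop_", seq_len(maxG))] <- NA_real_
      next
    }
    fits[[i]] <- fit
    ic <- information_criteria(fit$loglik, fit$n_params, fit$n_subjects)
    props <- tabulate(fit$modal_class, nbins = G) / fit$n_subjects
    r <- data.frame(G = G, loglik = fit$loglik, k = fit$n_params,
                    AIC = ic["AIC"], BIC = ic["BIC"], SABIC = ic["SABIC"],
                    entropy = relative_entropy(fit$posterior),
                    failed = FALSE)
    r[paste0("prop_", seq_len(maxG))] <- c(props, rep(NA_real_, maxG - G))
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # the G = 1 entropy of 1 is a convention, not evidence of separation, so
  # the entropy rule selects among the multi-class fits when any succeeded
  cand <- which(!is.na(out$entropy) & (out$G > 1 | all(out$G == 1)))
  if (!length(cand)) cand <- which(!is.na(out$entropy))
  sel <- if (!length(cand)) NA_integer_
         else out$G[cand[which.max(out$entropy[cand])]]
  structure(out, fits = fits, selected = sel, class = c("jlcm_selection",
                                                        "data.frame"))
}

#' Posterior classification quality by modal class
#'
#' For each modal class: size, mean posterior probability of the assigned
#' class, and the fraction of members whose own-class posterior exceeds each
#' threshold.
#'
#' @param fit A `jlcm_fit` (or a posterior matrix).
#' @param thresholds Posterior probability thresholds.
#' @return Data frame with one row per class.
#' @export
posterior_quality <- function(fit, thresholds = c(0.5, 0.7, 0.8, 0.9)) {
  p <- if (inherits(fit, "jlcm_fit")) fit$posterior else as.matrix(fit)
  G <- ncol(p)
  modal <- max.col(p)
  own <- p[cbind(seq_len(nrow(p)), modal)]
  out <- do.call(rbind, lapply(seq_len(G), function(g) {
    sel <- modal == g
    r <- data.frame(class = g, n = sum(sel),
                    mean_posterior = if (any(sel)) mean(own[sel]) else NA_real_)
    for (th in thresholds)
      r[[sprintf("frac_gt_%g", th)]] <-
        if (any(sel)) mean(own[sel] > th) else NA_real_
    r
  }))
  rownames(out) <- NULL
  out
}
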