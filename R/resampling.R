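#' Percentile bootstrap confidence interval for a subject-level metric
#'
#' Resamples subjects with replacement `B` times and returns the percentile
#' 2.5/97.5 interval. Resamples where the metric is undefined (error or NA)
#' are skipped and counted; more than 50% degenerate resamples is an error.
#'
#' @param metric_fn Function of an index vector returning a scalar; it is
#'   called as `metric_fn(idx)` where `idx` indexes subjects of the original
#'   sample.
#' @param n Number of subjects.
#' @param B Number of bootstrap resamples (>= 10; default 2000).
#' @param seed Integer seed.
#' @return List with `point`, `lo95`, `hi95`, `n_degenerate`.
#' @export
bootstrap_ci <- function(metric_fn, n, B = 2000, seed = 1L) {
  if (B < 10) stop("B must be >= 10")
  point <- metric_fn(seq_len(n))
  set.seed(seed)
  vals <- numeric(B)
  degen <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(metric_fn(idx), error = function(e) NA_real_)
    if (is.na(v)) { degen <- degen + 1L; vals[b] <- NA_real_ }
    else vals[b] <- v
  }
  if (degen > B / 2) stop("more than 50% of bootstrap resamples degenerate")
  q <- quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(point = point, lo95 = q[1], hi95 = q[2], n_degenerate = degen)
}

#' Paired permutation comparison of two prediction models
#'
#' Tests whether a discrimination metric differs between two models that
#' produced paired predictions on the same subjects. The null distribution
#' is generated by independently swapping each subject's pair of predictions
#' with probability 1/2; the two-sided p-value is
#' `(1 + #\{|d*| >= |d|\}) / (n_perm + 1)`.
#'
#' @param risk_A,risk_B Paired risk scores from the two models.
#' @param times,events Shared outcomes.
#' @param metric Function `(risk, times, events) -> scalar`.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @return List with `observed` (metric A - metric B), `p_value`.
#' @export
permutation_compare <- function(risk_A, risk_B, times, events, metric,
                                n_perm = 2000, seed = 1L) {
  if (length(risk_A) != length(risk_B) ||
      length(risk_A) != length(times))
    stop("risk_A, risk_B and outcomes must be paired (equal length)")
  obs <- metric(risk_A, times, events) - metric(risk_B, times, events)
  set.seed(seed)
  n <- length(risk_A)
  count <- 0L
  for (p in seq_len(n_perm)) {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, risk_B, risk_A)
    b <- ifelse(swap, risk_A, risk_B)
    d <- metric(a, times, events) - metric(b, times, events)
    if (abs(d) >= abs(obs) - 1e-12) count <- count + 1L
  }
  list(observed = obs, p_value = (1 + count) / (n_perm + 1))
}
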