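#' Kaplan-Meier product-limit estimator
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @return Object of class `survival_curve`: data frame with `time`,
#'   `n_risk`, `n_event`, `survival` (step function starting at 1).
#' @export
km_estimator <- function(times, events) {
  if (!length(times)) stop("empty input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  sf <- survfit(Surv(times, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, survival = sf$surv)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Log-rank test across groups
#'
#' @param times,events As in [km_estimator()].
#' @param groups Group labels (>= 2 distinct values).
#' @return List with `statistic` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- as.factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups")
  sd_ <- survdiff(Surv(times, events) ~ g)
  df <- length(sd_$n) - 1
  list(statistic = sd_$chisq, df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs ordered concordantly by the risk score: a pair
#' (i, j) is usable when i has an event and `T_i < T_j`; ties in risk score
#' count 1/2.
#'
#' @param risk_scores Higher = predicted to fail earlier.
#' @param times,events Follow-up times and 0/1 event indicators.
#' @return List with `c_index`, `n_concordant`, `n_discordant`, `n_tied`,
#'   `n_pairs`.
#' @export
concordance_index <- function(risk_scores, times, events) {
  stopifnot(length(risk_scores) == length(times),
            length(times) == length(events))
  conc <- disc <- tied <- 0
  for (i in which(events == 1)) {
    j <- times > times[i]
    if (!any(j)) next
    d <- risk_scores[i] - risk_scores[j]
    conc <- conc + sum(d > 0)
    disc <- disc + sum(d < 0)
    tied <- tied + sum(d == 0)
  }
  n_pairs <- conc + disc + tied
  if (n_pairs == 0) stop("no usable pairs")
  list(c_index = (conc + 0.5 * tied) / n_pairs,
       n_concordant = conc, n_discordant = disc, n_tied = tied,
       n_pairs = n_pairs)
}

# censoring-distribution KM evaluated as a left-continuous step function
.censor_km <- function(times, events) {
  sf <- survfit(Surv(times, 1 - events) ~ 1)
  function(t) {
    # G(t-) : survival just before t
    if (!length(sf$time)) return(rep(1, length(t)))
    vapply(t, function(ti) {
      j <- sf$time < ti
      if (!any(j)) 1 else min(sf$surv[j])
    }, numeric(1))
  }
}

#' Cumulative/dynamic time-dependent AUC
#'
#' Discrimination between cases (events in `(s, t]`) and controls (subjects
#' surviving past `t`) at a landmark. The default IPCW estimator weights
#' cases by the inverse of the censoring-distribution Kaplan-Meier just
#' before their event time; `method = "naive"` simply drops subjects
#' censored inside `(s, t)`.
#'
#' @param risk_scores Higher = higher predicted risk.
#' @param times,events Follow-up among subjects at risk at `s`.
#' @param s Landmark day.
#' @param t Horizon day (> s).
#' @param method `"ipcw"` (default) or `"naive"`.
#' @return Scalar AUC.
#' @export
time_dependent_auc <- function(risk_scores, times, events, s, t,
                               method = c("ipcw", "naive")) {
  method <- match.arg(method)
  stopifnot(t > s, all(times > s))
  case <- events == 1 & times <= t
  ctrl <- times > t | (times == t & events == 0)
  if (!any(case)) stop("no cases in (s, t]")
  if (!any(ctrl)) stop("no controls past t")
  if (method == "ipcw") {
    G <- .censor_km(times, events)
    w_case <- 1 / pmax(G(times[case]), 1e-10)
  } else {
    w_case <- rep(1, sum(case))
  }
  rc <- risk_scores[case]
  rk <- risk_scores[ctrl]
  # controls carry a common weight, which cancels in the ratio
  num <- 0
  for (k in seq_along(rc)) {
    d <- rc[k] - rk
    num <- num + w_case[k] * (sum(d > 0) + 0.5 * sum(d == 0))
  }
  num / (sum(w_case) * length(rk))
}

#' Binary classification metrics at a risk threshold
#'
#' @param risk_scores Predicted risk in [0, 1].
#' @param binary_outcomes 0/1 observed outcomes (indeterminate subjects must
#'   be excluded upstream).
#' @param threshold Classification threshold on risk (default 0.5).
#' @return List with `accuracy`, `sensitivity`, `specificity` (NA when a
#'   class is absent) and the 2x2 counts.
#' @export
confusion_metrics <- function(risk_scores, binary_outcomes, threshold = 0.5) {
  stopifnot(length(risk_scores) == length(binary_outcomes),
            all(binary_outcomes %in% c(0, 1)))
  pred <- as.integer(risk_scores >= threshold)
  tp <- sum(pred == 1 & binary_outcomes == 1)
  fn <- sum(pred == 0 & binary_outcomes == 1)
  fp <- sum(pred == 1 & binary_outcomes == 0)
  tn <- sum(pred == 0 & binary_outcomes == 0)
  list(accuracy = (tp + tn) / length(pred),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fn = fn, fp = fp, tn = tn)
}
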