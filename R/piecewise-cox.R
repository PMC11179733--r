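#' Split follow-up into counting-process intervals at cut points
#'
#' Expands each subject's follow-up `(0, T_i]` into one `(start, stop]` row
#' per traversed interval; the event indicator is carried only by the final
#' row. Total exposure is preserved exactly.
#'
#' @param subjects Data frame with `subject_id`, `time_days`, `event`.
#' @param classes Vector of class assignments aligned with `subjects` rows.
#' @param cutpoints Strictly increasing cut points inside the follow-up
#'   window.
#' @return Data frame (`counting_process` class attribute): `subject_id`,
#'   `start`, `stop`, `event`, `interval_id`, `interval`, `class`.
#' @export
split_followup <- function(subjects, classes, cutpoints) {
  stopifnot(length(classes) == nrow(subjects))
  cutpoints <- sort(unique(as.numeric(cutpoints)))
  maxT <- max(subjects$time_days)
  if (length(cutpoints) && (any(cutpoints <= 0) || any(cutpoints >= maxT)))
    stop("cutpoints must lie strictly inside (0, max follow-up)")
  bounds <- c(0, cutpoints, Inf)
  nint <- length(bounds) - 1
  labels <- paste0("(", bounds[-length(bounds)], ",",
                   ifelse(is.finite(bounds[-1]), bounds[-1], "Inf"), "]")
  Tm <- subjects$time_days
  rows <- lapply(seq_len(nint), function(j) {
    sel <- Tm > bounds[j]
    if (!any(sel)) return(NULL)
    stop_ <- pmin(bounds[j + 1], Tm[sel])
    data.frame(subject_id = subjects$subject_id[sel], start = bounds[j],
               stop = stop_, event = subjects$event[sel] *
                 as.integer(Tm[sel] <= bounds[j + 1]),
               interval_id = j, class = classes[sel])
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$subject_id, subjects$subject_id),
                   out$interval_id), , drop = FALSE]
  out$interval <- labels[out$interval_id]
  rownames(out) <- NULL
  attr(out, "cutpoints") <- cutpoints
  attr(out, "n_intervals") <- nint
  class(out) <- c("counting_process", "data.frame")
  out
}

#' Cox partial-likelihood fit on counting-process data
#'
#' Maximizes the Cox partial likelihood for left-truncated `(start, stop]`
#' data with Efron tie handling (via the survival package), returning the
#' coefficient MLE, inverse-information covariance and the maximized partial
#' log-likelihood.
#'
#' @param counting_table A data frame with `start`, `stop`, `event` and the
#'   term columns.
#' @param terms Character vector of covariate column names.
#' @return List with `coef`, `vcov`, `partial_loglik`, `converged` and the
#'   underlying `coxph` fit.
#' @export
fit_cox <- function(counting_table, terms) {
  if (sum(counting_table$event) < 1) stop("need at least one event")
  if (!length(terms)) stop("no model terms")
  fml <- stats::as.formula(paste("Surv(start, stop, event) ~",
                                 paste(sprintf("`%s`", terms),
                                       collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    coxph(fml, data = counting_table, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  list(coef = stats::coef(fit),
       vcov = stats::vcov(fit),
       partial_loglik = fit$loglik[length(fit$loglik)],
       converged = !flagged,
       fit = fit)
}

#' Piecewise Cox model with class-by-interval hazard ratios
#'
#' Splits follow-up at the cut points and fits a Cox model with one
#' indicator term per (non-reference class x interval) cell, optionally
#' adjusted for subject-level covariates; class 1 (the smallest class label)
#' is the reference, so each exponentiated coefficient is the hazard ratio
#' of that class versus class 1 within that interval.
#'
#' @param subjects Data frame with `subject_id`, `time_days`, `event` and any
#'   adjuster columns.
#' @param classes Class assignment vector aligned with `subjects`.
#' @param cutpoints Numeric cut points (possibly empty for a single
#'   interval).
#' @param adjusters Optional character vector of covariate columns to adjust
#'   for (standardized internally).
#' @return Object of class `piecewise_cox_fit`: list with `cutpoints`,
#'   `hr_table` (term, interval, HR, lo95, hi95, p, n_events), `coef`,
#'   `vcov`, `partial_loglik`, `n_events_per_interval`, `converged`.
#' @export
fit_piecewise_cox <- function(subjects, classes, cutpoints,
                              adjusters = NULL) {
  lev <- sort(unique(classes))
  if (length(lev) < 2) stop("need at least two classes")
  ref <- lev[1]
  ct <- split_followup(subjects, classes, cutpoints)
  nint <- attr(ct, "n_intervals")
  labels <- unique(ct$interval[order(ct$interval_id)])
  terms <- character(0)
  for (g in lev[-1]) for (j in seq_len(nint)) {
    nm <- sprintf("cls%s_int%d", g, j)
    ct[[nm]] <- as.integer(ct$class == g & ct$interval_id == j)
    terms <- c(terms, nm)
  }
  if (!is.null(adjusters)) {
    for (a in adjusters) {
      v <- subjects[[a]][match(ct$subject_id, subjects$subject_id)]
      ct[[a]] <- (v - mean(subjects[[a]])) / sd(subjects[[a]])
    }
    terms <- c(terms, adjusters)
  }
  cf <- fit_cox(ct, terms)
  ev_int <- tapply(ct$event, ct$interval_id, sum)
  n_ev <- setNames(integer(nint), seq_len(nint))
  n_ev[names(ev_int)] <- ev_int

  rows <- list()
  for (g in lev[-1]) for (j in seq_len(nint)) {
    nm <- sprintf("cls%s_int%d", g, j)
    b <- cf$coef[nm]
    se <- sqrt(cf$vcov[nm, nm])
    cell_events <- sum(ct$event[ct$class == g & ct$interval_id == j])
    estimable <- is.finite(b) && is.finite(se) && se < 50 && cell_events > 0
    rows[[length(rows) + 1]] <- data.frame(
      term = paste0("class", g), interval = labels[j],
      HR = if (estimable) exp(b) else NA_real_,
      lo95 = if (estimable) exp(b - 1.96 * se) else NA_real_,
      hi95 = if (estimable) exp(b + 1.96 * se) else NA_real_,
      p = if (estimable) 2 * pnorm(-abs(b / se)) else NA_real_,
      n_events = cell_events,
      estimable = estimable)
  }
  hr <- do.call(rbind, rows)
  rownames(hr) <- NULL
  structure(list(cutpoints = sort(unique(as.numeric(cutpoints))),
                 reference = ref,
                 hr_table = hr,
                 coef = cf$coef, vcov = cf$vcov,
                 partial_loglik = cf$partial_loglik,
                 n_events_per_interval = n_ev,
                 converged = cf$converged,
                 counting_table = ct,
                 cox = cf$fit),
            class = "piecewise_cox_fit")
}

#' @export
print.piecewise_cox_fit <- function(x, ...) {
  cat("Piecewise Cox fit, cutpoints:",
      if (length(x$cutpoints)) paste(x$cutpoints, collapse = ", ")
      else "(none)",
      sprintf(" partial loglik %.3f\n", x$partial_loglik))
  print(x$hr_table, digits = 3)
  invisible(x)
}

#' Search for the cut point maximizing the partial likelihood
#'
#' Fits the single-cut piecewise Cox model at each candidate day and returns
#' the candidate with the highest maximized partial log-likelihood (ties
#' broken toward the smaller cut point) together with the full profile.
#'
#' @param subjects,classes As in [fit_piecewise_cox()].
#' @param candidate_days At least two candidate cut points (default days
#'   1..14).
#' @param adjusters Optional adjusters passed through.
#' @return List with `best` (selected cut point) and `profile` (data frame:
#'   cutpoint, partial_loglik, converged).
#' @export
search_cutpoint <- function(subjects, classes, candidate_days = 1:14,
                            adjusters = NULL) {
  if (length(candidate_days) < 2) stop("need at least two candidate days")
  prof <- lapply(candidate_days, function(tau) {
    f <- tryCatch(fit_piecewise_cox(subjects, classes, tau, adjusters),
                  error = function(e) NULL)
    if (is.null(f))
      data.frame(cutpoint = tau, partial_loglik = NA_real_, converged = FALSE)
    else
      data.frame(cutpoint = tau, partial_loglik = f$partial_loglik,
                 converged = f$converged)
  })
  prof <- do.call(rbind, prof)
  if (all(is.na(prof$partial_loglik))) stop("all candidate cut points failed")
  ok <- which(!is.na(prof$partial_loglik))
  best <- prof$cutpoint[ok[which.max(prof$partial_loglik[ok])]]
  list(best = best, profile = prof)
}

#' Proportional-hazards score test on scaled Schoenfeld residuals
#'
#' Grambsch-Therneau style test of the correlation between scaled Schoenfeld
#' residuals and time, per term and globally.
#'
#' @param fit A `piecewise_cox_fit` or a list returned by [fit_cox()].
#' @return Data frame with `term`, `chisq`, `df`, `p` (last row `GLOBAL`),
#'   or all-`NA` rows when the test is degenerate (e.g. a single event).
#' @export
ph_test <- function(fit) {
  cox <- if (inherits(fit, "piecewise_cox_fit")) fit$cox else fit$fit
  z <- tryCatch(cox.zph(cox, transform = "identity"),
                error = function(e) NULL)
  if (is.null(z)) {
    return(data.frame(term = "GLOBAL", chisq = NA_real_, df = NA_real_,
                      p = NA_real_))
  }
  tab <- as.data.frame(z$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}
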