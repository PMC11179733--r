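# CSV files carry a schema declaration in a leading comment line; readers
# check it so stale or foreign files fail loudly.

.SCHEMAS <- list(
  longitudinal = c("subject_id", "time_days", "platelet"),
  subjects = c("subject_id", "aps3", "cci", "platelet_baseline",
               "time_days", "event", "true_class"))

.write_schema_csv <- function(df, path, schema) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# schema: trajsurv/%s v1", schema), con)
  write.csv(df, con, row.names = FALSE)
}

.read_schema_csv <- function(path, schema) {
  first <- readLines(path, n = 1)
  expected <- sprintf("# schema: trajsurv/%s v1", schema)
  if (!identical(first, expected))
    stop("schema mismatch in ", path, ": expected '", expected, "'")
  read.csv(path, comment.char = "#")
}

#' Write a simulated cohort to CSV files
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`longitudinal`, `subjects`,
#'   `config`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(longitudinal = file.path(dir, "longitudinal.csv"),
             subjects = file.path(dir, "subjects.csv"),
             config = file.path(dir, "cohort_config.yaml"))
  .write_schema_csv(cohort$longitudinal, paths["longitudinal"],
                    "longitudinal")
  .write_schema_csv(cohort$subjects, paths["subjects"], "subjects")
  write_cohort_config(cohort$config, paths["config"])
  invisible(paths)
}

#' Read cohort CSV files written by [write_cohort()]
#'
#' @param dir Directory holding `longitudinal.csv` and `subjects.csv`.
#' @return List with `longitudinal` and `subjects` data frames (and
#'   `config` if present).
#' @export
read_cohort <- function(dir) {
  out <- list(
    longitudinal = .read_schema_csv(file.path(dir, "longitudinal.csv"),
                                    "longitudinal"),
    subjects = .read_schema_csv(file.path(dir, "subjects.csv"), "subjects"))
  cfg <- file.path(dir, "cohort_config.yaml")
  if (file.exists(cfg)) out$config <- read_cohort_config(cfg)
  out
}

#' Serialize a cohort configuration as structured text
#'
#' Round-trippable `key: value` (YAML) serialization.
#'
#' @param config A `cohort_config`.
#' @param path Output file.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$classes <- lapply(x$classes, unclass)
  for (f in c("covariate_effects", "covariate_means", "covariate_sds"))
    x[[f]] <- as.list(x[[f]])
  write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @return `read_cohort_config()` returns the reconstructed `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  x <- read_yaml(path)
  classes <- lapply(x$classes, function(cl)
    class_spec(cl$proportion, unlist(cl$fixed_effects), cl$weibull_scale,
               cl$weibull_shape, cl$label))
  cohort_config(n_subjects = x$n_subjects, classes = classes,
                re_sd_intercept = x$re_sd_intercept,
                re_sd_slope = x$re_sd_slope, re_corr = x$re_corr,
                resid_sd = x$resid_sd,
                covariate_effects = unlist(x$covariate_effects),
                covariate_means = unlist(x$covariate_means),
                covariate_sds = unlist(x$covariate_sds),
                measurement_interval_days = x$measurement_interval_days,
                missing_rate = x$missing_rate,
                admin_censor_day = x$admin_censor_day,
                discharge_rate = x$discharge_rate,
                seed = x$seed)
}

#' Serialize a fitted joint latent class model to JSON
#'
#' Stores all parameters, the covariate standardization, the model
#' specification, the log-likelihood and a schema version; enough to
#' reconstruct predictions exactly (the posterior matrix itself is not
#' stored).
#'
#' @param fit A `jlcm_fit`.
#' @param path Output JSON file.
#' @export
write_jlcm_model <- function(fit, path) {
  p <- fit$params
  obj <- list(
    schema = "trajsurv/jlcm-model",
    schema_version = 1L,
    spec = unclass(fit$spec),
    params = list(
      # matrices are flattened column-major; dimensions are implied by the
      # spec on read
      xi = p$xi, beta = as.numeric(p$beta),
      chol_B = as.numeric(p$chol_B), sigma = p$sigma,
      weibull = as.numeric(p$weibull), gamma = as.list(p$gamma),
      covariate_standardization = lapply(p$covariate_standardization,
                                         as.list)),
    loglik = fit$loglik,
    n_params = fit$n_params,
    converged = fit$converged,
    n_subjects = fit$n_subjects,
    n_events = fit$n_events)
  write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted joint latent class model from JSON
#'
#' @param path JSON file written by [write_jlcm_model()].
#' @return A `jlcm_fit` object (without posterior/modal-class fields, which
#'   belong to the training data).
#' @export
read_jlcm_model <- function(path) {
  obj <- read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "trajsurv/jlcm-model"))
    stop("not a trajsurv model file: ", path)
  sp <- obj$spec
  spec <- jlcm_spec(n_classes = sp$n_classes, poly_degree = sp$poly_degree,
                    random_effects = sp$random_effects,
                    survival_covariates = sp$survival_covariates,
                    n_starts = sp$n_starts, max_iter = sp$max_iter,
                    rel_tol = sp$rel_tol, seed = sp$seed)
  G <- spec$n_classes
  d <- spec$poly_degree
  q <- if (identical(spec$random_effects, "intercept")) 1L else 2L
  pj <- obj$params
  beta <- matrix(unlist(pj$beta), d + 1, G)
  L <- matrix(unlist(pj$chol_B), q, q)
  wb <- matrix(unlist(pj$weibull), G, 2,
               dimnames = list(NULL, c("lambda", "rho")))
  std <- list(mean = unlist(pj$covariate_standardization$mean),
              sd = unlist(pj$covariate_standardization$sd))
  params <- structure(
    list(xi = as.numeric(unlist(pj$xi)), beta = beta, chol_B = L,
         B = L %*% t(L), sigma = pj$sigma, weibull = wb,
         gamma = unlist(pj$gamma),
         covariate_standardization = std),
    class = "jlcm_params")
  attr(params, "spec") <- spec
  structure(list(spec = spec, params = params, loglik = obj$loglik,
                 posterior = NULL, modal_class = NULL,
                 n_params = obj$n_params, converged = obj$converged,
                 n_subjects = obj$n_subjects, n_events = obj$n_events),
            class = "jlcm_fit")
}
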