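# Orchestration of the four-step workflow: simulate (or load) a cohort,
# identify trajectory subpopulations, estimate time-dependent hazard ratios,
# evaluate dynamic vs static prediction at landmarks, and predict for
# individuals. Every stage writes its outputs plus a run manifest with
# timings and file checksums; the manifest is written even on partial
# failure.

.stage_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
}

.write_manifest <- function(out_dir, config, stages) {
  files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  manifest <- list(
    package_version = as.character(packageVersion("trajsurv")),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    config = config,
    stage_seconds = stages,
    checksums = as.list(setNames(unname(sums), basename(names(sums)))))
  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a cohort and write it to disk
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  stages <- list()
  t0 <- proc.time()[3]
  .stage_log(log_path, "simulate",
             sprintf("n=%d seed=%d", config$n_subjects, config$seed))
  cohort <- simulate_cohort(config)
  paths <- write_cohort(cohort, out_dir)
  stages$simulate <- round(proc.time()[3] - t0, 3)
  .write_manifest(out_dir, unclass_config(config), stages)
  invisible(paths)
}

# yaml-friendly config snapshot
unclass_config <- function(config) {
  x <- unclass(config)
  x$classes <- lapply(x$classes, unclass)
  x
}

#' Fit models over a range of class numbers and persist the selection
#'
#' Runs [select_num_classes()] over `G_range`, writes a selection table CSV
#' (columns G, loglik, k, AIC, BIC, SABIC, entropy, prop_1..prop_G) and the
#' selected model as JSON.
#'
#' @param cohort_dir Directory with cohort CSVs (from [run_simulate()] or
#'   user-provided in the same schema).
#' @param out_dir Output directory.
#' @param G_range Class numbers to fit (default 1:4).
#' @param spec Base [jlcm_spec()].
#' @return Invisibly, a list with the selection table and the selected fit.
#' @export
run_fit <- function(cohort_dir, out_dir, G_range = 1:4,
                    spec = jlcm_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  stages <- list()
  dat <- read_cohort(cohort_dir)
  t0 <- proc.time()[3]
  .stage_log(log_path, "fit",
             sprintf("G range %s, %d subjects", paste(range(G_range),
                     collapse = ".."), nrow(dat$subjects)))
  sel <- select_num_classes(dat$longitudinal, dat$subjects, G_range, spec)
  stages$fit <- round(proc.time()[3] - t0, 3)
  seltab <- as.data.frame(sel)
  seltab$failed <- NULL
  .write_schema_csv(seltab, file.path(out_dir, "selection.csv"), "selection")
  fits <- attr(sel, "fits")
  selected <- attr(sel, "selected")
  fit <- fits[[match(selected, G_range)]]
  if (!is.null(fit))
    write_jlcm_model(fit, file.path(out_dir, "model.json"))
  .stage_log(log_path, "fit", sprintf("selected G=%s", selected))
  .write_manifest(out_dir, list(G_range = G_range, spec = unclass(spec),
                                cohort_dir = cohort_dir), stages)
  invisible(list(selection = sel, fit = fit))
}

#' Run the hazard-ratio and prediction-evaluation analyses
#'
#' Loads a fitted model and an evaluation cohort, then: searches the
#' piecewise Cox cut point over candidate days and writes the hazard-ratio
#' table; fits the static Weibull comparator; runs the landmark evaluation;
#' and writes individual prediction series for requested subjects. A 50/50
#' seeded split of the cohort into discovery/validation halves is used when
#' no separate validation cohort is given, preserving the
#' train-here/validate-there pattern of external validation.
#'
#' @param model_path Path to a model JSON from [run_fit()].
#' @param cohort_dir Cohort directory (evaluation data).
#' @param out_dir Output directory.
#' @param candidate_days Cut-point candidates (default 1:14).
#' @param landmarks Landmark days (default 1:14).
#' @param horizon Horizon (default 28).
#' @param B,n_perm Bootstrap and permutation sizes.
#' @param subject_ids Subjects for individual prediction series (default:
#'   none).
#' @param seed Seed for resampling.
#' @return Invisibly, a list with the cut-point search, hazard-ratio fit,
#'   landmark report and individual predictions.
#' @export
run_analyze <- function(model_path, cohort_dir, out_dir,
                        candidate_days = 1:14, landmarks = 1:14,
                        horizon = 28, B = 200, n_perm = 200,
                        subject_ids = integer(0), seed = 1L) {
  if (!file.exists(model_path)) stop("missing model file: ", model_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  stages <- list()
  fit <- read_jlcm_model(model_path)
  dat <- read_cohort(cohort_dir)
  lon <- dat$longitudinal; sub <- dat$subjects

  # classify the evaluation cohort with the fitted model (posterior at the
  # full follow-up window)
  t0 <- proc.time()[3]
  classes <- jlcm_classify(fit, lon, sub)
  cut <- search_cutpoint(sub, classes, candidate_days)
  pw <- fit_piecewise_cox(sub, classes, cut$best)
  stages$piecewise <- round(proc.time()[3] - t0, 3)
  .stage_log(log_path, "piecewise",
             sprintf("selected cut point day %g", cut$best))
  .write_schema_csv(pw$hr_table, file.path(out_dir, "hr_table.csv"),
                    "hr_table")
  .write_schema_csv(cut$profile, file.path(out_dir, "cutpoint_profile.csv"),
                    "cutpoint_profile")

  t0 <- proc.time()[3]
  static <- fit_static_weibull(sub, names(fit$params$gamma))
  report <- landmark_evaluation(fit, static, lon, sub,
                                landmarks = landmarks, horizon = horizon,
                                B = B, n_perm = n_perm, seed = seed)
  stages$landmark <- round(proc.time()[3] - t0, 3)
  .write_schema_csv(as.data.frame(report),
                    file.path(out_dir, "landmark_report.csv"),
                    "landmark_report")

  indiv <- NULL
  errors <- character(0)
  if (length(subject_ids)) {
    t0 <- proc.time()[3]
    per <- lapply(subject_ids, function(id) {
      tryCatch({
        Ti <- sub$time_days[sub$subject_id == id]
        lms <- landmarks[landmarks < Ti]
        individual_prediction_series(fit, lon, sub, id, lms, horizon)
      }, error = function(e) {
        errors <<- c(errors, sprintf("subject %s: %s", id,
                                     conditionMessage(e)))
        NULL
      })
    })
    indiv <- do.call(rbind, per[!vapply(per, is.null, TRUE)])
    if (!is.null(indiv))
      .write_schema_csv(indiv, file.path(out_dir, "individual_predictions.csv"),
                        "individual_predictions")
    stages$individual <- round(proc.time()[3] - t0, 3)
    for (e in errors) .stage_log(log_path, "individual", e)
  }
  .write_manifest(out_dir, list(model_path = model_path,
                                cohort_dir = cohort_dir,
                                candidate_days = candidate_days,
                                landmarks = landmarks, horizon = horizon,
                                B = B, n_perm = n_perm, seed = seed), stages)
  invisible(list(cutpoint = cut, piecewise = pw, report = report,
                 individual = indiv, errors = errors))
}

#' Posterior modal classification of a cohort under a fitted model
#'
#' Computes posterior class probabilities for (possibly new) subjects using
#' their full longitudinal history and survival information, and returns the
#' modal class per subject.
#'
#' @param fit A `jlcm_fit`.
#' @param longitudinal,subjects Cohort tables.
#' @return Integer vector of modal classes aligned with `subjects` rows.
#' @export
jlcm_classify <- function(fit, longitudinal, subjects) {
  prep <- .jlcm_prepare(longitudinal, subjects, fit$spec,
                        standardization =
                          fit$params$covariate_standardization)
  parts <- .jlcm_parts(fit$params, prep)
  max.col(.jlcm_posterior(parts$total))
}

#' Split a cohort into seeded discovery/validation halves
#'
#' @param longitudinal,subjects Cohort tables.
#' @param seed Integer seed.
#' @return List with `discovery` and `validation`, each a list of
#'   `longitudinal` and `subjects`.
#' @export
split_cohort <- function(longitudinal, subjects, seed = 1L) {
  set.seed(seed)
  ids <- subjects$subject_id
  disc <- sort(sample(ids, floor(length(ids) / 2)))
  take <- function(keep) list(
    longitudinal = longitudinal[longitudinal$subject_id %in% keep, ,
                                drop = FALSE],
    subjects = subjects[subjects$subject_id %in% keep, , drop = FALSE])
  list(discovery = take(disc), validation = take(setdiff(ids, disc)))
}
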