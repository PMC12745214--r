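#' Minimum cohort size under the events-per-variable rule
#'
#' The cohort sizing rule used in the study design: 5--10 subjects per
#' independent variable, inflated for an anticipated dropout rate; the
#' result is the floor of `n_vars * multiplier / (1 - dropout_rate)`.
#'
#' @param n_vars Number of independent variables (>= 1).
#' @param multiplier Subjects per variable, conventionally in 5--10.
#' @param dropout_rate Anticipated dropout fraction in \[0, 1).
#' @return Integer minimum cohort size.
#' @examples
#' required_sample_size(17, 5, 0.10)   # 94
#' required_sample_size(17, 10, 0.10)  # 188
#' @export
required_sample_size <- function(n_vars, multiplier, dropout_rate = 0) {
  stopifnot(n_vars >= 1, multiplier > 0)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  as.integer(floor(n_vars * multiplier / (1 - dropout_rate)))
}

#' Run the full trajectory / cost-effectiveness pipeline
#'
#' End-to-end orchestration: read (or simulate) the three input tables,
#' compute the item-level dysfunction/improvement summary, select and fit
#' the trajectory model, compare covariates across the fitted groups, fit
#' the proportional-odds model on the significant covariates, and compute
#' the per-group cost-effectiveness table. Each stage's output is written
#' as a plain CSV under `output_dir` and listed, with an MD5 checksum, in
#' the returned run report.
#'
#' @param config A list (see Details) or `NULL` to run the synthetic
#'   default. Recognised elements: `cohort` (an `"icf_cohort"`), or
#'   `assessments_csv` / `covariates_csv` / `episodes_csv` paths, or
#'   `synthetic` (a `"cohort_config"`); `K_range` (default `2:5`);
#'   `orders` (default 2); `avepp_min` (0.7); `share_min` (0.05); `alpha`
#'   (0.05, univariate screening level for the ordinal model); `n_starts`
#'   (default 2); `seed`.
#' @param output_dir Directory for stage outputs (created if needed);
#'   `NULL` skips writing.
#' @param seed Master seed (overrides `config$seed`).
#' @param verbose Print stage progress.
#' @return An object of class `"icf_run_report"`: per-stage status and
#'   warnings, the output manifest with checksums, and the stage results
#'   (`item_summary`, `selection`, `fit`, `univariate`, `ordinal`,
#'   `cost_table`).
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL, seed = NULL,
                         verbose = TRUE) {
  if (is.null(config)) config <- list()
  seed <- if (!is.null(seed)) seed else
    if (!is.null(config$seed)) config$seed else 1L
  say <- function(...) if (verbose) message(...)
  report <- list(package_version = as.character(utils::packageVersion("icftraj")),
                 seed = seed, stages = list(), warnings = character(),
                 manifest = data.frame(file = character(),
                                       md5 = character()))
  note_warning <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  # ---- stage 1: inputs ----
  say("stage 1: inputs")
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    assessments <- cohort$assessments
    covariates <- cohort$covariates
    episodes <- cohort$episodes
  } else if (!is.null(config$assessments_csv)) {
    for (p in c(config$assessments_csv, config$covariates_csv,
                config$episodes_csv)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
    assessments <- read_assessments(config$assessments_csv)
    covariates <- utils::read.csv(config$covariates_csv,
                                  stringsAsFactors = FALSE)
    episodes <- utils::read.csv(config$episodes_csv,
                                stringsAsFactors = FALSE)
    cohort <- NULL
  } else {
    sc <- if (!is.null(config$synthetic)) config$synthetic else
      default_cohort_config()
    cohort <- simulate_cohort(sc, seed = seed)
    assessments <- cohort$assessments
    covariates <- cohort$covariates
    episodes <- cohort$episodes
  }
  validation <- withCallingHandlers(validate_cohort(assessments),
                                    warning = note_warning)
  report$stages$inputs <- list(status = "ok",
                               n_patients = length(unique(assessments$patient_id)),
                               n_assessments = nrow(assessments),
                               n_violations = validation$n_violations)

  # ---- stage 2: instrument summary ----
  say("stage 2: item summaries")
  ae <- admission_endpoint(assessments)
  item_summary <- item_cohort_summary(ae$admission, ae$endpoint)
  report$stages$item_summary <- list(status = "ok")

  # ---- stage 3: trajectory model selection ----
  say("stage 3: trajectory model")
  assessments <- add_total_score(assessments)
  K_range <- if (!is.null(config$K_range)) config$K_range else 2:5
  orders <- if (!is.null(config$orders)) config$orders else 2
  n_starts <- if (!is.null(config$n_starts)) config$n_starts else 2
  selection <- withCallingHandlers(
    select_gbtm(total ~ day | patient_id, assessments, K_range = K_range,
                orders = orders,
                avepp_min = if (!is.null(config$avepp_min))
                  config$avepp_min else 0.7,
                share_min = if (!is.null(config$share_min))
                  config$share_min else 0.05,
                n_starts = n_starts, seed = seed),
    warning = note_warning)
  fit <- selection$chosen
  report$stages$gbtm <- list(status = "ok", chosen_K = selection$chosen_K,
                             admissible = selection$admissible,
                             bic = fit$bic, converged = fit$converged)

  # ---- stage 4: group comparisons ----
  say("stage 4: group comparisons")
  assignment <- predict(fit, type = "class")
  cv <- covariates[match(names(assignment), covariates$patient_id), ]
  grp <- assignment
  univariate <- withCallingHandlers(compare_groups(cv, grp),
                                    warning = note_warning)
  alpha <- if (!is.null(config$alpha)) config$alpha else 0.05
  keep <- univariate$variable[univariate$p_value <= alpha]
  keep <- setdiff(keep, "patient_id")
  ordinal <- NULL
  if (length(keep) >= 1) {
    ordinal <- tryCatch(
      withCallingHandlers(
        ordinal_logit_fit(cv, grp, predictors = keep),
        warning = note_warning),
      error = function(e) {
        report$warnings <<- c(report$warnings,
                              paste("ordinal fit failed:",
                                    conditionMessage(e)))
        NULL
      })
  }
  report$stages$comparison <- list(status = "ok",
                                   significant = keep,
                                   ordinal_fitted = !is.null(ordinal))

  # ---- stage 5: cost-effectiveness ----
  say("stage 5: cost-effectiveness")
  cost_table <- withCallingHandlers(
    group_cost_table(assessments, episodes, assignment),
    warning = note_warning)
  report$stages$cost <- list(status = "ok")

  # ---- outputs ----
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    emit <- function(df, name) {
      p <- file.path(output_dir, name)
      utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
      report$manifest <<- rbind(report$manifest,
                                data.frame(file = name,
                                           md5 = unname(tools::md5sum(p))))
    }
    emit(item_summary, "item_summary.csv")
    emit(selection$candidates, "model_selection.csv")
    emit(trajectory_curves(fit), "trajectory_curves.csv")
    post <- as.data.frame(predict(fit, type = "posterior"))
    names(post) <- paste0("group", seq_len(ncol(post)))
    post <- cbind(patient_id = fit$ids, post,
                  assignment = fit$assignment)
    emit(post, "posteriors.csv")
    emit(univariate, "univariate_comparison.csv")
    if (!is.null(ordinal)) emit(ordinal$terms, "ordinal_terms.csv")
    emit(cost_table, "cost_effectiveness.csv")
  }

  report$results <- list(item_summary = item_summary, selection = selection,
                         fit = fit, univariate = univariate,
                         ordinal = ordinal, cost_table = cost_table,
                         validation = validation)
  class(report) <- "icf_run_report"
  report
}

#' @export
print.icf_run_report <- function(x, ...) {
  cat("Pipeline run report (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat("  ", nm, ": ", st$status, sep = "")
    if (!is.null(st$chosen_K)) cat("  [K =", st$chosen_K, "]")
    cat("\n")
  }
  if (length(x$warnings)) {
    cat("  warnings:", length(x$warnings), "\n")
  }
  if (nrow(x$manifest)) {
    cat("  outputs:\n")
    for (i in seq_len(nrow(x$manifest))) {
      cat("    ", x$manifest$file[i], " ", x$manifest$md5[i], "\n", sep = "")
    }
  }
  invisible(x)
}
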