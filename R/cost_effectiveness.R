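#' Cost-effectiveness index arithmetic
#'
#' The four per-group rehabilitation indices, each a ratio of group means
#' (not a mean of per-patient ratios):
#' \describe{
#'   \item{`daily_cost`}{mean treatment cost / mean length of stay
#'     (currency per day).}
#'   \item{`effect_index`}{100 x mean score improvement / mean admission
#'     score (percent functional gain).}
#'   \item{`efficiency_index`}{effect index / mean length of stay
#'     (percent per day).}
#'   \item{`benefit_index`}{mean treatment cost / mean score improvement
#'     (currency per 1-point improvement).}
#' }
#'
#' @param cost_mean Mean treatment cost of the group.
#' @param los_mean Mean length of stay in days (> 0).
#' @return `daily_cost()`: currency units per day.
#' @examples
#' daily_cost(56321, 88.9)      # 633.53
#' benefit_index(15463, 8.5)    # 1819.18
#' effect_index(31.5, 91.3)     # 34.5
#' efficiency_index(34.13, 31.9) # 1.07
#' @export
daily_cost <- function(cost_mean, los_mean) {
  if (any(los_mean <= 0)) stop("length of stay must be positive")
  cost_mean / los_mean
}

#' @rdname daily_cost
#' @param improvement Mean score improvement (admission mean minus
#'   discharge mean).
#' @param admission_mean Mean admission score (> 0).
#' @export
effect_index <- function(improvement, admission_mean) {
  if (any(admission_mean <= 0)) stop("admission mean must be positive")
  100 * improvement / admission_mean
}

#' @rdname daily_cost
#' @param effect Effect index in percent.
#' @export
efficiency_index <- function(effect, los_mean) {
  if (any(los_mean <= 0)) stop("length of stay must be positive")
  effect / los_mean
}

#' @rdname daily_cost
#' @export
benefit_index <- function(cost_mean, improvement) {
  out <- rep(NA_real_, length(improvement))
  zero_cost <- cost_mean == 0
  ok <- improvement > 0
  if (any(!ok & !zero_cost)) {
    warning("benefit index undefined for group(s) with no mean improvement")
  }
  out[ok] <- cost_mean[ok] / improvement[ok]
  out[zero_cost] <- 0
  out
}

#' Per-trajectory-group cost-effectiveness table
#'
#' Aggregates a cohort by trajectory group: mean admission and discharge
#' totals, mean improvement, mean length of stay and treatment cost, and
#' the four ratio-of-means indices. Optionally (`per_patient = TRUE`) the
#' indices are instead computed as means of per-patient ratios, for
#' sensitivity analysis.
#'
#' @param assessments Long-format assessment data frame (`patient_id`,
#'   `day`, item columns or a `total` column).
#' @param episodes Data frame `patient_id`, `length_of_stay`, `cost`.
#' @param assignment Named vector (or data frame `patient_id`, `group`)
#'   giving each patient's trajectory group.
#' @param per_patient Use mean-of-ratios instead of ratio-of-means.
#' @return Data frame, one row per group: `group`, `n`, `admission_mean`,
#'   `discharge_mean`, `improvement`, `los_mean`, `cost_mean`,
#'   `daily_cost`, `effect_index`, `efficiency_index`, `benefit_index`.
#'   Groups with no members are omitted with a warning.
#' @export
group_cost_table <- function(assessments, episodes, assignment,
                             per_patient = FALSE) {
  if (is.data.frame(assignment)) {
    assignment <- stats::setNames(assignment$group, assignment$patient_id)
  }
  if (!("total" %in% names(assessments))) {
    assessments <- add_total_score(assessments)
  }
  ae <- admission_endpoint_totals(assessments)
  ids <- ae$patient_id
  miss <- setdiff(ids, names(assignment))
  if (length(miss) > 0) {
    stop("patients without a group assignment: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  miss_ep <- setdiff(ids, episodes$patient_id)
  if (length(miss_ep) > 0) {
    stop("patients without an episode record: ",
         paste(utils::head(miss_ep, 5), collapse = ", "))
  }
  ep <- episodes[match(ids, episodes$patient_id), ]
  g <- assignment[ids]
  groups <- sort(unique(g))
  all_groups <- seq_len(max(as.integer(groups)))
  if (length(setdiff(all_groups, as.integer(groups))) > 0) {
    warning("omitting empty group(s): ",
            paste(setdiff(all_groups, as.integer(groups)), collapse = ", "))
  }
  rows <- lapply(groups, function(k) {
    sel <- g == k
    adm <- ae$admission_total[sel]
    dis <- ae$endpoint_total[sel]
    los <- ep$length_of_stay[sel]
    cost <- ep$cost[sel]
    if (per_patient) {
      imp_i <- adm - dis
      ok <- imp_i > 0
      data.frame(group = k, n = sum(sel),
                 admission_mean = mean(adm), discharge_mean = mean(dis),
                 improvement = mean(imp_i),
                 los_mean = mean(los), cost_mean = mean(cost),
                 daily_cost = mean(daily_cost(cost, los)),
                 effect_index = mean(effect_index(imp_i[adm > 0],
                                                  adm[adm > 0])),
                 efficiency_index = mean(effect_index(imp_i[adm > 0],
                                                      adm[adm > 0]) /
                                           los[adm > 0]),
                 benefit_index = mean(cost[ok] / imp_i[ok]))
    } else {
      imp <- mean(adm) - mean(dis)
      eff <- effect_index(imp, mean(adm))
      data.frame(group = k, n = sum(sel),
                 admission_mean = mean(adm), discharge_mean = mean(dis),
                 improvement = imp,
                 los_mean = mean(los), cost_mean = mean(cost),
                 daily_cost = daily_cost(mean(cost), mean(los)),
                 effect_index = eff,
                 efficiency_index = efficiency_index(eff, mean(los)),
                 benefit_index = benefit_index(mean(cost), imp))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# admission (first) and endpoint (last) totals per patient
admission_endpoint_totals <- function(assessments) {
  ord <- order(assessments$patient_id, assessments$day)
  a <- assessments[ord, ]
  first <- !duplicated(a$patient_id)
  last <- !duplicated(a$patient_id, fromLast = TRUE)
  data.frame(patient_id = a$patient_id[first],
             admission_total = a$total[first],
             endpoint_total = a$total[last],
             stringsAsFactors = FALSE)
}
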