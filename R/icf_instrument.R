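#' The 20-item ICF disability assessment instrument
#'
#' Returns the item catalogue of the 20-item disability assessment tool
#' derived from the ICF (International Classification of Functioning,
#' Disability and Health). Each item is scored on a 0--10 numerical rating
#' scale where 0 means no problem and 10 means complete dysfunction, so the
#' total score ranges over 0--200 with higher values indicating worse
#' function. Four somatic-function items (b130, b134, b152, b280) are
#' self-reported; the rest are observer-rated.
#'
#' @return A data frame with one row per item and columns `code`, `name`,
#'   `functional_area` (one of `"self_care_activities"`,
#'   `"cognition_perception"`, `"emotion_spirit"`) and `rating_mode`
#'   (`"self_reported"` or `"observer_rated"`).
#' @examples
#' items <- icf_items()
#' table(items$functional_area)
#' @export
icf_items <- function() {
  items <- data.frame(
    code = c("d450", "d455", "b455", "b525", "b620", "d530", "d230",
             "d510", "d520", "d540", "d550",
             "b114", "b144", "b210", "b230", "d710",
             "b130", "b152", "b280", "b134"),
    name = c("Walking", "Moving around", "Exercise tolerance functions",
             "Defecation functions", "Urination functions", "Toileting",
             "Carrying out daily routine", "Washing oneself",
             "Caring for body parts", "Dressing", "Eating",
             "Orientation functions", "Memory functions", "Seeing functions",
             "Hearing functions", "Basic interpersonal interactions",
             "Energy and drive functions", "Emotional functions",
             "Sensation of pain", "Sleep functions"),
    functional_area = c(rep("self_care_activities", 11),
                        rep("cognition_perception", 5),
                        rep("emotion_spirit", 4)),
    stringsAsFactors = FALSE
  )
  items$rating_mode <- ifelse(items$code %in% c("b130", "b134", "b152", "b280"),
                              "self_reported", "observer_rated")
  items
}

#' Item codes of the instrument
#'
#' @return Character vector of the 20 ICF item codes, in catalogue order.
#' @export
icf_item_codes <- function() icf_items()$code

# Check that a data frame carries all 20 item columns with scores in 0..10.
check_score_columns <- function(df, where = "assessment table") {
  codes <- icf_item_codes()
  missing <- setdiff(codes, names(df))
  if (length(missing) > 0L) {
    stop("missing item column(s) in ", where, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(codes)
}

#' Total ICF disability score
#'
#' Sums the 20 item scores of one assessment. Scores must each lie in
#' 0--10, so the total lies in 0--200.
#'
#' @param scores A named numeric vector, list, or single-row data frame
#'   containing all 20 item codes as names/columns.
#' @return Integer total in \[0, 200\].
#' @examples
#' s <- setNames(rep(5, 20), icf_item_codes())
#' total_score(s)  # 100
#' @export
total_score <- function(scores) {
  if (is.data.frame(scores)) {
    if (nrow(scores) != 1L) stop("expected a single assessment (one row)")
    check_score_columns(scores, "assessment")
    scores <- unlist(scores[, icf_item_codes(), drop = FALSE])
  } else {
    scores <- unlist(scores)
    missing <- setdiff(icf_item_codes(), names(scores))
    if (length(missing) > 0L) {
      stop("missing item score(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    scores <- scores[icf_item_codes()]
  }
  if (anyNA(scores)) stop("NA item score")
  if (any(scores < 0 | scores > 10)) stop("item scores must lie in [0, 10]")
  as.integer(round(sum(scores)))
}

#' Item-level dysfunction and improvement summary
#'
#' Computes, for each of the 20 items, the cohort counts and means that
#' describe dysfunction at admission and improvement at the study endpoint:
#' how many patients had any dysfunction (admission score > 0), how many of
#' those improved (endpoint score strictly below admission score), the
#' admission and endpoint score means over all patients, the mean
#' improvement, and the improvement rate (mean improvement as a percentage
#' of the admission mean).
#'
#' @param admissions Data frame of admission assessments: `patient_id` plus
#'   the 20 item columns.
#' @param endpoints Data frame of endpoint assessments with the same
#'   columns; must contain exactly the same patients.
#' @return A data frame with one row per item: `code`, `name`,
#'   `functional_area`, `n_dysfunction`, `pct_dysfunction`, `n_improved`,
#'   `pct_improved`, `mean_admission`, `mean_discharge`, `improvement`,
#'   `improvement_rate`.
#' @export
item_cohort_summary <- function(admissions, endpoints) {
  check_score_columns(admissions, "admission table")
  check_score_columns(endpoints, "endpoint table")
  if (nrow(admissions) == 0L) stop("empty cohort")
  if (!("patient_id" %in% names(admissions)) ||
      !("patient_id" %in% names(endpoints))) {
    stop("both tables need a patient_id column")
  }
  unpaired <- union(setdiff(admissions$patient_id, endpoints$patient_id),
                    setdiff(endpoints$patient_id, admissions$patient_id))
  if (length(unpaired) > 0L) {
    stop("unpaired patient(s): ", paste(unpaired, collapse = ", "),
         call. = FALSE)
  }
  endpoints <- endpoints[match(admissions$patient_id, endpoints$patient_id), ]
  items <- icf_items()
  n <- nrow(admissions)
  out <- lapply(items$code, function(code) {
    adm <- admissions[[code]]
    end <- endpoints[[code]]
    dys <- adm > 0
    n_dys <- sum(dys)
    n_imp <- sum(dys & end < adm)
    mean_adm <- mean(adm)
    mean_dis <- mean(end)
    imp <- mean_adm - mean_dis
    data.frame(
      code = code,
      n_dysfunction = n_dys,
      pct_dysfunction = 100 * n_dys / n,
      n_improved = n_imp,
      pct_improved = if (n_dys > 0) 100 * n_imp / n_dys else 0,
      mean_admission = mean_adm,
      mean_discharge = mean_dis,
      improvement = imp,
      improvement_rate = if (mean_adm > 0) 100 * imp / mean_adm else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  cbind(items[, c("code", "name", "functional_area")],
        out[, setdiff(names(out), "code")])
}

#' Validate a longitudinal assessment table
#'
#' Report-only screening of a long-format assessment table against the
#' cohort inclusion rules: every patient needs at least two assessments,
#' every item score must lie in 0--10, and no patient may have two
#' assessments on the same day.
#'
#' @param records Long-format data frame: `patient_id`, `day`, plus the 20
#'   item columns (one row per patient-visit).
#' @return A list of class `"icf_validation"` with elements
#'   `too_few_assessments` (patient ids), `out_of_range` (data frame of
#'   patient_id/day/code/value), `duplicated_days` (data frame of
#'   patient_id/day), and `n_violations`.
#' @export
validate_cohort <- function(records) {
  codes <- check_score_columns(records, "assessment table")
  counts <- table(records$patient_id)
  too_few <- names(counts)[counts < 2]

  score_mat <- as.matrix(records[, codes, drop = FALSE])
  bad <- which(is.na(score_mat) | score_mat < 0 | score_mat > 10,
               arr.ind = TRUE)
  out_of_range <- if (nrow(bad) > 0L) {
    data.frame(patient_id = records$patient_id[bad[, 1]],
               day = records$day[bad[, 1]],
               code = codes[bad[, 2]],
               value = score_mat[bad],
               stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = character(), day = numeric(),
               code = character(), value = numeric())
  }

  key <- paste(records$patient_id, records$day, sep = "\r")
  dup <- duplicated(key)
  duplicated_days <- unique(records[dup, c("patient_id", "day")])
  rownames(duplicated_days) <- NULL

  res <- list(too_few_assessments = too_few,
              out_of_range = out_of_range,
              duplicated_days = duplicated_days,
              n_violations = length(too_few) + nrow(out_of_range) +
                nrow(duplicated_days))
  class(res) <- "icf_validation"
  res
}

#' @export
print.icf_validation <- function(x, ...) {
  cat("Cohort validation report\n")
  cat("  patients with fewer than two assessments:",
      length(x$too_few_assessments), "\n")
  cat("  out-of-range item scores:", nrow(x$out_of_range), "\n")
  cat("  duplicated assessment days:", nrow(x$duplicated_days), "\n")
  if (x$n_violations == 0) cat("  clean cohort\n")
  invisible(x)
}

#' Read / write long-format assessment tables
#'
#' The on-disk format is a UTF-8 CSV with columns `patient_id`, `day`, then
#' the 20 item columns named by ICF code. `read_assessments()` validates
#' the header strictly.
#'
#' @param path File path.
#' @return `read_assessments()` returns the assessment data frame.
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  expected <- c("patient_id", "day", icf_item_codes())
  if (!identical(names(df)[seq_along(expected)], expected)) {
    stop("bad assessment header in ", path, "; expected columns: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_assessments
#' @param records Assessment data frame to write.
#' @export
write_assessments <- function(records, path) {
  check_score_columns(records)
  cols <- c("patient_id", "day", icf_item_codes())
  utils::write.csv(records[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Extract admission / endpoint assessments per patient
#'
#' The admission assessment is each patient's earliest visit; the endpoint
#' is the last available assessment regardless of the reason the episode
#' ended (discharge, referral, death or end of study).
#'
#' @param records Long-format assessment data frame.
#' @return A list with data frames `admission` and `endpoint`.
#' @export
admission_endpoint <- function(records) {
  check_score_columns(records)
  ord <- order(records$patient_id, records$day)
  records <- records[ord, ]
  first <- !duplicated(records$patient_id)
  last <- !duplicated(records$patient_id, fromLast = TRUE)
  list(admission = records[first, ], endpoint = records[last, ])
}

#' Total scores of a long-format assessment table
#'
#' @param records Long-format assessment data frame.
#' @return The input with a `total` column appended (row sums of the 20
#'   item columns).
#' @export
add_total_score <- function(records) {
  codes <- check_score_columns(records)
  records$total <- rowSums(records[, codes, drop = FALSE])
  records
}
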