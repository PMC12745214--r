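#' Model selection for the trajectory model
#'
#' Fits a censored-normal trajectory model for every candidate number of
#' groups and applies the reported selection rule: a candidate is
#' admissible when every group's average posterior probability of
#' assignment (Avepp) exceeds `avepp_min` and every group holds at least
#' `share_min` of the patients; among admissible candidates the one with
#' BIC closest to 0 is chosen. If no candidate is admissible the best-BIC
#' candidate is returned with `admissible = FALSE`.
#'
#' @param formula,data As for [gbtm()].
#' @param K_range Integer vector of candidate group counts.
#' @param orders Polynomial order(s), passed to [gbtm()].
#' @param avepp_min Avepp admissibility threshold (default 0.7).
#' @param share_min Minimum assigned share per group (default 0.05).
#' @param ... Further arguments passed to [gbtm()] (`n_starts`, `seed`,
#'   `bounds`, ...).
#' @return An object of class `"gbtm_selection"`: a list with `candidates`
#'   (data frame of K, bic, min_avepp, min_share, admissible), `chosen`
#'   (the selected `"gbtm"` fit), `chosen_K` and `admissible`.
#' @export
select_gbtm <- function(formula, data, K_range, orders = 2,
                        avepp_min = 0.7, share_min = 0.05, ...) {
  if (length(K_range) == 0) stop("empty K_range")
  fits <- lapply(K_range, function(K) {
    gbtm(formula, data, ngroups = K, orders = orders, ...)
  })
  cand <- data.frame(
    K = K_range,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    min_avepp = vapply(fits, function(f) min(f$avepp, na.rm = TRUE),
                       numeric(1)),
    min_share = vapply(fits, function(f) min(f$shares), numeric(1))
  )
  cand$admissible <- cand$min_avepp > avepp_min & cand$min_share >= share_min
  pool <- if (any(cand$admissible)) which(cand$admissible) else
    seq_along(fits)
  pick <- pool[which.min(abs(cand$bic[pool]))]
  out <- list(candidates = cand, chosen = fits[[pick]],
              chosen_K = K_range[pick],
              admissible = cand$admissible[pick],
              thresholds = c(avepp_min = avepp_min, share_min = share_min))
  class(out) <- "gbtm_selection"
  out
}

#' @export
print.gbtm_selection <- function(x, ...) {
  cat("Trajectory model selection (Avepp >", x$thresholds["avepp_min"],
      ", share >=", x$thresholds["share_min"], ", BIC closest to 0)\n")
  print(transform(x$candidates,
                  loglik = round(loglik, 1), bic = round(bic, 1),
                  min_avepp = round(min_avepp, 3),
                  min_share = round(min_share, 3)))
  cat("chosen: K =", x$chosen_K,
      if (x$admissible) "(admissible)" else "(no admissible candidate)", "\n")
  invisible(x)
}

#' Dump / load a fitted trajectory model as structured text
#'
#' Writes the specification, parameters and diagnostics of a fit to a
#' plain-text key/value file that [read_gbtm()] can restore (posteriors
#' and data are not stored; the round trip restores parameters and
#' summary diagnostics only).
#'
#' @param object A `"gbtm"` fit.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gbtm <- function(object, path) {
  stopifnot(inherits(object, "gbtm"))
  num <- function(x) paste(sprintf("%.17g", as.numeric(x)), collapse = " ")
  lines <- c(
    paste("ngroups:", object$ngroups),
    paste("orders:", num(object$orders)),
    paste("bounds:", num(object$bounds)),
    paste("time_scale:", num(object$time_scale)),
    paste("group_probs:", num(object$group_probs)),
    paste("sigma:", num(object$sigma)),
    paste("loglik:", num(object$loglik)),
    paste("bic:", num(object$bic)),
    paste("n_params:", object$n_params),
    paste("n_subjects:", object$n_subjects),
    paste("avepp:", num(object$avepp)),
    paste("shares:", num(object$shares)),
    paste("converged:", object$converged),
    vapply(seq_len(object$ngroups), function(k) {
      paste0("coef_group", k, ": ", num(object$coefficients[k, ]))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gbtm
#' @export
read_gbtm <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) {
    v <- strsplit(x[2], " ", fixed = TRUE)[[1]]
    suppressWarnings(n <- as.numeric(v))
    if (anyNA(n)) v else n
  }), vapply(kv, `[[`, character(1), 1))
  K <- as.integer(vals$ngroups)
  cf <- do.call(rbind, lapply(seq_len(K),
                              function(k) vals[[paste0("coef_group", k)]]))
  rownames(cf) <- paste0("group", seq_len(K))
  colnames(cf) <- paste0("t^", seq_len(ncol(cf)) - 1)
  list(ngroups = K, orders = as.integer(vals$orders), bounds = vals$bounds,
       time_scale = vals$time_scale, group_probs = vals$group_probs,
       coefficients = cf, sigma = vals$sigma, loglik = vals$loglik,
       bic = vals$bic, n_params = as.integer(vals$n_params),
       n_subjects = as.integer(vals$n_subjects), avepp = vals$avepp,
       shares = vals$shares, converged = as.logical(vals$converged))
}
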