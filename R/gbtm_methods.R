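#' @export
print.gbtm <- function(x, digits = 3, ...) {
  cat("Censored-normal group-based trajectory model\n")
  cat("  ", x$ngroups, "groups,", x$n_subjects, "patients,",
      x$n_obs, "assessments\n")
  cat("  log-likelihood:", format(x$loglik, digits = 7),
      "  BIC:", format(x$bic, digits = 7), "\n")
  cat("  sigma:", round(x$sigma, digits), "\n")
  tab <- data.frame(share = round(x$shares, digits),
                    pi = round(x$group_probs, digits),
                    avepp = round(x$avepp, digits),
                    mean_day0 = round(x$coefficients[, 1], 1))
  rownames(tab) <- rownames(x$coefficients)
  print(tab)
  if (!x$converged) cat("  warning: EM did not converge\n")
  if (x$degenerate) cat("  warning: degenerate group (posterior mass < 1)\n")
  invisible(x)
}

#' @export
summary.gbtm <- function(object, ...) {
  structure(list(fit = object), class = "summary.gbtm")
}

#' @export
print.summary.gbtm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPolynomial coefficients (time in days /", f$time_scale, "):\n")
  print(round(f$coefficients, 4))
  cat("\nPer-day coefficients:\n")
  print(signif(coef(f, scale = "day"), 4))
  invisible(x)
}

#' Extract trajectory coefficients
#'
#' @param object A fitted `"gbtm"` model.
#' @param scale `"scaled"` returns the coefficients on the internal basis
#'   (polynomial in `day / time_scale`); `"day"` rescales them to a
#'   polynomial in raw days.
#' @param ... Unused.
#' @return K x (max order + 1) coefficient matrix.
#' @export
coef.gbtm <- function(object, scale = c("scaled", "day"), ...) {
  scale <- match.arg(scale)
  cf <- object$coefficients
  if (scale == "day") {
    powers <- seq_len(ncol(cf)) - 1
    cf <- sweep(cf, 2, object$time_scale^powers, `/`)
  }
  cf
}

#' @export
logLik.gbtm <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = object$n_subjects, class = "logLik")
}

#' Predict from a fitted trajectory model
#'
#' @param object A `"gbtm"` fit.
#' @param newdata Optional data frame with a `day` column (or numeric
#'   vector of days) at which to evaluate group mean curves. Defaults to
#'   the observed day range.
#' @param type `"mean"`: per-group fitted mean curves (data frame in long
#'   format); `"posterior"`: the posterior membership matrix;
#'   `"class"`: the modal group assignment per patient.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.gbtm <- function(object, newdata = NULL,
                         type = c("mean", "posterior", "class"), ...) {
  type <- match.arg(type)
  if (type == "posterior") {
    out <- object$posterior
    rownames(out) <- object$ids
    return(out)
  }
  if (type == "class") {
    return(stats::setNames(object$assignment, object$ids))
  }
  days <- if (is.null(newdata)) {
    seq(min(object$time), max(object$time), length.out = 50)
  } else if (is.data.frame(newdata)) {
    newdata$day
  } else {
    as.numeric(newdata)
  }
  t <- days / object$time_scale
  X <- outer(t, seq_len(ncol(object$coefficients)) - 1, `^`)
  mu <- X %*% t(object$coefficients)
  mu <- pmin(pmax(mu, object$bounds[1]), object$bounds[2])
  data.frame(group = rep(seq_len(object$ngroups), each = length(days)),
             day = rep(days, object$ngroups),
             mean = as.vector(mu))
}

#' @export
fitted.gbtm <- function(object, ...) {
  t <- object$time / object$time_scale
  X <- outer(t, seq_len(ncol(object$coefficients)) - 1, `^`)
  mu <- X %*% t(object$coefficients)
  mu[cbind(seq_along(object$y), object$assignment[object$idx])]
}

#' Residuals of a trajectory model
#'
#' Raw residuals of each assessment about the mean curve of the patient's
#' assigned group (censoring is ignored in the residual, so residuals at
#' the scale bounds are shrunk toward zero).
#'
#' @param object A `"gbtm"` fit.
#' @param ... Unused.
#' @return Numeric vector, one residual per assessment.
#' @export
residuals.gbtm <- function(object, ...) {
  object$y - fitted(object)
}

#' Plot fitted trajectory curves
#'
#' Draws the fitted group mean curves over the observed day range, with
#' the observed per-patient trajectories (coloured by assigned group) in
#' the background.
#'
#' @param x A `"gbtm"` fit.
#' @param show_data Draw the observed spaghetti behind the curves.
#' @param ... Passed to [graphics::matplot()] for the mean curves.
#' @return Invisibly, the curve grid from `predict(x)`.
#' @export
plot.gbtm <- function(x, show_data = TRUE, ...) {
  grid <- predict(x, type = "mean")
  cols <- grDevices::hcl.colors(x$ngroups, "Dark 3")
  graphics::plot(NA, xlim = range(grid$day), ylim = x$bounds,
                 xlab = "Days since admission", ylab = "Total ICF score")
  if (show_data) {
    for (i in seq_len(x$n_subjects)) {
      sel <- x$idx == i
      graphics::lines(x$time[sel], x$y[sel],
                      col = grDevices::adjustcolor(cols[x$assignment[i]], 0.25))
    }
  }
  for (k in seq_len(x$ngroups)) {
    sel <- grid$group == k
    graphics::lines(grid$day[sel], grid$mean[sel], col = cols[k], lwd = 3, ...)
  }
  graphics::legend("topright",
                   legend = sprintf("group %d (%.1f%%)", seq_len(x$ngroups),
                                    100 * x$shares),
                   col = cols, lwd = 3, bty = "n")
  invisible(grid)
}

#' Simulate trajectories from a fitted model
#'
#' Draws new patients from the fitted mixture: group from the mixing
#' proportions, then censored-normal outcomes about the group curve on a
#' fortnightly day grid.
#'
#' @param object A `"gbtm"` fit.
#' @param nsim Number of patients to simulate.
#' @param seed Optional seed.
#' @param days Day grid for each simulated patient (default fortnightly
#'   over the observed range).
#' @param ... Unused.
#' @return Long-format data frame: `patient_id`, `day`, `total`, `group`.
#' @export
simulate.gbtm <- function(object, nsim = object$n_subjects, seed = NULL,
                          days = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(days)) days <- seq(min(object$time), max(object$time), by = 14)
  g <- sample.int(object$ngroups, nsim, replace = TRUE,
                  prob = object$group_probs)
  t <- days / object$time_scale
  X <- outer(t, seq_len(ncol(object$coefficients)) - 1, `^`)
  mu <- X %*% t(object$coefficients)
  out <- lapply(seq_len(nsim), function(i) {
    y <- mu[, g[i]] + stats::rnorm(length(days), 0, object$sigma)
    y <- pmin(pmax(y, object$bounds[1]), object$bounds[2])
    data.frame(patient_id = sprintf("S%04d", i), day = days, total = y,
               group = g[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export the fitted trajectory curves as a plain table
#'
#' @param object A `"gbtm"` fit.
#' @param days Day grid (default fortnightly over the observed range).
#' @return Data frame `group`, `day`, `mean` suitable for CSV export and
#'   re-plotting.
#' @export
trajectory_curves <- function(object, days = NULL) {
  stopifnot(inherits(object, "gbtm"))
  if (is.null(days)) days <- seq(min(object$time), max(object$time), by = 14)
  predict(object, newdata = days, type = "mean")
}
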