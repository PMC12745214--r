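univariate_result <- function(variable, test, statistic, df, p_value,
                              note = NA_character_) {
  structure(list(variable = variable, test = test, statistic = statistic,
                 df = df, p_value = p_value, note = note),
            class = "univariate_result")
}

#' @export
print.univariate_result <- function(x, ...) {
  cat(sprintf("%s: %s statistic = %.4g, df = %s, p = %.4g\n", x$variable,
              x$test, x$statistic, paste(x$df, collapse = ","), x$p_value))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Pearson chi-square test on an r x c contingency table
#'
#' Classic Pearson chi-square test of independence without continuity
#' correction, as used for the trajectory-group comparisons of categorical
#' covariates. Rows or columns with zero margin are dropped (with a
#' warning) before computation.
#'
#' @param table Matrix of nonnegative integer counts (rows = covariate
#'   levels, columns = trajectory groups).
#' @param variable Label for the result.
#' @return A `"univariate_result"`: statistic, df `(r-1)(c-1)`, p-value.
#' @examples
#' tab <- rbind(yes = c(0, 4, 12, 12), no = c(17, 30, 14, 6))
#' pearson_chi2(tab)  # 27.69 on 3 df
#' @export
pearson_chi2 <- function(table, variable = "variable") {
  table <- as.matrix(table)
  if (any(table < 0) || nrow(table) < 2 || ncol(table) < 2 ||
      sum(table) == 0) {
    stop("need a nonnegative r x c table with r, c >= 2 and a positive total")
  }
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin row(s)/column(s) before chi-square")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  univariate_result(variable, "pearson_chi2",
                    unname(res$statistic), unname(res$parameter),
                    res$p.value)
}

# log null probability of an r x c table given its margins
log_table_prob <- function(tab, rs = rowSums(tab), cs = colSums(tab)) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(tab) + 1) -
    sum(lgamma(tab + 1))
}

# Enumerate all nonnegative integer tables with the given margins,
# applying `fun` to each; depth-first over cells row by row.
enumerate_tables <- function(rs, cs, fun, budget = 2e6) {
  r <- length(rs); cc <- length(cs)
  tab <- matrix(0L, r, cc)
  count <- 0L
  rec <- function(i, j, rrem, crem) {
    if (i == r) {
      # last row forced by column remainders
      if (any(crem < 0)) return()
      tab[r, ] <<- crem
      count <<- count + 1L
      if (count > budget) {
        stop("enumeration budget exceeded; use mode = \"monte_carlo\"",
             call. = FALSE)
      }
      fun(tab)
      return()
    }
    if (j == cc) {
      # last cell of the row forced by the row remainder
      if (rrem > crem[cc]) return()
      tab[i, cc] <<- rrem
      crem[cc] <- crem[cc] - rrem
      rec(i + 1L, 1L, rs[i + 1L], crem)
      return()
    }
    for (v in 0:min(rrem, crem[j])) {
      tab[i, j] <<- v
      crem2 <- crem
      crem2[j] <- crem2[j] - v
      rec(i, j + 1L, rrem - v, crem2)
    }
  }
  rec(1L, 1L, rs[1L], cs)
  invisible(count)
}

#' Fisher-type exact test for an r x c contingency table
#'
#' Exact conditional test of independence: given the observed margins, the
#' two-sided p-value is the total null (multivariate hypergeometric)
#' probability of all tables no more probable than the observed one. Used
#' for the sparse covariate-by-trajectory-group tables where expected
#' counts fall below 5. `mode = "enumerate"` enumerates every
#' margin-consistent table (budget-limited); `mode = "monte_carlo"` draws
#' tables from the conditional null with Patefield's algorithm
#' ([stats::r2dtable()]) and reports the estimated p with its standard
#' error.
#'
#' @param table Matrix of nonnegative integer counts.
#' @param mode `"enumerate"` or `"monte_carlo"`.
#' @param n_draws Monte-Carlo sample size.
#' @param seed Seed for Monte-Carlo mode.
#' @param variable Label for the result.
#' @return A `"univariate_result"` with `test = "fisher_exact"`; in
#'   Monte-Carlo mode the result carries an `se` element.
#' @examples
#' fisher_exact_rxc(rbind(c(1, 9), c(11, 3)))
#' @export
fisher_exact_rxc <- function(table, mode = c("enumerate", "monte_carlo"),
                             n_draws = 1e4, seed = 1L,
                             variable = "variable") {
  mode <- match.arg(mode)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("need nonnegative integer counts")
  }
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  table <- table[keep_r, keep_c, drop = FALSE]
  rs <- rowSums(table); cs <- colSums(table)
  lp_obs <- log_table_prob(table, rs, cs)
  tol <- 1e-7
  if (mode == "enumerate") {
    p <- 0
    enumerate_tables(rs, cs, function(tab) {
      lp <- log_table_prob(tab, rs, cs)
      if (lp <= lp_obs + tol) p <<- p + exp(lp)
    })
    res <- univariate_result(variable, "fisher_exact", NA_real_, NA_integer_,
                             min(p, 1))
  } else {
    set.seed(seed)
    draws <- stats::r2dtable(n_draws, rs, cs)
    hits <- vapply(draws, function(tab) {
      log_table_prob(tab, rs, cs) <= lp_obs + tol
    }, logical(1))
    p <- mean(hits)
    res <- univariate_result(variable, "fisher_exact", NA_real_, NA_integer_,
                             p, note = sprintf("monte_carlo, %d draws",
                                               as.integer(n_draws)))
    res$se <- sqrt(p * (1 - p) / n_draws)
  }
  res
}

#' One-way ANOVA F test across trajectory groups
#'
#' @param values Numeric outcome (e.g. age).
#' @param group Group label per observation.
#' @param variable Label for the result.
#' @return A `"univariate_result"` with the F statistic, df
#'   `(k - 1, N - k)` and p-value. When the within-group mean square is
#'   zero, F is 0 if the between-group mean square is also zero and the
#'   result is flagged degenerate otherwise.
#' @export
anova_f <- function(values, group, variable = "variable") {
  group <- factor(group)
  k <- nlevels(group)
  n <- length(values)
  stopifnot(k >= 2, n > k)
  fit <- stats::lm(values ~ group)
  # suppress the "essentially perfect fit" warning; degeneracy is handled
  an <- suppressWarnings(stats::anova(fit))
  msw <- an$`Mean Sq`[2]
  msb <- an$`Mean Sq`[1]
  if (msw <= 1e-10 * max(msb, 1)) {
    if (msb <= 1e-10) {
      return(univariate_result(variable, "anova_f", 0, an$Df, 1))
    }
    return(univariate_result(variable, "anova_f", Inf, an$Df, 0,
                             note = "degenerate: zero within-group variance"))
  }
  univariate_result(variable, "anova_f", an$`F value`[1], an$Df,
                    an$`Pr(>F)`[1])
}

#' Kruskal-Wallis rank test across trajectory groups
#'
#' Midrank-tie-corrected Kruskal-Wallis H with a chi-square reference on
#' `k - 1` df, for skewed continuous covariates such as disease course.
#'
#' @inheritParams anova_f
#' @return A `"univariate_result"`.
#' @export
kruskal_wallis <- function(values, group, variable = "variable") {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2)
  if (length(unique(values)) == 1L) {
    return(univariate_result(variable, "kruskal_wallis", 0,
                             nlevels(group) - 1L, 1))
  }
  res <- stats::kruskal.test(values, group)
  univariate_result(variable, "kruskal_wallis", unname(res$statistic),
                    unname(res$parameter), res$p.value)
}

#' Univariate comparison of covariates across trajectory groups
#'
#' Applies the reported testing rule across a covariate table: categorical
#' variables get a Pearson chi-square unless any expected cell count falls
#' below `exact_threshold`, in which case a Fisher-type exact test is used;
#' continuous variables get a one-way ANOVA F (`normal`) or a
#' Kruskal-Wallis H (`nonnormal`). All p-values are two-sided.
#'
#' @param covariates Data frame of per-patient covariates.
#' @param group Trajectory-group label per patient.
#' @param categorical,normal,nonnormal Character vectors naming the
#'   covariate columns of each kind; defaults to all non-id columns as
#'   categorical unless listed in `normal`/`nonnormal`.
#' @param exact_threshold Expected-count threshold that triggers the exact
#'   test (default 5; set to 0 to force Pearson everywhere).
#' @param mc_fallback_draws Monte-Carlo draws used if enumeration exceeds
#'   its budget.
#' @return Data frame (one row per variable): `variable`, `test`,
#'   `statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(covariates, group,
                           categorical = NULL,
                           normal = intersect("age", names(covariates)),
                           nonnormal = intersect("disease_course",
                                                 names(covariates)),
                           exact_threshold = 5,
                           mc_fallback_draws = 1e5) {
  if (is.null(categorical)) {
    categorical <- setdiff(names(covariates),
                           c("patient_id", "group", normal, nonnormal))
  }
  rows <- list()
  for (v in c(normal, nonnormal, categorical)) {
    res <- if (v %in% normal) {
      anova_f(covariates[[v]], group, v)
    } else if (v %in% nonnormal) {
      kruskal_wallis(covariates[[v]], group, v)
    } else {
      tab <- table(covariates[[v]], group)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < exact_threshold)) {
        tryCatch(fisher_exact_rxc(tab, "enumerate", variable = v),
                 error = function(e) {
                   fisher_exact_rxc(tab, "monte_carlo",
                                    n_draws = mc_fallback_draws,
                                    variable = v)
                 })
      } else {
        pearson_chi2(tab, v)
      }
    }
    rows[[v]] <- data.frame(variable = res$variable, test = res$test,
                            statistic = res$statistic,
                            df = if (length(res$df)) res$df[1] else NA,
                            p_value = res$p_value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Odds ratio with Wald confidence interval
#'
#' @param beta Log-odds coefficient.
#' @param se Standard error (> 0).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(or, lower, upper)`.
#' @examples
#' or_ci(3.180, 1.477)  # OR 24.05 (1.33-435.03)
#' @export
or_ci <- function(beta, se, level = 0.95) {
  stopifnot(se > 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(beta), lower = exp(beta - z * se), upper = exp(beta + z * se))
}
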