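#' Censored-normal log-density
#'
#' Log-density of the censored normal (Tobit-type) outcome distribution
#' used by the trajectory model: a normal density in the interior of the
#' score scale, with probability mass at the scale floor and ceiling.
#' For `y` strictly inside `bounds` this is the normal log-density; at the
#' lower bound it is `log P(Y* <= s_min)` and at the upper bound
#' `log P(Y* >= s_max)` for the latent normal Y*.
#'
#' @param y Observed score(s), each within `bounds`.
#' @param mu Latent mean(s).
#' @param sigma Latent SD (> 0).
#' @param bounds Length-2 censoring limits `c(s_min, s_max)`.
#' @return Log-density (log-mass at the bounds), vectorised over `y`/`mu`.
#' @examples
#' cnorm_logdensity(0, 0, 1, c(-5, 5)) # log dnorm(0) = -0.9189
#' cnorm_logdensity(200, 190, 10, c(0, 200)) # log(1 - pnorm(1))
#' @export
cnorm_logdensity <- function(y, mu, sigma, bounds) {
  if (sigma <= 0) stop("sigma must be positive")
  if (any(y < bounds[1] | y > bounds[2])) {
    stop("y outside censoring bounds [", bounds[1], ", ", bounds[2], "]")
  }
  z <- (y - mu) / sigma
  out <- stats::dnorm(z, log = TRUE) - log(sigma)
  lo <- y == bounds[1]
  hi <- y == bounds[2]
  if (any(lo)) {
    out[lo] <- stats::pnorm((bounds[1] - mu[lo]) / sigma, log.p = TRUE)
  }
  if (any(hi)) {
    out[hi] <- stats::pnorm((bounds[2] - mu[hi]) / sigma, log.p = TRUE,
                            lower.tail = FALSE)
  }
  out
}

# Derivatives of the censored-normal log-density wrt mu and log(sigma),
# used by the weighted M-step. Inverse Mills ratios are computed on the
# log scale for stability far in the tails.
cnorm_logdensity_grad <- function(y, mu, sigma, bounds) {
  z <- (y - mu) / sigma
  dmu <- z / sigma
  dls <- z^2 - 1
  lo <- y == bounds[1]
  hi <- y == bounds[2]
  if (any(lo)) {
    zl <- (bounds[1] - mu[lo]) / sigma
    r <- exp(stats::dnorm(zl, log = TRUE) - stats::pnorm(zl, log.p = TRUE))
    dmu[lo] <- -r / sigma
    dls[lo] <- -r * zl
  }
  if (any(hi)) {
    zh <- (bounds[2] - mu[hi]) / sigma
    r <- exp(stats::dnorm(zh, log = TRUE) -
               stats::pnorm(zh, log.p = TRUE, lower.tail = FALSE))
    dmu[hi] <- r / sigma
    dls[hi] <- r * zh
  }
  list(dmu = dmu, dlogsigma = dls)
}

#' Mixture log-likelihood of a trajectory model
#'
#' Log-likelihood of a K-group censored-normal trajectory mixture:
#' patients are conditionally independent given group, and observations
#' within a patient are independent given the group's polynomial mean
#' curve. `sum_i log sum_k p_k prod_t f_cnorm(y_it | x_it' beta_k, sigma)`.
#'
#' @param y Numeric outcome vector (one entry per assessment).
#' @param time Assessment times (same length as `y`), in days.
#' @param id Patient identifier per assessment.
#' @param group_probs Mixing proportions (length K, sums to 1).
#' @param coefs List of K polynomial coefficient vectors (intercept first),
#'   evaluated in `time / time_scale`.
#' @param sigma Residual SD.
#' @param bounds Censoring limits.
#' @param time_scale Divisor applied to `time` before polynomial
#'   evaluation.
#' @return The log-likelihood (scalar).
#' @export
cnorm_mixture_loglik <- function(y, time, id, group_probs, coefs, sigma,
                                 bounds = c(0, 200), time_scale = 100) {
  if (!all(is.finite(unlist(coefs))) || !is.finite(sigma)) {
    stop("non-finite model parameter")
  }
  if (abs(sum(group_probs) - 1) > 1e-8) stop("group_probs must sum to 1")
  idx <- match(id, unique(id))
  lpp <- patient_group_loglik(y, time, idx, coefs, sigma, bounds, time_scale)
  lw <- sweep(lpp, 2, log(group_probs), `+`)
  sum(logrowsumexp(lw))
}

# n_patients x K matrix of per-patient conditional log-likelihoods.
patient_group_loglik <- function(y, time, idx, coefs, sigma, bounds,
                                 time_scale) {
  K <- length(coefs)
  t <- time / time_scale
  lpp <- matrix(0, max(idx), K)
  for (k in seq_len(K)) {
    mu <- poly_eval(coefs[[k]], t)
    lpp[, k] <- rowsum(cnorm_logdensity(y, mu, sigma, bounds), idx)
  }
  lpp
}

poly_eval <- function(coefs, t) {
  mu <- rep(coefs[1], length(t))
  tp <- t
  for (j in seq_along(coefs)[-1]) {
    mu <- mu + coefs[j] * tp
    tp <- tp * t
  }
  mu
}

logrowsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Trajectory-model BIC
#'
#' Bayesian information criterion in the sign convention used for
#' trajectory-model reporting: `loglik - 0.5 * n_params * log(n_subjects)`.
#' Values are negative and a value closer to 0 indicates better fit.
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_subjects Number of subjects (not observations).
#' @return The BIC (scalar).
#' @examples
#' gbtm_bic(-100, 5, 95) # -100 - 2.5 * log(95)
#' @export
gbtm_bic <- function(loglik, n_params, n_subjects) {
  stopifnot(n_subjects >= 1, n_params >= 0)
  loglik - 0.5 * n_params * log(n_subjects)
}

#' Average posterior probability of assignment (Avepp)
#'
#' For each trajectory group, the mean posterior membership probability of
#' the patients assigned to that group. Values above 0.7 are conventionally
#' required for an acceptable grouping.
#'
#' @param posterior n x K matrix of posterior group probabilities (rows sum
#'   to 1).
#' @param assignment Optional assigned group per patient; defaults to the
#'   row-wise argmax with ties broken toward the lower group index.
#' @return Numeric vector of length K; `NA` for groups with no members.
#' @export
avepp <- function(posterior, assignment = NULL) {
  if (is.null(assignment)) assignment <- max.col(posterior, "first")
  K <- ncol(posterior)
  vapply(seq_len(K), function(k) {
    members <- assignment == k
    if (!any(members)) return(NA_real_)
    mean(posterior[members, k])
  }, numeric(1))
}

# ---- fitting ------------------------------------------------------------

parse_gbtm_formula <- function(formula, data) {
  if (length(formula) != 3L) stop("formula must look like y ~ time | id")
  rhs <- formula[[3]]
  if (!(is.call(rhs) && identical(rhs[[1]], as.name("|")))) {
    stop("formula must look like y ~ time | id (grouping after '|')")
  }
  env <- environment(formula)
  y <- eval(formula[[2]], data, env)
  time <- eval(rhs[[2]], data, env)
  id <- eval(rhs[[3]], data, env)
  if (length(y) != length(time) || length(y) != length(id)) {
    stop("outcome, time and id lengths differ")
  }
  keep <- !(is.na(y) | is.na(time) | is.na(id))
  list(y = as.numeric(y[keep]), time = as.numeric(time[keep]),
       id = as.character(id[keep]))
}

#' Fit a censored-normal group-based trajectory model
#'
#' Fits a K-group finite mixture of polynomial trajectories to a
#' longitudinal outcome by expectation-maximisation, with a censored-normal
#' (Tobit-type) outcome distribution: the outcome is normal about the
#' group's polynomial mean curve, censored at the ends of the measurement
#' scale. This is the model used to identify latent recovery trajectories
#' of the total ICF disability score (scale 0--200) during inpatient
#' rehabilitation.
#'
#' The E-step computes posterior group-membership probabilities; the
#' M-step updates the mixing proportions in closed form and the curve
#' coefficients and residual SD by posterior-weighted censored-normal
#' regression (closed-form weighted least squares when no observation sits
#' at a bound, quasi-Newton maximisation otherwise, so the observed-data
#' log-likelihood is non-decreasing across iterations). Several seeded
#' starts are run and the best local optimum kept. Groups are relabelled in
#' increasing order of fitted mean at time 0, so group 1 is always the
#' mildest trajectory.
#'
#' @param formula A formula `outcome ~ time | id`, e.g.
#'   `total ~ day | patient_id`.
#' @param data Data frame holding the three variables, one row per
#'   assessment.
#' @param ngroups Number of latent trajectory groups K.
#' @param orders Polynomial order per group (0--3); a scalar is recycled.
#' @param bounds Censoring limits of the measurement scale; defaults to the
#'   ICF total-score scale `c(0, 200)`.
#' @param time_scale Time divisor applied before polynomial evaluation
#'   (default 100, i.e. curves are polynomials in days/100) to condition
#'   the optimisation.
#' @param n_starts Number of EM starts (1 deterministic quantile start plus
#'   `n_starts - 1` seeded perturbations).
#' @param seed Seed for the randomised starts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @return An object of class `"gbtm"`; see Details. Supports `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate` and `logLik` methods.
#' @details The returned object contains `group_probs` (mixing
#'   proportions), `coefficients` (K x (max order + 1) matrix on the
#'   scaled-time basis; `coef()` can return the per-day basis), `sigma`,
#'   `loglik`, `bic` (subject-count convention, see [gbtm_bic()]),
#'   `posterior`, `assignment`, `avepp`, `shares`, `loglik_trace` and
#'   convergence flags.
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(n_patients = 60))
#' fit <- gbtm(total ~ day | patient_id, cohort$assessments,
#'             ngroups = 2, n_starts = 1)
#' print(fit)
#' @export
gbtm <- function(formula, data, ngroups, orders = 2, bounds = c(0, 200),
                 time_scale = 100, n_starts = 3, seed = 1L, tol = 1e-8,
                 max_iter = 500L) {
  stopifnot(ngroups >= 1, bounds[1] < bounds[2], n_starts >= 1)
  orders <- rep_len(as.integer(orders), ngroups)
  if (any(orders < 0 | orders > 3)) stop("polynomial orders must be in 0..3")
  d <- parse_gbtm_formula(formula, data)
  uid <- unique(d$id)
  n <- length(uid)
  if (n < ngroups) stop("need at least as many patients as groups")
  idx <- match(d$id, uid)

  # per-patient mean outcome drives the deterministic quantile start
  pmean <- as.numeric(rowsum(d$y, idx) / tabulate(idx))

  set.seed(seed)
  start_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    z <- quantile_start(pmean, ngroups)
    if (s > 1) {
      set.seed(start_seeds[s])
      flip <- sample.int(n, max(1L, round(0.2 * n)))
      z[flip] <- sample.int(ngroups, length(flip), replace = TRUE)
    }
    fit <- em_cnorm(d$y, d$time, idx, z, ngroups, orders, bounds,
                    time_scale, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # canonical labels: increasing fitted mean at time 0
  ord <- order(vapply(seq_len(ngroups),
                      function(k) best$coefs[[k]][1], numeric(1)))
  best$coefs <- best$coefs[ord]
  best$p <- best$p[ord]
  best$post <- best$post[, ord, drop = FALSE]

  assignment <- max.col(best$post, "first")
  shares <- tabulate(assignment, nbins = ngroups) / n
  coefmat <- matrix(0, ngroups, max(orders) + 1L,
                    dimnames = list(paste0("group", seq_len(ngroups)),
                                    paste0("t^", 0:max(orders))))
  for (k in seq_len(ngroups)) {
    coefmat[k, seq_along(best$coefs[[k]])] <- best$coefs[[k]]
  }
  n_params <- sum(orders + 1L) + 1L + (ngroups - 1L)

  out <- list(call = match.call(), formula = formula, ngroups = ngroups,
              orders = orders, bounds = bounds, time_scale = time_scale,
              group_probs = best$p, coefficients = coefmat,
              sigma = best$sigma, loglik = best$loglik,
              n_params = n_params, n_subjects = n, n_obs = length(d$y),
              bic = gbtm_bic(best$loglik, n_params, n),
              bic_obs = gbtm_bic(best$loglik, n_params, length(d$y)),
              posterior = best$post, assignment = assignment,
              avepp = avepp(best$post, assignment), shares = shares,
              loglik_trace = best$trace, converged = best$converged,
              degenerate = any(colSums(best$post) < 1),
              ids = uid, y = d$y, time = d$time, idx = idx)
  class(out) <- "gbtm"
  out
}

quantile_start <- function(pmean, K) {
  if (K == 1L) return(rep(1L, length(pmean)))
  br <- unique(stats::quantile(pmean, probs = seq(0, 1, length.out = K + 1)))
  if (length(br) == K + 1) {
    z <- as.integer(cut(pmean, br, include.lowest = TRUE))
  } else {
    # collapsed quantile bins (heavy ties): split by rank instead
    z <- as.integer(cut(rank(pmean, ties.method = "first"), K,
                        labels = FALSE))
  }
  z[is.na(z)] <- 1L
  z
}

em_cnorm <- function(y, time, idx, z0, K, orders, bounds, time_scale,
                     tol, max_iter) {
  n <- max(idx)
  t <- time / time_scale
  Xfull <- outer(t, 0:max(orders), `^`)
  Xk <- lapply(seq_len(K), function(k) Xfull[, 1:(orders[k] + 1L),
                                             drop = FALSE])
  censored <- y == bounds[1] | y == bounds[2]

  # start from one-hot posteriors of the initial assignment
  post <- matrix(0, n, K)
  post[cbind(seq_len(n), z0)] <- 1
  p <- pmax(colMeans(post), 1e-6); p <- p / sum(p)
  ms <- mstep(y, Xk, idx, post, NULL, bounds, censored)
  coefs <- ms$coefs; sigma <- ms$sigma

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lpp <- patient_group_loglik(y, time, idx, coefs, sigma, bounds,
                                time_scale)
    lw <- sweep(lpp, 2, log(p), `+`)
    lse <- logrowsumexp(lw)
    ll <- sum(lse)
    trace <- c(trace, ll)
    post <- exp(lw - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    p <- pmax(colMeans(post), 1e-10); p <- p / sum(p)
    ms <- mstep(y, Xk, idx, post, list(coefs = coefs, sigma = sigma),
                bounds, censored)
    coefs <- ms$coefs; sigma <- ms$sigma
  }
  list(p = p, coefs = coefs, sigma = sigma, loglik = ll, post = post,
       trace = trace, converged = converged)
}

# Posterior-weighted M-step for (beta_1..K, shared sigma). Closed-form
# weighted least squares when the sample has no censored observation;
# otherwise warm-started BFGS on the weighted Tobit objective (a
# generalised EM step: the objective never decreases from the warm start).
mstep <- function(y, Xk, idx, post, warm, bounds, censored) {
  K <- length(Xk)
  W <- post[idx, , drop = FALSE]
  if (!any(censored)) {
    coefs <- vector("list", K)
    rss <- 0
    for (k in seq_len(K)) {
      w <- W[, k]
      fit <- stats::lm.wfit(Xk[[k]], y, pmax(w, 1e-12))
      coefs[[k]] <- unname(fit$coefficients)
      rss <- rss + sum(w * fit$residuals^2)
    }
    sigma <- sqrt(rss / length(y))
    return(list(coefs = coefs, sigma = sigma))
  }

  pk <- lapply(Xk, ncol)
  split_theta <- function(theta) {
    coefs <- vector("list", K)
    pos <- 1L
    for (k in seq_len(K)) {
      coefs[[k]] <- theta[pos:(pos + pk[[k]] - 1L)]
      pos <- pos + pk[[k]]
    }
    list(coefs = coefs, sigma = exp(theta[pos]))
  }
  negQ <- function(theta) {
    th <- split_theta(theta)
    if (th$sigma < 1e-4) return(1e12)
    val <- 0
    for (k in seq_len(K)) {
      mu <- drop(Xk[[k]] %*% th$coefs[[k]])
      val <- val + sum(W[, k] * cnorm_logdensity(y, mu, th$sigma, bounds))
    }
    -val
  }
  negQ_grad <- function(theta) {
    th <- split_theta(theta)
    g <- numeric(length(theta))
    pos <- 1L
    gls <- 0
    for (k in seq_len(K)) {
      mu <- drop(Xk[[k]] %*% th$coefs[[k]])
      d <- cnorm_logdensity_grad(y, mu, th$sigma, bounds)
      g[pos:(pos + pk[[k]] - 1L)] <- -drop(crossprod(Xk[[k]], W[, k] * d$dmu))
      gls <- gls + sum(W[, k] * d$dlogsigma)
      pos <- pos + pk[[k]]
    }
    g[pos] <- -gls
    g
  }

  if (is.null(warm)) {
    # bootstrap a warm start from uncensored weighted least squares
    coefs <- vector("list", K)
    rss <- 0
    for (k in seq_len(K)) {
      fit <- stats::lm.wfit(Xk[[k]], y, pmax(W[, k], 1e-12))
      coefs[[k]] <- unname(fit$coefficients)
      rss <- rss + sum(W[, k] * fit$residuals^2)
    }
    warm <- list(coefs = coefs, sigma = sqrt(rss / length(y)))
  }
  theta0 <- c(unlist(warm$coefs), log(max(warm$sigma, 1e-3)))
  opt <- stats::optim(theta0, negQ, negQ_grad, method = "BFGS",
                      control = list(maxit = 60, reltol = 1e-10))
  # never move to a worse point than the warm start
  if (opt$value > negQ(theta0)) opt$par <- theta0
  split_theta(opt$par)
}
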