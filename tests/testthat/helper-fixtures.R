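# In-code fixtures shared across test files.

codes <- icf_item_codes()

# Build a wide assessment row from a length-20 score vector.
assessment_row <- function(id, day, scores) {
  stopifnot(length(scores) == 20)
  out <- data.frame(patient_id = id, day = day, stringsAsFactors = FALSE)
  out[codes] <- as.list(as.integer(scores))
  out
}

# Three-patient toy cohort with hand-chosen admission/endpoint scores:
# item 1 (d450) exercises improvement, item 2 (d455) a tie, the last item
# (b134) is all-zero at admission.
toy_cohort <- function() {
  adm <- rbind(
    assessment_row("A", 0, c(8, 5, rep(1, 17), 0)),
    assessment_row("B", 0, c(6, 4, rep(0, 17), 0)),
    assessment_row("C", 0, c(0, 3, rep(2, 17), 0))
  )
  end <- rbind(
    assessment_row("A", 28, c(4, 5, rep(1, 17), 0)),
    assessment_row("B", 28, c(6, 4, rep(0, 17), 0)),
    assessment_row("C", 28, c(0, 3, rep(1, 17), 0))
  )
  list(admission = adm, endpoint = end)
}

# Longitudinal totals-only frame for trajectory fits: K groups with
# linear-in-time means, normal noise, no censoring by construction.
toy_trajectories <- function(n_per_group = 15, means0 = c(30, 90),
                             slopes = c(-10, -20), sigma = 5,
                             days = seq(0, 56, by = 14), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in seq_along(means0)) {
    for (i in seq_len(n_per_group)) {
      id <- sprintf("g%d_%02d", g, i)
      y <- means0[g] + slopes[g] * days / 100 + rnorm(length(days), 0, sigma)
      rows[[id]] <- data.frame(patient_id = id, day = days, total = y,
                               group = g, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Draw from a proportional-odds model: P(Y <= j) = plogis(zeta_j - eta),
# eta = X beta, so positive beta pushes toward higher (more severe) levels.
simulate_prop_odds <- function(n, beta = c(x1 = 0.8, x2 = -0.5),
                               zeta = c(-1, 0.5, 2), seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.5)
  eta <- beta[1] * x1 + beta[2] * x2
  cum <- vapply(zeta, function(z) plogis(z - eta), numeric(n))
  u <- runif(n)
  y <- rowSums(u > cum) + 1L
  data.frame(y = y, x1 = x1, x2 = x2)
}

# Same model with four binary risk-factor predictors, mirroring the
# mostly-binary covariates (dysphagia, device use, surgery, ...) of the
# group-membership regression.
simulate_prop_odds_binary <- function(n, beta = c(0.8, -0.5, 0.6, -0.4),
                                      prev = c(0.5, 0.3, 0.4, 0.25),
                                      zeta = c(-1, 0.5, 2), seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * 4, 1, rep(prev, each = n)), n, 4)
  eta <- drop(X %*% beta)
  cum <- vapply(zeta, function(z) plogis(z - eta), numeric(n))
  y <- rowSums(runif(n) > cum) + 1L
  data.frame(y = y, x1 = X[, 1], x2 = X[, 2], x3 = X[, 3], x4 = X[, 4])
}
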