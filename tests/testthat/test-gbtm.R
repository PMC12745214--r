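test_that("censored-normal log-density matches its closed forms", {
  b <- c(0, 200)
  expect_equal(cnorm_logdensity(50, 50, 1, b), log(1 / sqrt(2 * pi)))
  expect_equal(cnorm_logdensity(0, 0, 7, b), log(0.5))
  expect_equal(cnorm_logdensity(200, 190, 10, b), log(1 - pnorm(1)))
  expect_equal(cnorm_logdensity(60, 50, 5, b), dnorm(60, 50, 5, log = TRUE))
  expect_error(cnorm_logdensity(-1, 0, 1, b), "bounds")
  expect_error(cnorm_logdensity(10, 10, 0, b), "sigma")
})

test_that("censored-normal mass integrates to one", {
  b <- c(0, 200)
  for (mu in c(-10, 5, 100, 195)) {
    interior <- integrate(function(y) dnorm(y, mu, 15), b[1], b[2])$value
    mass <- interior + exp(cnorm_logdensity(0, mu, 15, b)) +
      exp(cnorm_logdensity(200, mu, 15, b))
    expect_equal(mass, 1, tolerance = 1e-7)
  }
})

test_that("mixture log-likelihood reduces, doubles and enumerates correctly", {
  d <- toy_trajectories(n_per_group = 5, means0 = 60, slopes = -10,
                        sigma = 4, seed = 2)
  # K = 1, no censoring: plain sum of normal log-densities about the line
  cf <- list(c(60, -10))
  ll <- cnorm_mixture_loglik(d$total, d$day, d$patient_id, 1, cf, 4)
  direct <- sum(dnorm(d$total, 60 - 10 * d$day / 100, 4, log = TRUE))
  expect_equal(ll, direct, tolerance = 1e-10)

  # duplicating every patient doubles the log-likelihood exactly
  d2 <- rbind(d, transform(d, patient_id = paste0(patient_id, "_dup")))
  ll2 <- cnorm_mixture_loglik(d2$total, d2$day, d2$patient_id, 1, cf, 4)
  expect_equal(ll2, 2 * ll, tolerance = 1e-10)

  # 2 patients x 2 groups x 1 time point: hand-computed mixture sum
  y <- c(30, 80)
  p <- c(0.3, 0.7)
  cfs <- list(c(35), c(75))
  ll_hand <- sum(log(p[1] * dnorm(y, 35, 10) + p[2] * dnorm(y, 75, 10)))
  expect_equal(
    cnorm_mixture_loglik(y, c(0, 0), c("a", "b"), p, cfs, 10),
    ll_hand, tolerance = 1e-12)
})

test_that("trajectory BIC uses the subject-count penalty convention", {
  expect_equal(gbtm_bic(0, 5, 95), -0.5 * 5 * log(95))
  expect_equal(gbtm_bic(-100, 5, 95), -100 - 2.5 * log(95))
  expect_equal(gbtm_bic(-42, 0, 10), -42)
})

test_that("avepp averages assigned posteriors with lower-index ties", {
  expect_equal(avepp(diag(3)[c(1, 2, 3, 1), ]), c(1, 1, 1))
  tie <- matrix(0.5, 4, 2)
  expect_equal(avepp(tie), c(0.5, NA))          # all tie-break to group 1
  expect_equal(avepp(tie, assignment = c(1, 1, 2, 2)), c(0.5, 0.5))
  post <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.3, 0.7))
  expect_equal(avepp(post), c((0.9 + 0.8) / 2, 0.7))
})

test_that("a noise-free single-group quadratic is recovered exactly", {
  days <- seq(0, 84, by = 14)
  truth <- c(80, -30, 6)
  d <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(patient_id = i, day = days,
               total = truth[1] + truth[2] * days / 100 +
                 truth[3] * (days / 100)^2)
  }))
  fit <- gbtm(total ~ day | patient_id, d, ngroups = 1, orders = 2,
              n_starts = 1)
  expect_equal(unname(fit$coefficients[1, ]), truth, tolerance = 1e-6)
  expect_lt(fit$sigma, 1e-4)
})

test_that("K=1 without censoring matches pooled least squares", {
  d <- toy_trajectories(n_per_group = 20, means0 = 70, slopes = -25,
                        sigma = 6, seed = 3)
  fit <- gbtm(total ~ day | patient_id, d, ngroups = 1, orders = 2,
              bounds = c(-1e9, 1e9), n_starts = 1)
  ols <- lm(total ~ poly(day / 100, 2, raw = TRUE), data = d)
  expect_equal(unname(fit$coefficients[1, ]), unname(coef(ols)),
               tolerance = 1e-6)
  expect_equal(fit$sigma^2, mean(residuals(ols)^2), tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone and the fit is well-formed", {
  d <- toy_trajectories(seed = 4)
  fit <- gbtm(total ~ day | patient_id, d, ngroups = 2, n_starts = 2,
              seed = 5)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_equal(sum(fit$group_probs), 1, tolerance = 1e-8)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, fit$n_subjects),
               tolerance = 1e-8)
  expect_equal(sum(fit$shares), 1)
  expect_true(all(fit$avepp >= 1 / 2 - 1e-8, na.rm = TRUE))
  # the two planted groups are recovered
  truth <- tapply(d$group, d$patient_id, `[`, 1)[fit$ids]
  expect_gt(mean(fit$assignment == truth), 0.95)
})

test_that("permuting patient order leaves the fit invariant", {
  d <- toy_trajectories(seed = 6)
  fit1 <- gbtm(total ~ day | patient_id, d, ngroups = 2, n_starts = 1)
  set.seed(8)
  perm <- d[sample(nrow(d)), ]
  fit2 <- gbtm(total ~ day | patient_id, perm, ngroups = 2, n_starts = 1)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit1$bic, fit2$bic, tolerance = 1e-6)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-4)
  expect_equal(fit1$group_probs, fit2$group_probs, tolerance = 1e-5)
})

test_that("groups are labelled mildest-first and methods are coherent", {
  d <- toy_trajectories(seed = 7)
  fit <- gbtm(total ~ day | patient_id, d, ngroups = 2, n_starts = 1)
  expect_true(fit$coefficients[1, 1] < fit$coefficients[2, 1])
  expect_equal(length(residuals(fit)), nrow(d))
  expect_equal(fitted(fit) + residuals(fit), d$total,
               tolerance = 1e-12, ignore_attr = TRUE)
  grid <- predict(fit, newdata = c(0, 14, 28), type = "mean")
  expect_equal(nrow(grid), 6)
  expect_equal(grid$mean[grid$group == 1 & grid$day == 0],
               unname(fit$coefficients[1, 1]), tolerance = 1e-8)
  cls <- predict(fit, type = "class")
  expect_equal(unname(cls), fit$assignment)
  cf_day <- coef(fit, scale = "day")
  expect_equal(cf_day[, 2], fit$coefficients[, 2] / 100)
  sim <- simulate(fit, nsim = 10, seed = 1)
  expect_true(all(sim$total >= fit$bounds[1] & sim$total <= fit$bounds[2]))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), fit$n_params)
})

test_that("model dump/load round-trips parameters as text", {
  d <- toy_trajectories(seed = 9)
  fit <- gbtm(total ~ day | patient_id, d, ngroups = 2, n_starts = 1)
  p <- tempfile(fileext = ".txt")
  write_gbtm(fit, p)
  back <- read_gbtm(p)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$sigma, fit$sigma)
  expect_equal(back$bic, fit$bic)
  expect_equal(back$avepp, unname(fit$avepp))
})

test_that("selection rule prefers BIC closest to zero among admissible", {
  d <- toy_trajectories(n_per_group = 20, seed = 10)
  sel <- select_gbtm(total ~ day | patient_id, d, K_range = 1:3,
                     n_starts = 1)
  expect_equal(sel$chosen_K, 2)
  expect_true(sel$admissible)
  adm <- sel$candidates[sel$candidates$admissible, ]
  expect_equal(min(abs(adm$bic)), abs(sel$chosen$bic))
  expect_error(select_gbtm(total ~ day | patient_id, d, K_range = integer(0)),
               "empty")
})

test_that("an inadmissible single candidate is returned flagged", {
  # two clear groups forced into 5: tiny shares violate the 5% rule
  d <- toy_trajectories(n_per_group = 8, seed = 11)
  sel <- select_gbtm(total ~ day | patient_id, d, K_range = 5,
                     n_starts = 1)
  expect_false(sel$admissible)
  expect_equal(sel$chosen_K, 5)
})
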