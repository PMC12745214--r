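test_that("default configuration encodes the published study conditions", {
  cfg <- default_cohort_config()
  expect_equal(sum(cfg$group_probs), 1)
  expect_equal(cfg$los_model$mean[4], 88.9)
  expect_equal(cfg$cost_model$daily_mean,
               c(484.73, 531.28, 546.12, 633.53))
  day0 <- vapply(cfg$curves, `[[`, numeric(1), 1)
  expect_true(day0[1] >= 20 && day0[1] <= 30)
  expect_equal(day0[2:4], c(61, 88, 116), tolerance = 0.1)
  # curves decline over the reported stay of each group
  for (g in 1:4) {
    los <- cfg$los_model$mean[g]
    expect_lt(icftraj:::eval_curve(cfg$curves[[g]], los, cfg$time_scale),
              day0[g])
  }
})

test_that("mismatched group count is a config error", {
  expect_error(cohort_config(10, c(0.5, 0.5), curves = list(c(60)),
                             sigma = 1,
                             los_model = list(mean = c(30, 30),
                                              sd = c(5, 5)),
                             cost_model = list(daily_mean = c(1, 1),
                                               cv = 0.1)),
               "config error")
})

test_that("noise-free single-group cohort sits exactly on the curve", {
  cfg <- cohort_config(n_patients = 8, group_probs = 1,
                       curves = list(c(60, 0, 0)), sigma = 0,
                       los_model = list(mean = 30, sd = 1e-9),
                       cost_model = list(daily_mean = 500, cv = 0.1))
  co <- simulate_cohort(cfg, seed = 5)
  expect_true(all(co$assessments$total == 60))
  expect_equal(sort(unique(co$assessments$day)), c(0, 14, 28))
  expect_true(all(table(co$assessments$patient_id) == 3))
})

test_that("a curve above the ceiling is censored to the scale maximum", {
  cfg <- cohort_config(n_patients = 10, group_probs = 1,
                       curves = list(c(250, 0, 0)), sigma = 5,
                       los_model = list(mean = 30, sd = 1e-9),
                       cost_model = list(daily_mean = 500, cv = 0.1))
  co <- simulate_cohort(cfg, seed = 6)
  adm <- co$assessments[co$assessments$day == 0, ]
  expect_true(all(adm$total == 200))
})

test_that("empirical group shares track the mixing probabilities", {
  co <- simulate_cohort(default_cohort_config(n_patients = 1000), seed = 9)
  shares <- tabulate(co$truth$group, 4) / 1000
  expect_true(all(abs(shares - c(0.1789, 0.3579, 0.2737, 0.1895)) < 0.03))
})

test_that("identical seeds give byte-identical cohorts", {
  cfg <- default_cohort_config(n_patients = 30)
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(a$assessments, b$assessments)
  expect_identical(a$covariates, b$covariates)
  pa <- write_cohort(a, file.path(tempdir(), "coh_a"))
  pb <- write_cohort(b, file.path(tempdir(), "coh_b"))
  expect_identical(unname(tools::md5sum(pa)), unname(tools::md5sum(pb)))
  c_ <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(a$assessments, c_$assessments))
})

test_that("raising the ceiling never decreases a generated total", {
  cfg_low <- default_cohort_config(n_patients = 50)
  cfg_low$bounds <- c(0, 100)
  cfg_high <- default_cohort_config(n_patients = 50)
  lo <- simulate_cohort(cfg_low, seed = 31)
  hi <- simulate_cohort(cfg_high, seed = 31)
  expect_true(all(hi$assessments$total >= lo$assessments$total))
})

test_that("item allocation preserves totals within per-item bounds", {
  w <- icftraj:::default_item_weights()
  set.seed(4)
  for (total in c(0L, 1L, 7L, sample(0:200, 30), 199L, 200L)) {
    x <- icftraj:::allocate_item_scores(total, w)
    expect_equal(sum(x), total)
    expect_true(all(x >= 0 & x <= 10))
  }
})

test_that("generated cohorts satisfy the structural invariants", {
  co <- simulate_cohort(default_cohort_config(n_patients = 60), seed = 77)
  expect_true(all(table(co$assessments$patient_id) >= 2))
  expect_true(all(co$assessments$total >= 0 & co$assessments$total <= 200))
  expect_true(all(co$truth$group %in% 1:4))
  expect_true(all(co$episodes$length_of_stay >= 14))
  expect_true(all(co$episodes$cost > 0))
  expect_equal(validate_cohort(co$assessments)$n_violations, 0)
  expect_true(all(c("age", "dysphagia", "cognitive_impairment",
                    "assistive_device", "education", "hemiplegic_side")
                  %in% names(co$covariates)))
})
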