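test_that("item catalogue partitions as the instrument defines", {
  items <- icf_items()
  expect_equal(nrow(items), 20)
  expect_setequal(items$code,
                  c("d450", "d455", "b455", "b525", "b620", "d530", "d230",
                    "d510", "d520", "d540", "d550", "b130", "b134", "b152",
                    "b280", "b114", "b144", "b210", "b230", "d710"))
  expect_equal(as.integer(table(items$functional_area)[
    c("self_care_activities", "cognition_perception", "emotion_spirit")]),
    c(11L, 5L, 4L))
  expect_setequal(items$code[items$rating_mode == "self_reported"],
                  c("b130", "b134", "b152", "b280"))
})

test_that("total score sums the 20 items and respects the scale", {
  expect_equal(total_score(setNames(rep(0, 20), codes)), 0)
  expect_equal(total_score(setNames(rep(10, 20), codes)), 200)
  s <- c(7, 8, 4, 2, 2, 6, 7, 7, 7, 7, 3, 2, 2, 1, 0, 2, 2, 1, 1, 1)
  expect_equal(total_score(setNames(s, codes)), 72)
  expect_error(total_score(setNames(rep(1, 19), codes[-3])), "b455")
  expect_error(total_score(setNames(c(11, rep(0, 19)), codes)), "0, 10")
})

test_that("item summary matches hand enumeration on a 3-patient cohort", {
  tc <- toy_cohort()
  s <- item_cohort_summary(tc$admission, tc$endpoint)
  d450 <- s[s$code == "d450", ]
  # admissions 8, 6, 0 -> 2 dysfunctional; endpoint 4 < 8 improves, 6 == 6
  expect_equal(d450$n_dysfunction, 2)
  expect_equal(d450$pct_dysfunction, 100 * 2 / 3)
  expect_equal(d450$n_improved, 1)
  expect_equal(d450$pct_improved, 50)
  expect_equal(d450$mean_admission, (8 + 6 + 0) / 3)
  expect_equal(d450$mean_discharge, (4 + 6 + 0) / 3)
  expect_equal(d450$improvement, 14 / 3 - 10 / 3)
  expect_equal(d450$improvement_rate, 100 * (14 / 3 - 10 / 3) / (14 / 3))
  # d455 is a pure tie for every patient: dysfunction but no improvement
  d455 <- s[s$code == "d455", ]
  expect_equal(d455$n_dysfunction, 3)
  expect_equal(d455$n_improved, 0)
  # b134 nobody dysfunctional at admission: degenerate zeros, not NaN
  b134 <- s[s$code == "b134", ]
  expect_equal(b134$n_dysfunction, 0)
  expect_equal(b134$pct_improved, 0)
  expect_equal(b134$improvement_rate, 0)
})

test_that("summary counts and percentages respect their bounds", {
  co <- simulate_cohort(default_cohort_config(n_patients = 40), seed = 11)
  ae <- admission_endpoint(co$assessments)
  s <- item_cohort_summary(ae$admission, ae$endpoint)
  expect_true(all(s$n_improved <= s$n_dysfunction))
  expect_true(all(s$n_dysfunction <= 40))
  expect_true(all(s$pct_dysfunction >= 0 & s$pct_dysfunction <= 100))
  expect_true(all(s$pct_improved >= 0 & s$pct_improved <= 100))
  # linearity: item-level mean improvements sum to the total improvement
  tot_adm <- mean(rowSums(ae$admission[, codes]))
  tot_end <- mean(rowSums(ae$endpoint[, codes]))
  expect_equal(sum(s$improvement), tot_adm - tot_end, tolerance = 1e-10)
})

test_that("unpaired patients and empty cohorts are rejected", {
  tc <- toy_cohort()
  expect_error(item_cohort_summary(tc$admission, tc$endpoint[-2, ]), "B")
  expect_error(item_cohort_summary(tc$admission[0, ], tc$endpoint[0, ]),
               "empty")
})

test_that("cohort validation flags the inclusion-rule violations", {
  tc <- toy_cohort()
  long <- rbind(tc$admission, tc$endpoint)
  expect_equal(validate_cohort(long)$n_violations, 0)

  one_visit <- rbind(tc$admission, tc$endpoint[tc$endpoint$patient_id != "C", ])
  v <- validate_cohort(one_visit)
  expect_equal(v$too_few_assessments, "C")

  bad <- long
  bad$d450[1] <- 11L
  v <- validate_cohort(bad)
  expect_equal(nrow(v$out_of_range), 1)
  expect_equal(v$out_of_range$code, "d450")

  dup <- rbind(long, tc$admission[1, ])
  expect_equal(nrow(validate_cohort(dup)$duplicated_days), 1)
})

test_that("assessment CSV round trip is lossless and header-checked", {
  co <- simulate_cohort(default_cohort_config(n_patients = 5), seed = 2)
  p <- tempfile(fileext = ".csv")
  write_assessments(co$assessments, p)
  back <- read_assessments(p)
  expect_equal(back$d450, co$assessments$d450)
  expect_equal(back$day, co$assessments$day)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,day,wrong", "P1,0,1"), bad)
  expect_error(read_assessments(bad), "header")
})
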