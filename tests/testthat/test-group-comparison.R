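test_that("pearson chi-square equals the explicit cell-loop oracle", {
  chi2_oracle <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    s <- 0
    for (i in seq_len(nrow(tab))) {
      for (j in seq_len(ncol(tab))) {
        s <- s + (tab[i, j] - E[i, j])^2 / E[i, j]
      }
    }
    s
  }
  set.seed(20)
  for (rep in 1:100) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 8) + 1, r, cc)
    res <- pearson_chi2(tab)
    expect_equal(res$statistic, chi2_oracle(tab), tolerance = 1e-10)
    expect_equal(res$df, (r - 1) * (cc - 1))
  }
})

test_that("identical row proportions give a zero statistic", {
  tab <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_equal(pearson_chi2(tab)$statistic, 0, tolerance = 1e-12)
})

test_that("zero-margin rows are dropped with a warning", {
  tab <- rbind(c(5, 7), c(0, 0), c(3, 9))
  expect_warning(res <- pearson_chi2(tab), "zero-margin")
  expect_equal(res$df, 1)
})

test_that("exact-test enumeration probabilities total one", {
  set.seed(21)
  for (rep in 1:10) {
    tab <- matrix(rpois(6, 4), 2, 3)
    tab[1, 1] <- tab[1, 1] + 1  # avoid an all-zero table
    rs <- rowSums(tab); cs <- colSums(tab)
    total <- 0
    icftraj:::enumerate_tables(rs, cs, function(t2) {
      total <<- total + exp(icftraj:::log_table_prob(t2, rs, cs))
    })
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("enumerated exact p matches the classical reference", {
  tab <- rbind(c(1, 9), c(11, 3))
  p <- fisher_exact_rxc(tab)$p_value
  expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  # r x c case against the network-algorithm reference
  tab2 <- rbind(c(1, 4, 9, 8), c(16, 30, 17, 10))
  expect_equal(fisher_exact_rxc(tab2)$p_value,
               fisher.test(tab2)$p.value, tolerance = 1e-7)
})

test_that("removing an empty category leaves the exact p unchanged", {
  tab <- rbind(c(2, 5), c(0, 0), c(7, 1))
  expect_equal(fisher_exact_rxc(tab)$p_value,
               fisher_exact_rxc(tab[-2, ])$p_value)
})

test_that("monte carlo exact p agrees with enumeration within 3 SE", {
  tab <- rbind(c(1, 4, 9, 8), c(16, 30, 17, 10))
  p_exact <- fisher_exact_rxc(tab)$p_value
  mc <- fisher_exact_rxc(tab, mode = "monte_carlo", n_draws = 1e5, seed = 2)
  expect_lt(abs(mc$p_value - p_exact), 3 * mc$se + 1e-12)
})

test_that("anova F matches textbook arithmetic and handles degeneracy", {
  # hand example: groups {1,3}, {4,6}, {8,10}; grand mean 5.333...
  vals <- c(1, 3, 4, 6, 8, 10)
  g <- rep(1:3, each = 2)
  ssb <- 2 * ((2 - 16 / 3)^2 + (5 - 16 / 3)^2 + (9 - 16 / 3)^2)
  ssw <- sum((vals - rep(c(2, 5, 9), each = 2))^2)
  f_hand <- (ssb / 2) / (ssw / 3)
  res <- anova_f(vals, g)
  expect_equal(res$statistic, f_hand, tolerance = 1e-10)
  expect_equal(res$df, c(2, 3))

  expect_equal(anova_f(c(1, 3, 2, 2, 0, 4), rep(1:3, each = 2))$statistic, 0)
  deg <- anova_f(c(0, 0, 1, 1), rep(1:2, each = 2))
  expect_true(is.infinite(deg$statistic))
  expect_match(deg$note, "degenerate")
})

test_that("kruskal-wallis matches hand ranking and the midrank formula", {
  vals <- c(1, 2, 3, 4, 5, 6)  # ranks are the values themselves
  g <- rep(1:3, each = 2)
  rbar <- c(1.5, 3.5, 5.5)
  h_hand <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
  expect_equal(kruskal_wallis(vals, g)$statistic, h_hand, tolerance = 1e-10)

  expect_equal(kruskal_wallis(rep(5, 6), rep(1:2, each = 3))$statistic, 0)

  # tie-heavy case against the direct midrank formula with tie correction
  vals2 <- c(1, 1, 2, 2, 2, 3, 3, 1, 2)
  g2 <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  r <- rank(vals2)
  n <- length(vals2)
  h_raw <- 12 / (n * (n + 1)) *
    sum(tapply(r, g2, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(vals2)
  h_corr <- h_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskal_wallis(vals2, g2)$statistic, h_corr,
               tolerance = 1e-10)
})

test_that("odds-ratio intervals follow the Wald construction", {
  expect_equal(unname(or_ci(0, 1)),
               c(1, exp(-qnorm(0.975)), exp(qnorm(0.975))))
  ci <- or_ci(3.180, 1.477)
  expect_equal(round(unname(ci["or"]), 2), 24.05)
  expect_true(ci["lower"] < ci["or"] && ci["or"] < ci["upper"])
  expect_error(or_ci(1, 0), "se")
})

test_that("the test-selection rule routes sparse tables to the exact test", {
  co <- simulate_cohort(default_cohort_config(n_patients = 95), seed = 14)
  res <- compare_groups(co$covariates, co$truth$group)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$test[res$variable == "age"], "anova_f")
  expect_equal(res$test[res$variable == "disease_course"], "kruskal_wallis")
  # sparse flags (e.g. shoulder pain ~5% prevalence) must go exact
  expect_equal(res$test[res$variable == "shoulder_pain"], "fisher_exact")
  expect_setequal(setdiff(res$variable, c("age", "disease_course")),
                  setdiff(names(co$covariates),
                          c("patient_id", "age", "disease_course")))
})
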