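test_that("two-sided Fisher matches exhaustive enumeration on random tables", {
  withr::with_seed(11, {
    for (i in 1:100) {
      N <- sample(4:60, 1)
      n1 <- sample(2:(N - 2), 1)
      a <- sample(0:n1, 1); cc <- sample(0:(N - n1), 1)
      p <- fisher_exact_two_sided(a, n1 - a, cc, N - n1 - cc)
      expect_equal(p, fisher_enum(a, n1 - a, cc, N - n1 - cc),
                   tolerance = 1e-10)
      expect_gt(p, 0); expect_lte(p, 1)
      # library cross-check
      expect_equal(p, stats::fisher.test(
        matrix(c(a, n1 - a, cc, N - n1 - cc), 2, byrow = TRUE))$p.value,
        tolerance = 1e-7)
    }
  })
})

test_that("Fisher p is invariant to simultaneous row and column swaps", {
  withr::with_seed(12, {
    for (i in 1:30) {
      x <- sample(0:12, 4, replace = TRUE)
      if (sum(x[1:2]) == 0 || sum(x[3:4]) == 0) next
      p1 <- fisher_exact_two_sided(x[1], x[2], x[3], x[4])
      p2 <- fisher_exact_two_sided(x[4], x[3], x[2], x[1])
      expect_equal(p1, p2, tolerance = 1e-12)
    }
  })
})

test_that("Fisher handles degenerate tables by convention", {
  expect_equal(suppressMessages(fisher_exact_two_sided(0, 20, 0, 17)), 1)
  expect_equal(fisher_exact_two_sided(20, 0, 17, 0) , 1)
})

test_that("Wilcoxon rank-sum switches between exact and approximate branches", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6), 0.1) # 2 / choose(6, 3)
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.9)
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- rnorm(10); y <- rnorm(10, 0.5)
      exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
      approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
      expect_lt(abs(exact - approx), 0.02) # branches agree closely
      expect_equal(wilcoxon_rank_sum(x, y), exact) # n = 20, tie-free
    }
  })
})

test_that("group summary table reproduces hand-checked medians and reuses tests", {
  dat <- tibble::tibble(
    arm = rep(c("standard", "individualized"), each = 4),
    died = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    deficit = c(10, 20, 30, 40, 2, 4, 6, 8)
  )
  tab <- summarize_groups(dat, binary_vars = "died", continuous_vars = "deficit")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$standard[tab$variable == "died"], "1 (25%)")
  expect_equal(tab$standard[tab$variable == "deficit"], "25.0 [17.5-32.5]")
  expect_equal(tab$individualized[tab$variable == "deficit"], "5.0 [3.5-6.5]")
  expect_equal(tab$p_value[tab$variable == "died"],
               fisher_exact_two_sided(1, 3, 1, 3))
  expect_equal(tab$p_value[tab$variable == "deficit"],
               wilcoxon_rank_sum(c(10, 20, 30, 40), c(2, 4, 6, 8)))
})

test_that("sample-size calculators reproduce the planning numbers", {
  expect_equal(sample_size_two_proportions(0.20, 0.14, attrition = 0.025), 1260L)
  expect_equal(sample_size_two_proportions(0.20, 0.14), 1229L)
  ss <- sample_size_two_means(8, 9)
  expect_equal(ss$per_group, 20L)
  expect_equal(ss$total, 40L)
  expect_error(sample_size_two_proportions(0.2, 0.2),
               class = "mapdeficit_contract_error")
  expect_error(sample_size_two_means(0, 9),
               class = "mapdeficit_contract_error")
})

test_that("sample sizes are monotone in power and effect size", {
  powers <- seq(0.5, 0.95, by = 0.05)
  n_by_power <- vapply(powers, function(p)
    sample_size_two_proportions(0.20, 0.14, power = p), integer(1))
  expect_true(all(diff(n_by_power) >= 0))
  p2s <- seq(0.05, 0.17, by = 0.01)
  n_by_eff <- vapply(p2s, function(p2)
    sample_size_two_proportions(0.20, p2), integer(1))
  expect_true(all(diff(n_by_eff) >= 0)) # shrinking |effect| inflates n
  m_by_power <- vapply(powers, function(p)
    sample_size_two_means(8, 9, power = p)$total, integer(1))
  expect_true(all(diff(m_by_power) >= 0))
  expect_gt(sample_size_two_means(8, 18)$per_group,
            3.9 * sample_size_two_means(8, 9)$per_group - 4) # ~quadruples
})

test_that("the mixed model recovers an injected treatment effect", {
  long <- simulate_lmm_data(n_patients = 100, treatment_effect = -10, seed = 88)
  fit <- fit_lmm(long, "pct_deficit")
  tr <- fit[fit$term == "treatment", ]
  expect_gt(tr$conf_high, -10 - 3) # estimate near the truth...
  expect_lt(tr$conf_low, -10 + 3)
  expect_true(tr$conf_low <= -10 && -10 <= tr$conf_high) # ...and CI covers it
})

test_that("with balanced data and no time trend the treatment coefficient is the mean difference", {
  long <- simulate_lmm_data(n_patients = 60, treatment_effect = -8,
                            time_slope = 0, interaction = 0, rand_sd = 3,
                            resid_sd = 2, seed = 19)
  fit <- fit_lmm(long, "pct_deficit")
  by_arm <- tapply(long$pct_deficit, long$treatment, mean)
  expect_equal(fit$estimate[fit$term == "treatment"],
               unname(by_arm["1"] - by_arm["0"]), tolerance = 0.35)
})

test_that("daily group means use t-based intervals per day and arm", {
  long <- tibble::tibble(
    arm = rep(c("standard", "individualized"), each = 4),
    day = rep(c(1L, 1L, 1L, 2L), 2),
    y = c(10, 12, 14, 9, 5, 6, 7, 4)
  )
  dm <- daily_group_means(long, "y")
  row <- dm[dm$arm == "standard" & dm$day == 1, ]
  expect_equal(row$mean, 12)
  half <- qt(0.975, 2) * sd(c(10, 12, 14)) / sqrt(3)
  expect_equal(row$conf_low, 12 - half)
  expect_equal(row$conf_high, 12 + half)
  # singleton cell: mean, missing CI; no rows for absent days
  s2 <- dm[dm$arm == "standard" & dm$day == 2, ]
  expect_equal(s2$mean, 9)
  expect_true(is.na(s2$conf_low))
  expect_equal(sort(unique(dm$day)), c(1L, 2L))
  # constant outcome: zero-width interval
  const <- daily_group_means(tibble::tibble(arm = "standard", day = 1L,
                                            y = rep(7, 5)), "y")
  expect_equal(const$conf_low, 7)
  expect_equal(const$conf_high, 7)
})

test_that("build_daily_long shapes patient-day data for the models", {
  tr <- generate_trial(sim_config(n_patients = 16, seed = 55))
  long <- build_daily_long(tr$vitals, tr$cohort, tr$labs)
  expect_true(all(c("pct_deficit", "achieved_map", "vasopressor_dose",
                    "daily_highest", "daily_lowest", "daily_peak_creatinine",
                    "treatment", "days_since_rand") %in% names(long)))
  expect_true(all(long$daily_lowest <= long$daily_highest))
  expect_true(all(long$treatment %in% 0:1))
  one <- long[long$patient_id == long$patient_id[1] & long$day == 1, ]
  vit1 <- tr$vitals[tr$vitals$patient_id == one$patient_id &
                    tr$vitals$t_hours < 24, ]
  expect_equal(one$achieved_map, mean(vit1$map_mmHg))
  fit <- fit_lmm(long, "pct_deficit")
  expect_true(all(c("treatment", "treatment:days_since_rand") %in% fit$term))
})
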