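test_that("indirect effects are exactly additive and vanish when a = 0", {
  Vb <- matrix(c(0.004, -0.001, -0.001, 0.2), 2, 2)
  ind <- indirect_effects(a = -0.3, var_a = 0.0036, b_w = -0.687, b_b = 0.34,
                          vcov_b = Vb, mc_draws = 1000, mc_seed = 1)
  g <- function(e) ind$estimate[ind$effect == e]
  expect_identical(g("total"), g("within") + g("contextual"))
  expect_equal(g("within"), -0.3 * -0.687)

  ind0 <- indirect_effects(a = 0, var_a = 0.0036, b_w = -0.687, b_b = 0.34,
                           vcov_b = Vb, mc_draws = 0)
  expect_equal(ind0$estimate, c(0, 0, 0))
})

test_that("additivity holds on every fitted dataset", {
  for (seed in 1:3) {
    dat <- generate_trial(tiny_scenario(), seed = seed)
    med <- suppressWarnings(fit_baseline_mediation(dat, mc_draws = 200))
    g <- function(e) med$indirect$estimate[med$indirect$effect == e]
    expect_identical(g("total"), g("within") + g("contextual"))
  }
})

test_that("Monte-Carlo indirect intervals are seeded and reproducible", {
  Vb <- matrix(c(0.004, 0, 0, 0.2), 2, 2)
  i1 <- indirect_effects(-0.3, 0.0036, -0.687, 0.34, Vb, mc_seed = 42,
                         mc_draws = 2000)
  i2 <- indirect_effects(-0.3, 0.0036, -0.687, 0.34, Vb, mc_seed = 42,
                         mc_draws = 2000)
  expect_identical(i1$mc.low, i2$mc.low)
  i3 <- indirect_effects(-0.3, 0.0036, -0.687, 0.34, Vb, mc_seed = 43,
                         mc_draws = 2000)
  expect_false(identical(i1$mc.low, i3$mc.low))
})

test_that("baseline mediation recovers the uncentred formulation's path structure", {
  dat <- generate_trial(trial_scenario(J = 30, n_per_cluster = 60), seed = 12)
  med <- fit_baseline_mediation(dat, mc_draws = 500)
  expect_setequal(med$paths$term, c("a", "b_within", "b_between", "c_prime"))
  ## the outcome fit must include both the uncentred mediator and its
  ## cluster mean
  expect_true(all(c("mediator", "mediator_cluster_mean") %in%
                    names(med$fits$outcome$beta)))
  expect_true(med$mediator_screen$pass)  # generating a = -0.3 is detectable here
})

test_that("a null treatment-mediator path fails the screen with a warning, never an error", {
  dat <- generate_trial(trial_scenario(J = 10, n_per_cluster = 15, a = 0),
                        seed = 7)
  expect_warning(med <- fit_baseline_mediation(dat, mc_draws = 200),
                 "should not be considered further")
  expect_false(med$mediator_screen$pass)
  ## the moderation tests still run on the same data
  t1 <- fit_test1(dat)
  t2 <- fit_test2(dat)
  expect_s3_class(t1, "hcp_test")
  expect_s3_class(t2, "hcp_test")
})

test_that("a degenerate mediator is rejected", {
  df <- toy_trial_df()
  df$mediator <- 1
  expect_error(suppressWarnings(
    fit_baseline_mediation(as_trial_data(df, quiet = TRUE))),
    "degenerate", class = "hcp_validation_error")
})

test_that("classification follows the directional sign rule", {
  expect_equal(classify_hcp(-0.5, 0.01)$classification, "paradox_supported")
  expect_equal(classify_hcp(0.5, 0.01)$classification, "opposite_direction")
  ## the two magnitudes reported for the motivating trial are both
  ## non-significant, hence not_supported regardless of sign
  expect_equal(classify_hcp(1.089, 0.20)$classification, "not_supported")
  expect_equal(classify_hcp(-0.148, 0.21)$classification, "not_supported")
  ## flipping a direction flag flips the paradox sign
  expect_equal(classify_hcp(0.5, 0.01,
                            outcome_higher_is_better = FALSE)$classification,
               "paradox_supported")
  expect_equal(classify_hcp(0.5, 0.01,
                            mediator_higher_is_worse = FALSE)$classification,
               "paradox_supported")
  expect_equal(classify_hcp(-0.5, 0.01, mediator_higher_is_worse = FALSE,
                            outcome_higher_is_better = FALSE)$classification,
               "paradox_supported")
  ## alpha is respected
  expect_equal(classify_hcp(-0.5, 0.04, alpha = 0.01)$classification,
               "not_supported")
})

test_that("Test 1 reports the between-level interaction with a df-1 Wald comparison", {
  dat <- generate_trial(small_scenario(), seed = 13)
  t1 <- fit_test1(dat)
  expect_equal(t1$level, "contextual")
  expect_equal(t1$wald_vs_baseline$df, 1L)
  expect_equal(t1$wald_vs_baseline$terms, "mediator_cluster_mean:treatment")
  ## the Wald statistic for one fixed constraint equals est^2 / var from
  ## the joint observed-information covariance
  est <- t1$moderation$estimate
  v <- t1$fit$vcov["mediator_cluster_mean:treatment",
                   "mediator_cluster_mean:treatment"]
  expect_equal(t1$wald_vs_baseline$statistic, est^2 / v, tolerance = 1e-8)
})

test_that("Test 2 reports slope moderation with df-3 and df-2 Wald comparisons", {
  dat <- generate_trial(small_scenario(), seed = 14)
  t2 <- fit_test2(dat)
  expect_equal(t2$level, "individual")
  expect_setequal(t2$wald_vs_baseline$terms,
                  c("mediator_dev:treatment", "tau1", "tau01"))
  expect_equal(t2$wald_vs_baseline$df, 3L)
  expect_setequal(t2$wald_vs_reduced$terms, c("mediator_dev:treatment", "tau01"))
  expect_equal(t2$wald_vs_reduced$df, 2L)
  ## the centred formulation reports the control-arm slope and the
  ## between coefficient separately
  expect_equal(t2$control_arm_slope$term, "mediator_dev")
  expect_equal(t2$between_sum$term, "mediator_cluster_mean")
  expect_match(t2$wald_vs_baseline$caveat, "non-standard")
})

test_that("Test 2 control-arm slope agrees with baseline b_w absent heterogeneity or moderation", {
  ## no random slope, no moderation: the centred slope should estimate the
  ## same quantity as the uncentred within path, on average
  sc <- trial_scenario(J = 24, n_per_cluster = 40, tau2_1 = 0, tau01 = 0)
  diffs <- vapply(1:20, function(r) {
    dat <- generate_trial(sc, seed = 100 + r)
    med <- suppressWarnings(fit_baseline_mediation(dat, mc_draws = 0))
    t2 <- fit_test2(dat)
    t2$control_arm_slope$estimate -
      med$paths$estimate[med$paths$term == "b_within"]
  }, numeric(1))
  ## centred vs uncentred slope differ only via arm-specific sampling noise
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)) + 0.02)
})

test_that("delta-method and Monte-Carlo intervals agree on large samples", {
  dat <- generate_trial(trial_scenario(J = 80, n_per_cluster = 100), seed = 15)
  med <- fit_baseline_mediation(dat, mc_draws = 50000, mc_seed = 2)
  ind <- med$indirect
  for (k in seq_len(nrow(ind))) {
    width <- ind$conf.high[k] - ind$conf.low[k]
    expect_lt(abs(ind$mc.low[k] - ind$conf.low[k]), 0.1 * width)
    expect_lt(abs(ind$mc.high[k] - ind$conf.high[k]), 0.1 * width)
  }
})

test_that("tidy and glance methods return the documented columns", {
  dat <- generate_trial(tiny_scenario(), seed = 16)
  med <- suppressWarnings(fit_baseline_mediation(dat, mc_draws = 100))
  tt <- tidy(med)
  expect_true(all(c("a", "b_within", "b_between", "c_prime",
                    "indirect_total") %in% tt$term))
  t1 <- fit_test1(dat)
  g <- glance(t1)
  expect_named(g, c("level", "moderation", "p.value", "wald_statistic",
                    "wald_df", "wald_p", "classification", "converged"))
  expect_equal(tidy(t1)$term, "gamma_B")
  t2 <- fit_test2(dat)
  expect_equal(tidy(t2)$term, "d")
})
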