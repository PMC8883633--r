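test_that("fitted loglik equals a dense multivariate-normal evaluation (tiny data)", {
  ## 3 clusters x 2 members, fixed numbers
  df <- data.frame(
    cluster = rep(c("a", "b", "c", "d"), each = 2),
    treatment = rep(c(0, 1, 0, 1), each = 2),
    mediator = c(1.0, 2.0, 0.5, 1.5, 2.5, 3.0, 1.2, 0.8),
    outcome = c(3.1, 2.0, 4.0, 2.2, 1.0, 0.5, 2.8, 3.3)
  )
  td <- as_trial_data(df, quiet = TRUE)
  fit <- fit_lmm(td, outcome ~ mediator + treatment)
  direct <- oracle_loglik(td, outcome ~ mediator + treatment,
                          beta = fit$beta, vc = fit$vc)
  expect_equal(fit$loglik, direct, tolerance = 1e-6)
})

test_that("loglik matches the dense oracle for random-slope models on <=30 rows", {
  dat <- center_within_cluster(generate_trial(
    trial_scenario(J = 5, n_per_cluster = 6, tau2_1 = 0.3, tau01 = 0.1),
    seed = 2))
  fit <- fit_lmm(dat, outcome ~ mediator_dev + treatment,
                 random_slope = "mediator_dev")
  direct <- oracle_loglik(dat, outcome ~ mediator_dev + treatment,
                          beta = fit$beta, vc = fit$vc,
                          random_slope = "mediator_dev")
  expect_equal(fit$loglik, direct, tolerance = 1e-6)
})

test_that("engine agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  dat <- center_within_cluster(generate_trial(small_scenario(), seed = 3))
  fit <- fit_lmm(dat, outcome ~ mediator + mediator_cluster_mean + treatment)
  ref <- lme4::lmer(outcome ~ mediator + mediator_cluster_mean + treatment +
                      (1 | cluster), dat, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-4)

  fit2 <- fit_lmm(dat, outcome ~ mediator_dev + mediator_cluster_mean +
                    treatment + mediator_dev:treatment,
                  random_slope = "mediator_dev")
  ref2 <- lme4::lmer(outcome ~ mediator_dev + mediator_cluster_mean +
                       treatment + mediator_dev:treatment +
                       (1 + mediator_dev | cluster), dat, REML = FALSE)
  expect_equal(fit2$loglik, as.numeric(stats::logLik(ref2)), tolerance = 1e-6)
  expect_equal(unname(fit2$beta), unname(lme4::fixef(ref2)), tolerance = 1e-4)
  vc_ref <- lme4::VarCorr(ref2)$cluster
  expect_equal(unname(fit2$vc[c("tau0", "tau1", "tau01")]),
               c(vc_ref[1, 1], vc_ref[2, 2], vc_ref[1, 2]), tolerance = 1e-3)
})

test_that("monotone likelihood: a nesting model never fits worse than its nested model", {
  dat <- center_within_cluster(generate_trial(small_scenario(), seed = 5))
  base <- fit_lmm(dat, outcome ~ mediator + mediator_cluster_mean + treatment)
  full <- fit_lmm(dat, outcome ~ mediator + mediator_cluster_mean + treatment +
                    mediator_cluster_mean:treatment)
  expect_gte(full$loglik, base$loglik - 1e-6)
  slope <- fit_lmm(dat, outcome ~ mediator_dev + mediator_cluster_mean +
                     treatment + mediator_dev:treatment,
                   random_slope = "mediator_dev")
  base2 <- fit_lmm(dat, outcome ~ mediator_dev + mediator_cluster_mean +
                     treatment + mediator_dev:treatment)
  expect_gte(slope$loglik, base2$loglik - 1e-6)
})

test_that("estimates are invariant under within-cluster row permutation and re-fits are deterministic", {
  dat <- generate_trial(tiny_scenario(), seed = 6)
  fit1 <- fit_lmm(dat, outcome ~ mediator + treatment)
  perm <- withr::with_seed(99, {
    idx <- unlist(tapply(seq_len(nrow(dat)), dat$cluster, sample))
    dat[idx, ]
  })
  fit2 <- fit_lmm(perm, outcome ~ mediator + treatment)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
  fit3 <- fit_lmm(dat, outcome ~ mediator + treatment)
  expect_identical(fit1$beta, fit3$beta)
  expect_identical(fit1$loglik, fit3$loglik)
})

test_that("one member per cluster degenerates to pooled OLS with a flagged boundary", {
  df <- data.frame(
    cluster = sprintf("c%02d", 1:12),
    treatment = rep(c(0, 1), 6),
    mediator = c(0.1, 1.3, 2.2, 0.7, 1.8, 2.9, 0.4, 1.1, 2.6, 0.9, 1.5, 2.0),
    outcome = c(3.2, 2.1, 1.4, 2.8, 1.9, 0.7, 3.0, 2.4, 1.1, 2.6, 2.0, 1.6)
  )
  td <- as_trial_data(df, quiet = TRUE)
  fit <- fit_lmm(td, outcome ~ mediator + treatment)
  ols <- stats::lm(outcome ~ mediator + treatment, td)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-5)
  expect_false(fit$convergence$converged)
  expect_match(paste(fit$convergence$boundary, collapse = " "),
               "not separately identified")
})

test_that("rank-deficient designs raise an informative error naming the collinear term", {
  dat <- generate_trial(tiny_scenario(), seed = 7)
  dat$dup <- dat$treatment
  expect_error(fit_lmm(dat, outcome ~ mediator + treatment + dup),
               "dup", class = "hcp_rank_error")
})

test_that("Wald statistics match closed forms for single constraints", {
  dat <- generate_trial(small_scenario(), seed = 8)
  fit <- fit_lmm(dat, outcome ~ mediator + treatment)
  w <- wald_test(fit, "treatment")
  est <- fit$beta[["treatment"]]
  v <- fit$vcov["treatment", "treatment"]
  expect_equal(w$statistic, est^2 / v, tolerance = 1e-10)
  expect_equal(w$df, 1L)
  expect_equal(w$p.value, pchisq(est^2 / v, 1, lower.tail = FALSE))

  ## a zero estimate must give statistic 0 and p = 1
  fit0 <- fit
  fit0$beta[["treatment"]] <- 0
  w0 <- wald_test(fit0, "treatment")
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p.value, 1)

  expect_error(wald_test(fit, "nonexistent"), "Unknown parameter")
})

test_that("joint parameter covariance is symmetric PSD and spans variance components", {
  dat <- center_within_cluster(generate_trial(small_scenario(), seed = 9))
  fit <- fit_lmm(dat, outcome ~ mediator_dev + treatment + mediator_dev:treatment,
                 random_slope = "mediator_dev")
  V <- fit$vcov
  expect_true(all(c("sigma2", "tau0", "tau1", "tau01") %in% rownames(V)))
  expect_equal(V, t(V), tolerance = 1e-8)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("between-within degrees of freedom follow the term's level", {
  dat <- center_within_cluster(generate_trial(small_scenario(), seed = 10))
  J <- length(unique(dat$cluster)); N <- nrow(dat)
  fit <- fit_lmm(dat, outcome ~ mediator + mediator_cluster_mean + treatment)
  df <- fit$df_fixed
  ## cluster-level terms: intercept, cluster mean, treatment -> J - 3
  expect_equal(unname(df[c("(Intercept)", "mediator_cluster_mean", "treatment")]),
               rep(J - 3, 3))
  ## individual-level mediator -> N - J - 1
  expect_equal(unname(df[["mediator"]]), N - J - 1)
  fit2 <- fit_lmm(dat, outcome ~ mediator_dev + mediator_cluster_mean +
                    treatment + mediator_dev:treatment,
                  random_slope = "mediator_dev")
  ## slope-model terms (deviation and its treatment product) -> J - 2
  expect_equal(unname(fit2$df_fixed[c("mediator_dev", "mediator_dev:treatment")]),
               rep(J - 2, 2))
  ## normal reference is available on request
  fitn <- fit_lmm(dat, outcome ~ mediator + treatment,
                  control = lmm_control(df_method = "normal"))
  tn <- tidy(fitn)
  expect_true(all(is.infinite(tn$df)))
  expect_equal(tn$p.value, 2 * pnorm(-abs(tn$statistic)))
})

test_that("fit serialises to JSON with estimates, covariance and convergence", {
  dat <- generate_trial(tiny_scenario(), seed = 11)
  fit <- fit_lmm(dat, outcome ~ mediator + treatment)
  js <- jsonlite::fromJSON(lmm_to_json(fit))
  expect_equal(js$loglik, fit$loglik)
  expect_equal(js$fixed_estimates$treatment, unname(fit$beta["treatment"]))
  expect_true(is.matrix(js$parameter_covariance))
  expect_false(is.null(js$convergence$converged))
})
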