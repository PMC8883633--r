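## Run code under a temporary RNG state so seeded Monte-Carlo intervals do
## not disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Indirect effects of a 2-1-1 mediation fit
#'
#' Assembles the within (individual), contextual, and total indirect effects
#' from the treatment-mediator path `a` and the mediator-outcome paths
#' `(b_w, b_b)`: `indirect_within = a * b_w`, `indirect_contextual =
#' a * b_b`, `indirect_total = a * (b_w + b_b)`, so the total is exactly the
#' sum of the two components. Standard errors are first-order delta method
#' treating `a` and `(b_w, b_b)` as independent (they come from two
#' separately fitted equations); the Monte-Carlo interval draws the paths
#' from their joint normal approximation.
#'
#' @param a,var_a Treatment-mediator path estimate and its variance.
#' @param b_w,b_b Within and contextual mediator-outcome path estimates.
#' @param vcov_b 2x2 covariance of `(b_w, b_b)`.
#' @param conf_level Interval coverage (default 0.95).
#' @param mc_draws Number of Monte-Carlo draws (0 to skip).
#' @param mc_seed Seed for the Monte-Carlo draws.
#' @return A tibble with one row per effect (`within`, `contextual`,
#'   `total`): estimate, delta-method SE and normal-theory interval, and
#'   Monte-Carlo percentile interval.
#' @export
indirect_effects <- function(a, var_a, b_w, b_b, vcov_b,
                             conf_level = 0.95, mc_draws = 10000,
                             mc_seed = 1) {
  stopifnot(is.matrix(vcov_b), all(dim(vcov_b) == 2))
  s <- b_w + b_b
  var_s <- vcov_b[1, 1] + vcov_b[2, 2] + 2 * vcov_b[1, 2]
  ## total computed as the literal sum so additivity holds exactly in
  ## floating point, not just algebraically
  est <- c(within = a * b_w, contextual = a * b_b,
           total = a * b_w + a * b_b)
  se <- c(
    within = sqrt(b_w^2 * var_a + a^2 * vcov_b[1, 1]),
    contextual = sqrt(b_b^2 * var_a + a^2 * vcov_b[2, 2]),
    total = sqrt(s^2 * var_a + a^2 * var_s)
  )
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble(effect = names(est), estimate = unname(est),
                std.error = unname(se),
                conf.low = unname(est - z * se),
                conf.high = unname(est + z * se),
                mc.low = NA_real_, mc.high = NA_real_)
  if (mc_draws > 0) {
    qs <- with_local_seed(mc_seed, {
      a_draw <- rnorm(mc_draws, a, sqrt(max(var_a, 0)))
      eg <- eigen(vcov_b, symmetric = TRUE)
      B <- matrix(rnorm(2 * mc_draws), mc_draws, 2) %*%
        (t(eg$vectors) * sqrt(pmax(eg$values, 0)))
      bw_draw <- b_w + B[, 1]; bb_draw <- b_b + B[, 2]
      pr <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
      rbind(within = stats::quantile(a_draw * bw_draw, pr),
            contextual = stats::quantile(a_draw * bb_draw, pr),
            total = stats::quantile(a_draw * (bw_draw + bb_draw), pr))
    })
    out$mc.low <- unname(qs[, 1])
    out$mc.high <- unname(qs[, 2])
  }
  out
}

#' Fit the baseline 2-1-1 multilevel mediation model
#'
#' Two random-intercept Gaussian mixed models: a mediator equation
#' (`mediator ~ treatment`) giving the treatment-mediator path `a`, and an
#' outcome equation with the uncentred individual-level mediator alongside
#' its observed cluster mean (`outcome ~ mediator + mediator_cluster_mean +
#' treatment`). In this uncentred formulation the cluster-mean coefficient
#' IS the contextual effect `b_b` (the between-minus-within difference),
#' the individual-level coefficient is the within effect `b_w`, and the
#' treatment coefficient is the direct path `c'`. Indirect effects are
#' `a * b_w` (within), `a * b_b` (contextual) and their exact sum (total);
#' see [indirect_effects()].
#'
#' A non-significant `a` path fails the mediator screen: the function warns
#' that the candidate mediator should not be considered further, but never
#' refuses to fit (a null mediator-outcome path at one level can mask
#' effects at the other, so the moderation tests remain worth running).
#'
#' @param data A `trial_data` tibble.
#' @param alpha Two-sided level for the mediator screen.
#' @param conf_level Interval coverage for indirect effects.
#' @param mc_draws,mc_seed Monte-Carlo interval settings (`mc_draws = 0`
#'   skips the interval).
#' @param control [lmm_control()] settings.
#' @return An object of class `hcp_mediation`: `paths` (tibble with rows
#'   `a`, `b_within`, `b_between`, `c_prime`), `indirect` (tibble from
#'   [indirect_effects()]), `mediator_screen` (list with `pass` and
#'   `p_value`), and the two underlying `hcp_lmm` fits.
#' @examples
#' dat <- generate_trial(trial_scenario(J = 12, n_per_cluster = 30), seed = 1)
#' med <- fit_baseline_mediation(dat)
#' med$paths
#' @export
fit_baseline_mediation <- function(data, alpha = 0.05, conf_level = 0.95,
                                   mc_draws = 10000, mc_seed = 1,
                                   control = lmm_control()) {
  data <- center_within_cluster(data)
  if (sd(data$mediator) < 1e-12) {
    abort("Mediator is degenerate (zero variance).",
          class = "hcp_validation_error")
  }
  med_fit <- fit_lmm(data, mediator ~ treatment, control = control)
  out_fit <- fit_lmm(data, outcome ~ mediator + mediator_cluster_mean + treatment,
                     control = control)

  tm <- tidy(med_fit); to <- tidy(out_fit)
  row <- function(tt, term) tt[tt$term == term, ]
  a_row <- row(tm, "treatment")
  paths <- dplyr::bind_rows(
    mutate(a_row, term = "a"),
    mutate(row(to, "mediator"), term = "b_within"),
    mutate(row(to, "mediator_cluster_mean"), term = "b_between"),
    mutate(row(to, "treatment"), term = "c_prime")
  )

  Vb <- out_fit$vcov[c("mediator", "mediator_cluster_mean"),
                     c("mediator", "mediator_cluster_mean")]
  ind <- indirect_effects(
    a = a_row$estimate, var_a = a_row$std.error^2,
    b_w = paths$estimate[paths$term == "b_within"],
    b_b = paths$estimate[paths$term == "b_between"],
    vcov_b = Vb, conf_level = conf_level,
    mc_draws = mc_draws, mc_seed = mc_seed
  )

  screen_pass <- a_row$p.value < alpha
  if (!screen_pass) {
    warn(paste0(
      "Mediator screen: the treatment-mediator path is not significant (p = ",
      format.pval(a_row$p.value, digits = 3),
      "). A candidate mediator without a detectable treatment effect should not be ",
      "considered further; the moderation tests are still computed."))
  }

  structure(list(
    paths = paths,
    indirect = ind,
    mediator_screen = list(pass = screen_pass, p_value = a_row$p.value,
                           alpha = alpha),
    fits = list(mediator = med_fit, outcome = out_fit),
    alpha = alpha,
    directions = trial_directions(data)
  ), class = "hcp_mediation")
}

#' @export
print.hcp_mediation <- function(x, ...) {
  cat("Baseline 2-1-1 multilevel mediation model\n")
  cat("Paths (a: treatment->mediator; b_within / b_between: mediator->outcome",
      "at individual / contextual level; c_prime: direct):\n")
  print(x$paths, n = Inf)
  cat("Indirect effects (total = within + contextual):\n")
  print(x$indirect, n = Inf)
  cat(if (x$mediator_screen$pass)
    "Mediator screen: PASS (treatment-mediator path significant).\n"
    else "Mediator screen: FAIL (treatment-mediator path not significant).\n")
  invisible(x)
}

#' @method tidy hcp_mediation
#' @export
tidy.hcp_mediation <- function(x, ...) {
  dplyr::bind_rows(
    select(x$paths, "term", "estimate", "std.error", "p.value"),
    x$indirect %>%
      mutate(term = paste0("indirect_", .data$effect), p.value = NA_real_) %>%
      select("term", "estimate", "std.error", "p.value")
  )
}

#' @method glance hcp_mediation
#' @export
glance.hcp_mediation <- function(x, ...) {
  tibble(
    indirect_total = x$indirect$estimate[x$indirect$effect == "total"],
    screen_pass = x$mediator_screen$pass,
    screen_p = x$mediator_screen$p_value,
    loglik_mediator = x$fits$mediator$loglik,
    loglik_outcome = x$fits$outcome$loglik,
    nobs = x$fits$outcome$N,
    n_clusters = x$fits$outcome$J
  )
}

#' Classify evidence for the healthy context paradox
#'
#' Applies the directional decision rule to a moderation coefficient: the
#' paradox is supported only when the coefficient is significant at `alpha`
#' AND its sign implies a stronger adverse mediator-outcome association
#' under intervention. With the default scale directions (higher mediator =
#' worse, higher outcome = better) the adverse association is negative, so
#' the paradox sign is negative; flipping either flag flips the expected
#' sign.
#'
#' @param estimate Moderation coefficient (treatment x cluster-mean
#'   interaction for the contextual test; treatment effect on the within
#'   slope for the individual test).
#' @param p_value Its two-sided p-value.
#' @param alpha Significance level.
#' @param mediator_higher_is_worse,outcome_higher_is_better Direction flags.
#' @return A list with `classification` (one of `"paradox_supported"`,
#'   `"opposite_direction"`, `"not_supported"`), `paradox_sign`, and a
#'   human-readable `direction_note`.
#' @examples
#' classify_hcp(-0.5, 0.01)$classification   # "paradox_supported"
#' classify_hcp(1.089, 0.20)$classification  # "not_supported"
#' @export
classify_hcp <- function(estimate, p_value, alpha = 0.05,
                         mediator_higher_is_worse = TRUE,
                         outcome_higher_is_better = TRUE) {
  s_m <- if (isTRUE(mediator_higher_is_worse)) 1 else -1
  s_y <- if (isTRUE(outcome_higher_is_better)) 1 else -1
  paradox_sign <- -s_m * s_y
  significant <- is.finite(p_value) && p_value <= alpha
  classification <- if (!significant) "not_supported" else
    if (sign(estimate) == paradox_sign) "paradox_supported" else
      "opposite_direction"
  sign_word <- if (paradox_sign < 0) "negative" else "positive"
  note <- switch(
    classification,
    paradox_supported = paste0(
      "Significant moderation with the ", sign_word,
      " sign expected under a healthy context paradox: the adverse ",
      "mediator-outcome association is stronger under intervention."),
    opposite_direction = paste0(
      "Significant moderation with the sign OPPOSITE to a healthy context ",
      "paradox: it would indicate an enhanced benefit on the outcome in ",
      "clusters (or for individuals) experiencing residually higher ",
      "mediator levels."),
    not_supported = paste0(
      "Moderation not significant at alpha = ", alpha,
      ": no evidence of a healthy context paradox at this level. ",
      "(A healthy context paradox would show as a significant ", sign_word,
      " coefficient given the scale directions.)"))
  list(classification = classification, paradox_sign = paradox_sign,
       direction_note = note)
}

## shared constructor for the two test-result objects
new_hcp_test <- function(level, moderation, wald_vs_baseline, cls, fit,
                         alpha, extra = list()) {
  structure(c(list(
    level = level,
    moderation = moderation,
    wald_vs_baseline = wald_vs_baseline,
    classification = cls$classification,
    direction_note = cls$direction_note,
    fit = fit,
    alpha = alpha
  ), extra), class = "hcp_test")
}

#' Test 1: contextual-level healthy context paradox
#'
#' Augments the baseline outcome equation with the product of treatment and
#' the observed cluster mean of the mediator, so the contextual
#' mediator-outcome path differs between arms:
#' `outcome ~ mediator + mediator_cluster_mean + treatment +
#' mediator_cluster_mean:treatment`, with a cluster random intercept. The
#' interaction coefficient `gamma_B` is the contextual moderation; the Wald
#' comparison against the baseline model constrains that single parameter
#' (df = 1). Classification follows [classify_hcp()] under the dataset's
#' direction flags.
#'
#' @param data A `trial_data` tibble.
#' @param alpha Significance level for classification.
#' @param control [lmm_control()] settings.
#' @return An `hcp_test` object: `moderation` (tidy row for `gamma_B`),
#'   `wald_vs_baseline` (`hcp_wald`, df 1), `classification`,
#'   `direction_note`, and the full `hcp_lmm` fit.
#' @examples
#' dat <- generate_trial(trial_scenario(J = 12, n_per_cluster = 30), seed = 1)
#' fit_test1(dat)
#' @export
fit_test1 <- function(data, alpha = 0.05, control = lmm_control()) {
  data <- center_within_cluster(data)
  cs <- cluster_summaries(data)
  ## near-collinearity between the cluster mean and its product with treatment
  tm <- cs$treatment * cs$mediator_mean
  if (sd(tm) > 0 && abs(stats::cor(cs$mediator_mean, tm)) > 0.995) {
    warn("Cluster mediator mean and its treatment interaction are nearly collinear; the contextual moderation may be poorly identified.")
  }
  fit <- fit_lmm(data,
                 outcome ~ mediator + mediator_cluster_mean + treatment +
                   mediator_cluster_mean:treatment,
                 control = control)
  term <- "mediator_cluster_mean:treatment"
  moderation <- tidy(fit) %>% filter(.data$term == !!term)
  wb <- wald_test(fit, term)
  dirs <- trial_directions(data)
  cls <- classify_hcp(moderation$estimate, moderation$p.value, alpha = alpha,
                      mediator_higher_is_worse = dirs$mediator_higher_is_worse,
                      outcome_higher_is_better = dirs$outcome_higher_is_better)
  new_hcp_test("contextual", moderation, wb, cls, fit, alpha)
}

#' Test 2: individual-level healthy context paradox
#'
#' Re-expresses the outcome equation in the cluster-mean-centred
#' formulation: the within-cluster mediator deviation enters with a cluster
#' random slope (co-varying with the random intercept), and the slope is
#' regressed on treatment — implemented, as in the standard
#' random-coefficients representation, as the fixed cross-level product
#' `mediator_dev:treatment` with coefficient `d` plus the random slope:
#' `outcome ~ mediator_dev + mediator_cluster_mean + treatment +
#' mediator_dev:treatment`.
#'
#' In this centred formulation the cluster-mean coefficient is no longer
#' the contextual effect alone but approximates the SUM of the contextual
#' and individual effects (`b_w + b_b`), and the deviation's main
#' coefficient is the within-cluster slope in the CONTROL arm. Two Wald
#' comparisons are reported, both computed from the full fit's joint
#' parameter covariance: against the baseline model, constraining `d`, the
#' slope variance `tau1` and the slope-intercept covariance `tau01`
#' (df = 3); and against the reduced model that keeps the random slope but
#' drops its treatment regression and the covariance, constraining `d` and
#' `tau01` (df = 2).
#'
#' @inheritParams fit_test1
#' @return An `hcp_test` object: `moderation` (tidy row for `d`),
#'   `wald_vs_baseline` (df 3), `wald_vs_reduced` (df 2),
#'   `control_arm_slope` and `between_sum` tidy rows, `classification`,
#'   `direction_note`, and the full `hcp_lmm` fit.
#' @examples
#' dat <- generate_trial(trial_scenario(J = 12, n_per_cluster = 30), seed = 1)
#' fit_test2(dat)
#' @export
fit_test2 <- function(data, alpha = 0.05, control = lmm_control()) {
  data <- center_within_cluster(data)
  fit <- fit_lmm(data,
                 outcome ~ mediator_dev + mediator_cluster_mean + treatment +
                   mediator_dev:treatment,
                 random_slope = "mediator_dev", cov_slope_intercept = TRUE,
                 control = control)
  term <- "mediator_dev:treatment"
  tt <- tidy(fit)
  moderation <- tt %>% filter(.data$term == !!term)
  wb <- wald_test(fit, c(term, "tau1", "tau01"))
  wr <- wald_test(fit, c(term, "tau01"))
  dirs <- trial_directions(data)
  cls <- classify_hcp(moderation$estimate, moderation$p.value, alpha = alpha,
                      mediator_higher_is_worse = dirs$mediator_higher_is_worse,
                      outcome_higher_is_better = dirs$outcome_higher_is_better)
  new_hcp_test("individual", moderation, wb, cls, fit, alpha,
               extra = list(
                 wald_vs_reduced = wr,
                 control_arm_slope = tt %>% filter(.data$term == "mediator_dev"),
                 between_sum = tt %>%
                   filter(.data$term == "mediator_cluster_mean")
               ))
}

#' @export
print.hcp_test <- function(x, ...) {
  cat("Healthy context paradox test -", x$level, "level\n")
  cat("Moderation coefficient",
      if (x$level == "contextual") "(treatment x cluster mediator mean):"
      else "(treatment effect on the within-cluster slope):", "\n")
  print(x$moderation)
  cat("Wald comparison vs baseline model:\n")
  print(x$wald_vs_baseline)
  if (!is.null(x$wald_vs_reduced)) {
    cat("Wald comparison vs reduced model (random slope retained):\n")
    print(x$wald_vs_reduced)
    cat("Control-arm within-cluster slope:",
        format(x$control_arm_slope$estimate, digits = 4),
        " (SE", format(x$control_arm_slope$std.error, digits = 3), ")\n")
    cat("Cluster-mean coefficient (~ sum of individual + contextual effects):",
        format(x$between_sum$estimate, digits = 4), "\n")
  }
  cat("Classification:", x$classification, "\n")
  cat(strwrap(x$direction_note, width = 78, prefix = "  "), sep = "\n")
  invisible(x)
}

#' @method tidy hcp_test
#' @export
tidy.hcp_test <- function(x, ...) {
  mutate(x$moderation,
         term = if (x$level == "contextual") "gamma_B" else "d",
         level = x$level,
         classification = x$classification)
}

#' @method glance hcp_test
#' @export
glance.hcp_test <- function(x, ...) {
  tibble(level = x$level,
         moderation = x$moderation$estimate,
         p.value = x$moderation$p.value,
         wald_statistic = x$wald_vs_baseline$statistic,
         wald_df = x$wald_vs_baseline$df,
         wald_p = x$wald_vs_baseline$p.value,
         classification = x$classification,
         converged = x$fit$convergence$converged)
}
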