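#' Define a generative scenario for a two-level cluster-randomised trial
#'
#' Parameters of the synthetic trial generator. The defaults describe a
#' school-randomised trial of the size and effect structure of a large UK
#' whole-school trial: 40 schools of 150 students, a continuous mediator on
#' a victimisation-type scale (higher = worse) and a continuous wellbeing
#' outcome (higher = better), with a within-school mediator-outcome slope of
#' -0.687, a contextual (between-school) increment of 0.34, and no
#' treatment moderation at either level (`gamma_B = 0`, `d = 0`). Variance
#' defaults are chosen so that standard errors at the default sizes are of
#' the order reported for trials of this scale (SE of the within slope
#' ~0.06; SE of the contextual path ~0.45). The treatment effect on the
#' mediator (`a = -0.30`) is a package choice, as is the modest random
#' slope variance.
#'
#' The generative equations, for cluster j with treatment `T_j` and
#' individual i, are:
#' \deqn{\mu_{Mj} = \alpha_0 + a T_j + u^M_j, \quad u^M_j \sim N(0, \tau^2_M)}
#' \deqn{m_{ij} = \mu_{Mj} + e^M_{ij}, \quad e^M_{ij} \sim N(0, \sigma^2_M)}
#' \deqn{y_{ij} = \beta_0 + c' T_j + (b_b + b_w + \gamma_B T_j)\mu_{Mj}
#'   + (b_w + d T_j + s_j)(m_{ij} - \mu_{Mj}) + u^Y_j + e^Y_{ij}}
#' with \eqn{(u^Y_j, s_j)} jointly normal with variances
#' \eqn{(\tau^2_0, \tau^2_1)} and covariance \eqn{\tau_{01}}, and
#' \eqn{e^Y_{ij} \sim N(0, \sigma^2)}. Generation conditions on the latent
#' cluster mean \eqn{\mu_{Mj}}, while estimation uses the observed cluster
#' mean; the finite-cluster-size gap between the two produces a small,
#' documented attenuation.
#'
#' @param J Number of clusters (>= 4).
#' @param n_per_cluster Individuals per cluster: a single number for
#'   constant sizes, or a length-2 integer range for uniform sampling.
#' @param allocation Fraction of clusters treated (default 0.5, balanced).
#' @param alpha0 Mediator intercept.
#' @param a Treatment effect on the mediator (mediator-scale units).
#' @param tau2_M Between-cluster variance of the mediator.
#' @param sigma2_M Within-cluster variance of the mediator.
#' @param beta0 Outcome intercept.
#' @param c_prime Direct treatment effect on the outcome.
#' @param b_w Within-cluster (individual) mediator-outcome slope.
#' @param b_b Contextual increment: the between-cluster slope is
#'   `b_w + b_b`.
#' @param gamma_B Treatment moderation of the between-cluster slope
#'   (contextual-level healthy-context-paradox effect; negative under the
#'   default direction flags).
#' @param d Treatment moderation of the within-cluster slope
#'   (individual-level healthy-context-paradox effect).
#' @param tau2_0 Outcome random-intercept variance.
#' @param tau2_1 Random-slope variance of the within-cluster slope.
#' @param tau01 Intercept-slope covariance (must keep the 2x2 random-effects
#'   covariance positive semi-definite).
#' @param sigma2 Outcome residual variance.
#'
#' @return A list of class `hcp_scenario`.
#' @seealso [generate_trial()], [operating_characteristics()],
#'   [scenario_contextual_paradox()], [scenario_individual_paradox()]
#' @export
trial_scenario <- function(J = 40, n_per_cluster = 150, allocation = 0.5,
                           alpha0 = 0.6, a = -0.30,
                           tau2_M = 0.05, sigma2_M = 0.5,
                           beta0 = 23.5, c_prime = 0.3,
                           b_w = -0.687, b_b = 0.34,
                           gamma_B = 0, d = 0,
                           tau2_0 = 0.4, tau2_1 = 0.02, tau01 = 0,
                           sigma2 = 9) {
  sc <- list(J = as.integer(J), n_per_cluster = n_per_cluster,
             allocation = allocation, alpha0 = alpha0, a = a,
             tau2_M = tau2_M, sigma2_M = sigma2_M, beta0 = beta0,
             c_prime = c_prime, b_w = b_w, b_b = b_b,
             gamma_B = gamma_B, d = d, tau2_0 = tau2_0, tau2_1 = tau2_1,
             tau01 = tau01, sigma2 = sigma2)
  validate_scenario(sc)
  structure(sc, class = "hcp_scenario")
}

validate_scenario <- function(sc) {
  if (sc$J < 4) abort("Need J >= 4 clusters.", class = "hcp_validation_error")
  if (sc$allocation <= 0 || sc$allocation >= 1) {
    abort("`allocation` must be strictly between 0 and 1.",
          class = "hcp_validation_error")
  }
  nv <- c("tau2_M", "sigma2_M", "tau2_0", "tau2_1", "sigma2")
  for (v in nv) {
    if (sc[[v]] < 0) abort(paste0("`", v, "` must be >= 0."),
                           class = "hcp_validation_error")
  }
  if (sc$tau01^2 > sc$tau2_0 * sc$tau2_1 + 1e-12) {
    abort("Random-effects covariance not positive semi-definite: tau01^2 > tau2_0 * tau2_1.",
          class = "hcp_validation_error")
  }
  npc <- sc$n_per_cluster
  if (!length(npc) %in% c(1, 2) || any(npc < 1)) {
    abort("`n_per_cluster` must be a positive size or a length-2 range.",
          class = "hcp_validation_error")
  }
  if (length(npc) == 2 && npc[1] > npc[2]) {
    abort("`n_per_cluster` range must be increasing.",
          class = "hcp_validation_error")
  }
  invisible(sc)
}

#' Scenario with a planted contextual-level paradox
#'
#' The default `gamma_B = -2.5` is sized (by the analytic standard error of
#' the between-level interaction at the default trial size) to give roughly
#' 80% power for the contextual test.
#'
#' @param gamma_B Between-level moderation coefficient.
#' @param ... Passed to [trial_scenario()].
#' @return An `hcp_scenario`.
#' @export
scenario_contextual_paradox <- function(gamma_B = -2.5, ...) {
  trial_scenario(gamma_B = gamma_B, ...)
}

#' Scenario with a planted individual-level paradox
#'
#' The default `d = -0.6` is sized (by the analytic standard error of the
#' cross-level slope moderation at the default trial size) to give roughly
#' 80% power or more for the individual-level test.
#'
#' @param d Within-slope moderation coefficient.
#' @param ... Passed to [trial_scenario()].
#' @return An `hcp_scenario`.
#' @export
scenario_individual_paradox <- function(d = -0.6, ...) {
  trial_scenario(d = d, ...)
}

## 2x2 (or degenerate) multivariate normal draw, tolerant of singular and
## zero covariance matrices.
rmvnorm2 <- function(n, Sigma) {
  eg <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Zm <- matrix(rnorm(n * 2), n, 2)
  Zm %*% (t(eg$vectors) * sqrt(lam))
}

#' Generate a synthetic two-level trial
#'
#' Draws one dataset from the generative model described in
#' [trial_scenario()]. Deterministic given `seed` (same scenario and seed
#' give byte-identical datasets).
#'
#' @param scenario An `hcp_scenario`.
#' @param seed Integer seed.
#' @return A `trial_data` tibble with columns `cluster`, `treatment`,
#'   `mediator`, `outcome`, carrying the default direction flags.
#' @examples
#' dat <- generate_trial(trial_scenario(J = 8, n_per_cluster = 30), seed = 1)
#' cluster_summaries(dat)
#' @export
generate_trial <- function(scenario, seed) {
  stopifnot(inherits(scenario, "hcp_scenario"))
  validate_scenario(scenario)
  set.seed(as.integer(seed))
  sc <- scenario
  J <- sc$J
  n_treat <- max(1, round(J * sc$allocation))
  trt <- numeric(J)
  trt[sample.int(J, n_treat)] <- 1
  nj <- if (length(sc$n_per_cluster) == 1) rep(sc$n_per_cluster, J) else
    sc$n_per_cluster[1] +
      sample.int(sc$n_per_cluster[2] - sc$n_per_cluster[1] + 1, J,
                 replace = TRUE) - 1

  uM <- rnorm(J, 0, sqrt(sc$tau2_M))
  muM <- sc$alpha0 + sc$a * trt + uM
  re <- rmvnorm2(J, matrix(c(sc$tau2_0, sc$tau01, sc$tau01, sc$tau2_1), 2, 2))
  uY <- re[, 1]; sj <- re[, 2]

  cl_idx <- rep(seq_len(J), nj)
  N <- sum(nj)
  eM <- rnorm(N, 0, sqrt(sc$sigma2_M))
  eY <- rnorm(N, 0, sqrt(sc$sigma2))
  m <- muM[cl_idx] + eM
  between_slope <- sc$b_b + sc$b_w + sc$gamma_B * trt
  within_slope <- sc$b_w + sc$d * trt + sj
  y <- sc$beta0 + sc$c_prime * trt[cl_idx] +
    between_slope[cl_idx] * muM[cl_idx] +
    within_slope[cl_idx] * eM + uY[cl_idx] + eY

  out <- tibble(
    cluster = sprintf("school_%03d", cl_idx),
    treatment = trt[cl_idx],
    mediator = m,
    outcome = y
  )
  structure(out,
            class = c("trial_data", class(tibble())),
            directions = list(mediator_higher_is_worse = TRUE,
                              outcome_higher_is_better = TRUE),
            n_dropped = 0L,
            treatment_map = NULL)
}

#' Type-I error / power of the two paradox tests by Monte Carlo
#'
#' Repeatedly generates trials from `scenario` (replicate r uses seed
#' `seed + r`, so any replicate is reproducible in isolation), applies the
#' contextual test ([fit_test1()]) and the individual-level test
#' ([fit_test2()]), and reports rejection rates of the moderation
#' coefficients at level `alpha`, with binomial Monte-Carlo standard
#' errors, plus the rate of `paradox_supported` classifications.
#' Replicates whose fit fails or does not converge are excluded from the
#' denominators and counted.
#'
#' @param scenario An `hcp_scenario`.
#' @param n_reps Number of Monte-Carlo replicates (>= 1; rates from fewer
#'   than 100 replicates trigger a warning).
#' @param alpha Two-sided significance level (rejection is `p <= alpha`).
#' @param seed Base seed.
#' @param control [lmm_control()] settings passed to the fits.
#' @param progress Print a progress line every 100 replicates.
#' @return An object of class `hcp_oc`: a tibble with one row per test
#'   (`test`, `n_used`, `rejections`, `rejection_rate`, `mc_se`,
#'   `paradox_supported_rate`), with the scenario, `alpha`, `n_reps` and
#'   failure count attached as attributes.
#' @examples
#' \donttest{
#' oc <- operating_characteristics(trial_scenario(J = 12, n_per_cluster = 20),
#'                                 n_reps = 100, seed = 1)
#' }
#' @export
operating_characteristics <- function(scenario, n_reps, alpha = 0.05,
                                      seed = 1, control = lmm_control(),
                                      progress = FALSE) {
  stopifnot(inherits(scenario, "hcp_scenario"))
  if (!is.numeric(n_reps) || n_reps < 1) {
    abort("`n_reps` must be a positive integer.", class = "hcp_config_error")
  }
  if (n_reps < 100) {
    warn("Fewer than 100 replicates: reported rates will be unstable.")
  }
  res <- matrix(NA, nrow = n_reps, ncol = 4,
                dimnames = list(NULL, c("rej1", "par1", "rej2", "par2")))
  failures <- 0L
  for (r in seq_len(n_reps)) {
    dat <- generate_trial(scenario, seed = seed + r)
    one <- tryCatch({
      t1 <- suppressWarnings(fit_test1(dat, alpha = alpha, control = control))
      t2 <- suppressWarnings(fit_test2(dat, alpha = alpha, control = control))
      ok <- t1$fit$convergence$converged && t2$fit$convergence$converged
      if (!ok) NULL else
        c(t1$moderation$p.value <= alpha,
          t1$classification == "paradox_supported",
          t2$moderation$p.value <= alpha,
          t2$classification == "paradox_supported")
    }, error = function(e) NULL)
    if (is.null(one)) failures <- failures + 1L else res[r, ] <- one
    if (progress && r %% 100 == 0) {
      inform(paste0("replicate ", r, "/", n_reps))
    }
  }
  if (failures > 0.2 * n_reps) {
    warn(paste0("Convergence failures in ", failures, "/", n_reps,
                " replicates (> 20%); rates may be unreliable."))
  }
  used <- sum(!is.na(res[, 1]))
  rate <- function(col) mean(res[, col], na.rm = TRUE)
  tab <- tibble(
    test = c("contextual (Test 1)", "individual (Test 2)"),
    n_used = used,
    rejections = c(sum(res[, "rej1"], na.rm = TRUE),
                   sum(res[, "rej2"], na.rm = TRUE)),
    rejection_rate = c(rate("rej1"), rate("rej2")),
    mc_se = sqrt(c(rate("rej1") * (1 - rate("rej1")),
                   rate("rej2") * (1 - rate("rej2"))) / used),
    paradox_supported_rate = c(rate("par1"), rate("par2"))
  )
  structure(tab,
            class = c("hcp_oc", class(tibble())),
            scenario = scenario, alpha = alpha, n_reps = n_reps,
            failures = failures, seed = seed)
}

#' Read / write scenario files
#'
#' Scenarios serialise to YAML (or JSON, by extension) so simulation runs
#' can be configured from files.
#'
#' @param scenario An `hcp_scenario`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns an `hcp_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "hcp_scenario"))
  x <- unclass(scenario)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Scenario file not found: ", path), class = "hcp_config_error")
  }
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(trial_scenario, x)
}
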