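#' Control parameters for the mixed-model optimiser
#'
#' @param maxit Maximum optimiser iterations.
#' @param reltol Relative tolerance for the objective in [stats::optim()].
#' @param grad_tol Relative gradient-norm threshold below which a fit is
#'   declared converged.
#' @param par_tol Parameter-change threshold for the Nelder-Mead polish step.
#' @param df_method `"between-within"` (default) for small-sample t
#'   reference degrees of freedom on single fixed coefficients, or
#'   `"normal"` for Wald z p-values.
#' @return A list of class `hcp_lmm_control`.
#' @export
lmm_control <- function(maxit = 500, reltol = 1e-12, grad_tol = 1e-6,
                        par_tol = 1e-8,
                        df_method = c("between-within", "normal")) {
  structure(list(maxit = maxit, reltol = reltol, grad_tol = grad_tol,
                 par_tol = par_tol, df_method = match.arg(df_method)),
            class = "hcp_lmm_control")
}

## Sufficient statistics for the two-level Gaussian likelihood. Every
## likelihood evaluation is a few dense operations on J-row matrices, so the
## cost is independent of the number of individuals after this step.
## Z = [1] (intercept only) or [1, s] (random slope on s).
lmm_suffstats <- function(X, y, s, cluster) {
  f <- factor(cluster)
  nj <- as.numeric(table(f))
  out <- list(
    N = length(y), J = nlevels(f), p = ncol(X),
    q = if (is.null(s)) 1L else 2L,
    nj = nj,
    XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y * y),
    U = rowsum(X, f), zy1 = drop(rowsum(y, f)),
    clusters = levels(f)
  )
  if (!is.null(s)) {
    out$W <- rowsum(X * s, f)
    out$zy2 <- drop(rowsum(s * y, f))
    out$q12 <- drop(rowsum(s, f))
    out$q22 <- drop(rowsum(s * s, f))
  }
  out
}

## Core of the marginal likelihood for unit residual variance and
## random-effects ratio matrix Gr = G / sigma2. Returns the GLS normal
## equations (A, b), the y quadratic, and the log-determinant correction,
## all under V_unit = I + Z Gr Z'. Uses the Woodbury identity with
## closed-form 2x2 inverses, vectorised over clusters.
lmm_core <- function(Gr, ss) {
  if (ss$q == 1) {
    g <- Gr[1, 1]
    m <- 1 + g * ss$nj
    if (any(!is.finite(m)) || any(m <= 0)) return(NULL)
    w <- g / m
    list(A = ss$XtX - crossprod(ss$U, ss$U * w),
         b = ss$Xty - drop(crossprod(ss$U, ss$zy1 * w)),
         yy = ss$yty - sum(ss$zy1^2 * w),
         ldet = sum(log(m)))
  } else {
    g11 <- Gr[1, 1]; g12 <- Gr[1, 2]; g22 <- Gr[2, 2]
    q11 <- ss$nj; q12 <- ss$q12; q22 <- ss$q22
    ## M = I + Gr Q per cluster (2x2, vectorised entries)
    m11 <- 1 + g11 * q11 + g12 * q12
    m12 <- g11 * q12 + g12 * q22
    m21 <- g12 * q11 + g22 * q12
    m22 <- 1 + g12 * q12 + g22 * q22
    dM <- m11 * m22 - m12 * m21
    if (any(!is.finite(dM)) || any(dM <= 0)) return(NULL)
    ## C = M^{-1} Gr (symmetric in exact arithmetic)
    C11 <- (m22 * g11 - m12 * g12) / dM
    C22 <- (m11 * g22 - m21 * g12) / dM
    C12 <- ((m22 * g12 - m12 * g22) + (m11 * g12 - m21 * g11)) / (2 * dM)
    U <- ss$U; W <- ss$W; z1 <- ss$zy1; z2 <- ss$zy2
    A <- ss$XtX - (crossprod(U, U * C11) + crossprod(U, W * C12) +
                     crossprod(W, U * C12) + crossprod(W, W * C22))
    b <- ss$Xty - drop(crossprod(U, C11 * z1 + C12 * z2) +
                         crossprod(W, C12 * z1 + C22 * z2))
    yy <- ss$yty - sum(C11 * z1^2 + 2 * C12 * z1 * z2 + C22 * z2^2)
    list(A = A, b = b, yy = yy, ldet = sum(log(dM)))
  }
}

## Profiled negative log-likelihood: beta by GLS and sigma2 in closed form,
## leaving only the variance-ratio parameters to the optimiser.
lmm_nll_profiled <- function(Gr, ss) {
  core <- lmm_core(Gr, ss)
  if (is.null(core)) return(list(nll = 1e10))
  beta <- tryCatch(solve(core$A, core$b), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = 1e10))
  quad <- core$yy - sum(core$b * beta)
  if (!is.finite(quad) || quad <= 0) return(list(nll = 1e10))
  sigma2 <- quad / ss$N
  nll <- 0.5 * (ss$N * log(2 * pi) + ss$N * log(sigma2) + core$ldet + ss$N)
  list(nll = nll, beta = drop(beta), sigma2 = sigma2)
}

## Unprofiled negative log-likelihood on the natural scale
## theta = (beta, sigma2, tau0 [, tau1, tau01]); used for the observed
## information. Near the tau1 = 0 boundary this is evaluated by analytic
## continuation (the Woodbury form stays finite for slightly negative tau1),
## so central finite differences remain well defined.
lmm_nll_natural <- function(theta, ss, has_slope, has_cov) {
  p <- ss$p
  beta <- theta[seq_len(p)]
  sigma2 <- theta[p + 1]
  if (!is.finite(sigma2) || sigma2 <= 0) return(1e10)
  Gr <- if (has_slope) {
    tau01 <- if (has_cov) theta[p + 4] else 0
    matrix(c(theta[p + 2], tau01, tau01, theta[p + 3]), 2, 2) / sigma2
  } else {
    matrix(theta[p + 2], 1, 1) / sigma2
  }
  core <- lmm_core(Gr, ss)
  if (is.null(core)) return(1e10)
  quad <- (core$yy - 2 * sum(core$b * beta) +
             drop(crossprod(beta, core$A %*% beta))) / sigma2
  nll <- 0.5 * (ss$N * log(2 * pi) + ss$N * log(sigma2) + core$ldet + quad)
  if (!is.finite(nll)) return(1e10)
  nll
}

## Unconstrained optimiser scale -> ratio matrix Gr = G/sigma2.
## Log-Cholesky: every iterate maps to a valid covariance matrix.
lmm_phi_to_Gr <- function(phi, has_slope, has_cov) {
  if (!has_slope) return(matrix(exp(2 * phi[1]), 1, 1))
  if (has_cov) {
    L <- matrix(c(exp(phi[1]), phi[2], 0, exp(phi[3])), 2, 2)
    tcrossprod(L)
  } else {
    diag(c(exp(2 * phi[1]), exp(2 * phi[2])), 2)
  }
}

#' Fit a Gaussian linear mixed model by maximum likelihood
#'
#' Fits a two-level Gaussian linear mixed model with a cluster random
#' intercept and, optionally, a cluster random slope on one individual-level
#' variable (with or without a slope-intercept covariance), by maximising
#' the marginal log-likelihood (ML, not REML). The fixed-effect vector and
#' the residual variance are profiled out; the remaining variance-ratio
#' parameters are optimised on an unconstrained log-Cholesky scale so every
#' iterate maps to a valid covariance matrix. The parameter covariance is
#' the inverse observed information (numerical Hessian of the full
#' likelihood on the natural scale), computed jointly over fixed effects and
#' variance components — which is what permits Wald tests that constrain
#' variance components alongside fixed effects.
#'
#' Single-coefficient p-values reported by [tidy()] use a t reference whose
#' denominator degrees of freedom follow the between-within convention:
#' cluster-level terms are tested against `J - (number of cluster-level
#' terms)`, terms belonging to the random-slope model against `J - (number
#' of slope-model terms)`, and remaining individual-level terms against
#' `N - J - (number of within terms)`; reported standard errors carry the
#' matching REML-style rescaling `sqrt(m/(m - p))` at the term's level,
#' compensating the downward bias of ML variance components. Set
#' `df_method = "normal"` in [lmm_control()] for plain observed-information
#' Wald z p-values without either correction.
#'
#' @param data A data frame (typically a `trial_data` tibble, possibly
#'   augmented by [center_within_cluster()]).
#' @param fixed Two-sided formula for the fixed effects, e.g.
#'   `outcome ~ mediator + mediator_cluster_mean + treatment`.
#' @param cluster Name of the cluster-identifier column.
#' @param random_slope Name of an individual-level column receiving a
#'   cluster random slope, or `NULL` for a random intercept only.
#' @param cov_slope_intercept Estimate the slope-intercept covariance
#'   (ignored when `random_slope` is `NULL`).
#' @param control A [lmm_control()] list.
#'
#' @return An object of class `hcp_lmm` with components `beta` (named fixed
#'   estimates), `vc` (variance components `sigma2`, `tau0`, and with a
#'   slope `tau1`, `tau01`), `loglik`, `vcov` (joint parameter covariance),
#'   `df_fixed`, and a `convergence` block (status, iterations, relative
#'   gradient norm, boundary flags). Methods: [tidy()], [glance()],
#'   `print()`, [wald_test()].
#' @examples
#' sc <- trial_scenario(J = 12, n_per_cluster = 20)
#' dat <- generate_trial(sc, seed = 1)
#' fit <- fit_lmm(dat, outcome ~ mediator + treatment)
#' tidy(fit)
#' @export
fit_lmm <- function(data, fixed, cluster = "cluster", random_slope = NULL,
                    cov_slope_intercept = TRUE, control = lmm_control()) {
  mf <- model.frame(fixed, data = data, na.action = stats::na.fail)
  X <- model.matrix(fixed, mf)
  y <- as.numeric(model.response(mf))
  cl <- as.character(data[[cluster]])
  if (length(cl) != length(y)) {
    abort("`cluster` column must align with the model frame (no missing values allowed).")
  }
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("Fixed-effect design is rank deficient; collinear term(s): ",
                 paste(drop_cols, collapse = ", ")),
          class = "hcp_rank_error")
  }
  has_slope <- !is.null(random_slope)
  has_cov <- has_slope && isTRUE(cov_slope_intercept)
  if (has_slope && !random_slope %in% names(data)) {
    abort(paste0("random_slope column not found: ", random_slope))
  }
  s <- if (has_slope) as.numeric(data[[random_slope]]) else NULL

  ss <- lmm_suffstats(X, y, s, cl)
  all_singletons <- max(ss$nj) == 1

  obj <- function(phi) lmm_nll_profiled(lmm_phi_to_Gr(phi, has_slope, has_cov), ss)$nll

  ## The profiled likelihood is flat in log(tau0/sigma2) as tau0 -> 0, so
  ## gradient methods started on the steep side can overshoot past an
  ## interior optimum into the flat boundary region. The intercept ratio is
  ## therefore located by a coarse grid + golden-section refinement; slope
  ## models start from that solution and refine by Nelder-Mead then BFGS.
  grid <- seq(-9, 3, length.out = 25)
  ss1 <- ss; ss1$q <- 1L
  obj1 <- function(ph) lmm_nll_profiled(matrix(exp(2 * ph), 1, 1), ss1)$nll
  v1 <- vapply(grid, obj1, numeric(1))
  b <- which.min(v1)
  o1 <- stats::optimize(obj1, lower = grid[max(1, b - 1)],
                        upper = grid[min(length(grid), b + 1)], tol = 1e-10)
  if (!has_slope) {
    opt <- list(par = o1$minimum, value = o1$objective, convergence = 0,
                counts = c(`function` = length(grid) + 35, gradient = NA))
    par_change <- 0
  } else {
    phi0 <- if (has_cov)
      c(o1$minimum, 0, log(0.1 / max(sd(s), 1e-8))) else
        c(o1$minimum, log(0.1 / max(sd(s), 1e-8)))
    opt <- stats::optim(phi0, obj, method = "Nelder-Mead",
                        control = list(maxit = max(control$maxit, 2000),
                                       reltol = control$reltol))
    opt2 <- stats::optim(opt$par, obj, method = "BFGS",
                         control = list(maxit = control$maxit,
                                        reltol = control$reltol))
    par_change <- max(abs(opt2$par - opt$par))
    if (opt2$value < opt$value) {
      opt2$counts <- opt$counts + opt2$counts
      opt <- opt2
    }
  }

  Gr <- lmm_phi_to_Gr(opt$par, has_slope, has_cov)
  prof <- lmm_nll_profiled(Gr, ss)
  beta <- setNames(prof$beta, colnames(X))
  sigma2 <- prof$sigma2
  G <- Gr * sigma2
  vc <- c(sigma2 = sigma2, tau0 = G[1, 1])
  if (has_slope) vc <- c(vc, tau1 = G[2, 2], tau01 = G[1, 2])

  theta <- c(beta, vc)
  nll_nat <- function(th) lmm_nll_natural(th, ss, has_slope, has_cov)
  H <- pracma::hessian(nll_nat, theta)
  par_names <- c(colnames(X), names(vc))
  dimnames(H) <- list(par_names, par_names)
  ## Invert through the eigendecomposition. At a variance-component
  ## boundary the observed information can have a non-positive direction
  ## (the likelihood is locally a saddle in the continued parameter); the
  ## magnitudes are kept (absolute values, floored relative to the largest)
  ## so the covariance is always symmetric PSD, and the fit records that
  ## the information was not positive definite.
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  covariance_ok <- all(is.finite(eg$values)) && min(eg$values) > 0
  lam <- pmax(abs(eg$values), max(abs(eg$values)) * 1e-10)
  Vcov <- eg$vectors %*% (t(eg$vectors) / lam)
  Vcov <- (Vcov + t(Vcov)) / 2
  dimnames(Vcov) <- list(par_names, par_names)

  ## convergence is judged on the unconstrained optimiser scale: at a
  ## variance boundary (tau -> 0) the natural-scale gradient need not
  ## vanish, but the log-scale gradient does
  gr <- pracma::grad(obj, opt$par)
  grad_rel <- sqrt(sum(gr^2)) / (1 + abs(opt$value))
  vy <- var(y)
  boundary <- character(0)
  if (all_singletons) boundary <- c(boundary,
    "no cluster has >= 2 members: intercept variance and residual variance are not separately identified")
  if (vc[["tau0"]] < 1e-8 * vy) boundary <- c(boundary, "tau0 at boundary (~0)")
  if (has_slope && vc[["tau1"]] < 1e-8 * vy / max(var(s), 1e-12))
    boundary <- c(boundary, "tau1 at boundary (~0)")
  if (!covariance_ok)
    boundary <- c(boundary,
      "observed information not positive definite (variance component at or near its boundary)")

  dfinfo <- lmm_fixed_df(X, fixed, cl, random_slope, ss, data)
  converged <- opt$convergence == 0 && !all_singletons &&
    (grad_rel < control$grad_tol * 100 || par_change < control$par_tol * 1e3)
  if (!converged && !all_singletons && grad_rel > 1e-2) {
    warn(paste0("Mixed-model fit may not have converged (relative gradient norm ",
                signif(grad_rel, 3), ")."))
  }

  structure(list(
    beta = beta,
    vc = vc,
    loglik = -opt$value,
    vcov = Vcov,
    fixed = fixed,
    random_slope = random_slope,
    cov_slope_intercept = has_cov,
    df_fixed = dfinfo$df,
    se_scale = dfinfo$se_scale,
    df_method = control$df_method,
    N = ss$N, J = ss$J, p = p,
    convergence = list(converged = converged,
                       optim_status = opt$convergence,
                       iterations = unname(opt$counts[1]),
                       grad_norm_rel = grad_rel,
                       par_change = par_change,
                       boundary = boundary,
                       covariance_ok = covariance_ok)
  ), class = "hcp_lmm")
}

## Between-within style denominator degrees of freedom (HLM convention).
lmm_fixed_df <- function(X, fixed, cl, random_slope, ss, data) {
  assign <- attr(X, "assign")
  labels <- attr(terms(fixed), "term.labels")
  vars <- all.vars(stats::delete.response(terms(fixed)))
  ## a variable is cluster-level if constant within every cluster
  cls <- vapply(vars, function(v) {
    x <- data[[v]]
    if (is.null(x) || !is.numeric(x)) return(FALSE)
    all(tapply(as.numeric(x), cl, function(z) max(z) - min(z)) < 1e-10)
  }, logical(1))
  col_class <- vapply(seq_len(ncol(X)), function(k) {
    a <- assign[k]
    if (a == 0) return("between")
    tv <- all.vars(str2lang(labels[a]))
    if (!is.null(random_slope) && random_slope %in% tv) return("slope")
    if (all(cls[tv])) "between" else "within"
  }, character(1))
  nb <- sum(col_class == "between")
  nsl <- sum(col_class == "slope")
  nw <- sum(col_class == "within")
  df <- vapply(col_class, function(cc) {
    switch(cc,
           between = max(1, ss$J - nb),
           slope = max(1, ss$J - nsl),
           within = max(1, ss$N - ss$J - nw))
  }, numeric(1))
  ## ML variance components divide by the number of units at their level,
  ## not by units minus estimated coefficients, so standard errors of terms
  ## living at that level are biased low by sqrt((m - p)/m); the reported
  ## SEs are rescaled by the level-appropriate REML-style factor.
  se_scale <- vapply(col_class, function(cc) {
    switch(cc,
           between = sqrt(ss$J / max(1, ss$J - nb)),
           slope = sqrt(ss$J / max(1, ss$J - nsl)),
           within = sqrt(ss$N / max(1, ss$N - ss$J - nw)))
  }, numeric(1))
  list(df = setNames(df, colnames(X)),
       se_scale = setNames(se_scale, colnames(X)))
}

#' @export
print.hcp_lmm <- function(x, ...) {
  cat("Gaussian linear mixed model (ML)\n")
  cat("  ", x$N, "individuals in", x$J, "clusters; logLik =",
      format(x$loglik, digits = 8), "\n")
  cat("  Random effects: intercept",
      if (!is.null(x$random_slope))
        paste0("+ slope on ", x$random_slope,
               if (x$cov_slope_intercept) " (with covariance)" else ""),
      "\n")
  print(tidy(x), n = Inf)
  cat("Variance components:\n")
  print(round(x$vc, 5))
  if (!x$convergence$converged) cat("NOTE: fit flagged as not converged.\n")
  if (length(x$convergence$boundary))
    cat("Boundary:", paste(x$convergence$boundary, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a fitted mixed model
#'
#' @param x An `hcp_lmm` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `term`, `estimate`,
#'   `std.error`, `statistic`, `df`, `p.value`.
#' @method tidy hcp_lmm
#' @export
tidy.hcp_lmm <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov)[seq_along(x$beta)], 0))
  ## small-sample inference applies the level-wise REML-style SE rescaling;
  ## the plain normal-reference option reports raw observed-information SEs
  if (x$df_method == "between-within") se <- se * x$se_scale
  stat <- x$beta / se
  df <- x$df_fixed
  p <- if (x$df_method == "normal") 2 * pnorm(-abs(stat)) else
    2 * pt(-abs(stat), df = df)
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(se), statistic = unname(stat),
         df = if (x$df_method == "normal") Inf else unname(df),
         p.value = unname(p))
}

#' One-line fit summary
#'
#' @param x An `hcp_lmm` object.
#' @param ... Unused.
#' @return A one-row tibble: log-likelihood, AIC, variance components,
#'   sizes, convergence flag.
#' @method glance hcp_lmm
#' @export
glance.hcp_lmm <- function(x, ...) {
  k <- length(x$beta) + length(x$vc)
  tibble(logLik = x$loglik, AIC = -2 * x$loglik + 2 * k,
         sigma2 = unname(x$vc["sigma2"]), tau0 = unname(x$vc["tau0"]),
         tau1 = if ("tau1" %in% names(x$vc)) unname(x$vc["tau1"]) else NA_real_,
         tau01 = if ("tau01" %in% names(x$vc)) unname(x$vc["tau01"]) else NA_real_,
         nobs = x$N, n_clusters = x$J,
         converged = x$convergence$converged)
}

#' Wald test on a subset of model parameters
#'
#' Tests the joint null that the named parameters are zero, using the
#' corresponding block of the joint observed-information covariance:
#' `statistic = est' V_block^{-1} est`, referred to a chi-square with df
#' equal to the number of constrained parameters. Parameters may be fixed
#' effects (by term label) and/or variance components (`"tau1"`,
#' `"tau01"`), which is how the nested-model comparisons of the two
#' healthy-context-paradox tests are computed. Testing a variance component
#' at the boundary of its parameter space against a plain chi-square
#' reference is non-standard; when variance components are constrained the
#' result carries a caveat.
#'
#' @param fit An `hcp_lmm` fit (the FULL model).
#' @param terms Character vector of parameter names (rows of `fit$vcov`).
#' @return An `hcp_wald` object with `statistic`, `df`, `p.value`,
#'   `terms`, `caveat`.
#' @examples
#' sc <- trial_scenario(J = 12, n_per_cluster = 20)
#' dat <- generate_trial(sc, seed = 1)
#' fit <- fit_lmm(dat, outcome ~ mediator + treatment)
#' wald_test(fit, "treatment")
#' @export
wald_test <- function(fit, terms) {
  stopifnot(inherits(fit, "hcp_lmm"), length(terms) >= 1)
  par_names <- rownames(fit$vcov)
  missing_t <- setdiff(terms, par_names)
  if (length(missing_t) > 0) {
    abort(paste0("Unknown parameter(s): ", paste(missing_t, collapse = ", ")))
  }
  est <- c(fit$beta, fit$vc)
  v <- est[terms]
  Vb <- fit$vcov[terms, terms, drop = FALSE]
  rc <- rcond(Vb)
  if (!is.finite(rc) || rc < 1e-12) {
    abort(paste0("Covariance block for (", paste(terms, collapse = ", "),
                 ") is numerically singular; consider re-parameterising the model."),
          class = "hcp_singular_error")
  }
  stat <- drop(crossprod(v, solve(Vb, v)))
  df <- length(terms)
  caveat <- NULL
  vc_terms <- intersect(terms, c("tau0", "tau1", "tau01"))
  if (length(vc_terms) > 0) {
    caveat <- paste0(
      "Wald test constrains variance component(s) ",
      paste(vc_terms, collapse = ", "),
      "; the chi-square reference is non-standard at the boundary of the parameter space.")
    if (length(fit$convergence$boundary) > 0) {
      caveat <- paste(caveat, "The fit reports:",
                      paste(fit$convergence$boundary, collapse = "; "))
    }
  }
  structure(list(statistic = max(0, stat), df = df,
                 p.value = pchisq(max(0, stat), df = df, lower.tail = FALSE),
                 terms = terms, caveat = caveat),
            class = "hcp_wald")
}

#' @export
print.hcp_wald <- function(x, ...) {
  cat("Wald test on:", paste(x$terms, collapse = ", "), "\n")
  cat("  chi-square =", format(x$statistic, digits = 5),
      " df =", x$df, " p =", format.pval(x$p.value, digits = 3), "\n")
  if (!is.null(x$caveat)) cat("  Caveat:", x$caveat, "\n")
  invisible(x)
}

#' @method tidy hcp_wald
#' @export
tidy.hcp_wald <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         terms = paste(x$terms, collapse = ", "))
}

#' Serialise a fitted mixed model to JSON
#'
#' @param fit An `hcp_lmm` object.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
lmm_to_json <- function(fit, path = NULL) {
  payload <- list(
    fixed_estimates = as.list(fit$beta),
    std_errors = as.list(setNames(sqrt(pmax(diag(fit$vcov)[seq_along(fit$beta)], 0)),
                                  names(fit$beta))),
    variance_components = as.list(fit$vc),
    loglik = fit$loglik,
    parameter_covariance = fit$vcov,
    convergence = fit$convergence,
    n = fit$N, n_clusters = fit$J
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
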