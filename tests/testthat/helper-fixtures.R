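# Shared fixtures: tiny scenarios and an independent dense-likelihood oracle.

tiny_scenario <- function(...) {
  trial_scenario(J = 8, n_per_cluster = 15, ...)
}

small_scenario <- function(...) {
  trial_scenario(J = 20, n_per_cluster = 40, ...)
}

# A 4-cluster toy table (2 per arm, 3 members each) with known values.
toy_trial_df <- function() {
  data.frame(
    cluster = rep(c("A", "B", "C", "D"), each = 3),
    treatment = rep(c(0, 0, 1, 1), each = 3),
    mediator = c(1, 2, 3, 2, 4, 6, 1, 1, 4, 0, 5, 7),
    outcome = c(5, 4, 3, 6, 2, 1, 7, 6, 2, 8, 3, 1)
  )
}

write_toy_csv <- function(df = toy_trial_df()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Independent oracle: stacked multivariate-normal log-density evaluated
# through the full N x N covariance matrix (no Woodbury, no profiling).
oracle_loglik <- function(data, fixed, beta, vc, random_slope = NULL) {
  X <- model.matrix(fixed, model.frame(fixed, data))
  y <- as.numeric(model.response(model.frame(fixed, data)))
  N <- length(y)
  G <- if (is.null(random_slope)) {
    matrix(vc[["tau0"]], 1, 1)
  } else {
    matrix(c(vc[["tau0"]], vc[["tau01"]], vc[["tau01"]], vc[["tau1"]]), 2, 2)
  }
  V <- diag(vc[["sigma2"]], N)
  for (cl in unique(data$cluster)) {
    i <- which(data$cluster == cl)
    Z <- if (is.null(random_slope)) matrix(1, length(i), 1) else
      cbind(1, as.numeric(data[[random_slope]][i]))
    V[i, i] <- V[i, i] + Z %*% G %*% t(Z)
  }
  r <- y - drop(X %*% beta)
  ch <- chol(V)
  -0.5 * (N * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# Pooled within-cluster variance (moment estimator).
vw_est <- function(dat) {
  devs <- dat$outcome - stats::ave(dat$outcome, dat$cluster)
  sum(devs^2) / (nrow(dat) - length(unique(dat$cluster)))
}
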