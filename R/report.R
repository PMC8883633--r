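#' Analysis configuration
#'
#' Bundles every setting of the full analysis pipeline with defaults, so a
#' run is reproducible from the config alone. Round-trips through YAML/JSON
#' via [write_config()] / [read_config()].
#'
#' @param columns Named list mapping the standard roles (`cluster`,
#'   `treatment`, `mediator`, `outcome`) to input column names.
#' @param mediator_higher_is_worse,outcome_higher_is_better Direction flags.
#' @param alpha Two-sided significance level.
#' @param mc_draws Monte-Carlo draws for indirect-effect intervals.
#' @param seed Seed for the Monte-Carlo interval draws.
#' @param df_method Degrees-of-freedom method, see [lmm_control()].
#' @param grad_tol,reltol Optimiser tolerances, see [lmm_control()].
#' @return A list of class `hcp_config`.
#' @export
hcp_config <- function(columns = list(cluster = "cluster",
                                      treatment = "treatment",
                                      mediator = "mediator",
                                      outcome = "outcome"),
                       mediator_higher_is_worse = TRUE,
                       outcome_higher_is_better = TRUE,
                       alpha = 0.05, mc_draws = 10000, seed = 1,
                       df_method = "between-within",
                       grad_tol = 1e-6, reltol = 1e-12) {
  structure(list(columns = columns,
                 mediator_higher_is_worse = mediator_higher_is_worse,
                 outcome_higher_is_better = outcome_higher_is_better,
                 alpha = alpha, mc_draws = mc_draws, seed = seed,
                 df_method = df_method, grad_tol = grad_tol,
                 reltol = reltol),
            class = "hcp_config")
}

#' @rdname hcp_config
#' @param config An `hcp_config`.
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname hcp_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "hcp_config_error")
  }
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(x$columns)) x$columns <- as.list(x$columns)
  do.call(hcp_config, x)
}

config_control <- function(config) {
  lmm_control(df_method = config$df_method, grad_tol = config$grad_tol,
              reltol = config$reltol)
}

#' Run the full healthy-context-paradox analysis
#'
#' Fits the baseline 2-1-1 mediation model, the contextual-level test
#' ([fit_test1()]) and the individual-level test ([fit_test2()]) on one
#' dataset, returning everything needed for a report. Both tests are always
#' reported: the contextual test speaks to differences *between*
#' intervention and control clusters, the individual test to differences
#' *within* intervention clusters, and neither subsumes the other.
#'
#' @param data A `trial_data` tibble, or a path to a CSV file (read with
#'   the column map in `config`).
#' @param config An [hcp_config()].
#' @return An object of class `hcp_report`: `mediation` (`hcp_mediation`),
#'   `test1`, `test2` (`hcp_test`), the `config`, and a `provenance` block
#'   (package version, seed, config fingerprint, input fingerprint).
#' @examples
#' dat <- generate_trial(trial_scenario(J = 12, n_per_cluster = 30), seed = 1)
#' rep <- run_hcp_analysis(dat)
#' glance(rep$test1)
#' @export
run_hcp_analysis <- function(data, config = hcp_config()) {
  if (is.character(data)) {
    data <- read_trial_csv(
      data,
      cluster = config$columns$cluster, treatment = config$columns$treatment,
      mediator = config$columns$mediator, outcome = config$columns$outcome,
      mediator_higher_is_worse = config$mediator_higher_is_worse,
      outcome_higher_is_better = config$outcome_higher_is_better)
  }
  stopifnot(inherits(data, "trial_data"))
  control <- config_control(config)
  mediation <- fit_baseline_mediation(data, alpha = config$alpha,
                                      mc_draws = config$mc_draws,
                                      mc_seed = config$seed,
                                      control = control)
  t1 <- fit_test1(data, alpha = config$alpha, control = control)
  t2 <- fit_test2(data, alpha = config$alpha, control = control)
  fingerprint <- function(x) {
    u <- unlist(x, use.names = TRUE)
    v <- utf8ToInt(paste(names(u), format(u, digits = 12), collapse = "|"))
    sum(v * seq_along(v)) %% 1e9
  }
  structure(list(
    mediation = mediation, test1 = t1, test2 = t2, config = config,
    provenance = list(
      package_version = as.character(utils::packageVersion("hcptest")),
      seed = config$seed,
      config_fingerprint = fingerprint(unclass(config)),
      input_fingerprint = fingerprint(list(
        n = nrow(data), clusters = length(unique(data$cluster)),
        mediator_sum = sum(data$mediator), outcome_sum = sum(data$outcome))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "hcp_report")
}

#' @export
print.hcp_report <- function(x, ...) {
  writeLines(report_text(x))
  invisible(x)
}

report_text <- function(report) {
  utils::capture.output({
    cat("==== Healthy context paradox analysis ====\n\n")
    print(report$mediation)
    cat("\n---- Test 1: contextual level ----\n")
    print(report$test1)
    cat("\n---- Test 2: individual level ----\n")
    print(report$test2)
    cat("\nProvenance: hcptest", report$provenance$package_version,
        "| seed", report$provenance$seed,
        "| config fingerprint", report$provenance$config_fingerprint,
        "| input fingerprint", report$provenance$input_fingerprint, "\n")
  })
}

wald_payload <- function(w) {
  list(statistic = w$statistic, df = w$df, p_value = w$p.value,
       constrained_terms = w$terms, caveat = w$caveat)
}

test_payload <- function(t) {
  out <- list(
    level = t$level,
    moderation = list(estimate = t$moderation$estimate,
                      std_error = t$moderation$std.error,
                      df = t$moderation$df,
                      p_value = t$moderation$p.value),
    wald_vs_baseline = wald_payload(t$wald_vs_baseline),
    classification = t$classification,
    direction_note = t$direction_note,
    convergence = t$fit$convergence
  )
  if (!is.null(t$wald_vs_reduced)) {
    out$wald_vs_reduced <- wald_payload(t$wald_vs_reduced)
    out$control_arm_slope <- list(estimate = t$control_arm_slope$estimate,
                                  std_error = t$control_arm_slope$std.error)
    out$between_sum_coefficient <- list(estimate = t$between_sum$estimate,
                                        std_error = t$between_sum$std.error)
  }
  out
}

#' Write a JSON + plain-text report
#'
#' @param report An `hcp_report` from [run_hcp_analysis()].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_hcp_report <- function(report, dir) {
  stopifnot(inherits(report, "hcp_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    mediation = list(
      paths = report$mediation$paths,
      indirect_effects = report$mediation$indirect,
      mediator_screen = report$mediation$mediator_screen
    ),
    test1 = test_payload(report$test1),
    test2 = test_payload(report$test2),
    config = unclass(report$config),
    provenance = report$provenance
  )
  json_path <- file.path(dir, "hcp_report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt_path <- file.path(dir, "hcp_report.txt")
  writeLines(report_text(report), txt_path)
  csv_path <- file.path(dir, "hcp_summary.csv")
  readr::write_csv(report_summary_row(report), csv_path, progress = FALSE)
  invisible(c(json = json_path, text = txt_path, csv = csv_path))
}

## one-row summary suitable for batch collation
report_summary_row <- function(report) {
  p <- report$mediation$paths
  g <- function(tt) p$estimate[p$term == tt]
  tibble(
    a = g("a"), b_within = g("b_within"), b_between = g("b_between"),
    c_prime = g("c_prime"),
    indirect_total = report$mediation$indirect$estimate[
      report$mediation$indirect$effect == "total"],
    screen_pass = report$mediation$mediator_screen$pass,
    test1_estimate = report$test1$moderation$estimate,
    test1_p = report$test1$moderation$p.value,
    test1_classification = report$test1$classification,
    test2_estimate = report$test2$moderation$estimate,
    test2_p = report$test2$moderation$p.value,
    test2_classification = report$test2$classification
  )
}

#' Simulate a trial to CSV with a provenance sidecar
#'
#' Wraps [generate_trial()]: writes the dataset as CSV plus a YAML sidecar
#' recording the scenario, seed and package version, sufficient to
#' regenerate the file exactly.
#'
#' @param scenario An `hcp_scenario` (or path to a scenario file).
#' @param seed Integer seed.
#' @param path Output CSV path.
#' @return The dataset, invisibly.
#' @export
simulate_trial_to_csv <- function(scenario, seed, path) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  dat <- generate_trial(scenario, seed = seed)
  write_trial_csv(dat, path)
  yaml::write_yaml(
    list(scenario = unclass(scenario), seed = as.integer(seed),
         package_version = as.character(utils::packageVersion("hcptest")),
         rows = nrow(dat)),
    paste0(path, ".provenance.yaml"))
  invisible(dat)
}

#' Run an operating-characteristics study and write results
#'
#' Wraps [operating_characteristics()], writing a JSON and a CSV version of
#' the rejection-rate table.
#'
#' @param scenario An `hcp_scenario` (or path to a scenario file).
#' @param n_reps Number of replicates.
#' @param alpha Significance level.
#' @param seed Base seed.
#' @param dir Output directory.
#' @param control [lmm_control()] settings.
#' @return The `hcp_oc` table, invisibly.
#' @export
run_power <- function(scenario, n_reps, alpha = 0.05, seed = 1, dir = ".",
                      control = lmm_control()) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  oc <- operating_characteristics(scenario, n_reps = n_reps, alpha = alpha,
                                  seed = seed, control = control)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    scenario = unclass(attr(oc, "scenario")),
    n_reps = attr(oc, "n_reps"), alpha = attr(oc, "alpha"),
    seed = attr(oc, "seed"), convergence_failures = attr(oc, "failures"),
    rates = as_tibble(oc)
  )
  jsonlite::write_json(payload, file.path(dir, "operating_characteristics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_csv(as_tibble(oc), file.path(dir, "operating_characteristics.csv"),
                   progress = FALSE)
  invisible(oc)
}
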