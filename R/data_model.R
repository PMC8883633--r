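#' Construct a validated two-level trial dataset
#'
#' Standardises a long-format data frame (one row per individual nested in a
#' cluster, with a cluster-level binary treatment, a continuous mediator and a
#' continuous outcome) into the tibble that every model-fitting function in
#' the package consumes. Rows with a missing cluster, treatment, mediator or
#' outcome are dropped (listwise deletion) and the count is reported with a
#' message; the treatment column is recoded to 0/1 with an explicit, reported
#' mapping when it is not already numeric 0/1.
#'
#' Direction flags record the orientation of the measurement scales: with the
#' defaults, higher mediator values are worse (e.g. bullying victimisation)
#' and higher outcome values are better (e.g. mental wellbeing). They do not
#' change any estimate; they drive the sign convention used by
#' [classify_hcp()] when interpreting moderation coefficients.
#'
#' @param data A data frame.
#' @param cluster,treatment,mediator,outcome Names of the corresponding
#'   columns in `data`.
#' @param mediator_higher_is_worse,outcome_higher_is_better Direction flags
#'   for the two measurement scales.
#' @param quiet Suppress the dropped-row / recoding messages.
#'
#' @return A tibble of class `trial_data` with columns `cluster` (character),
#'   `treatment` (0/1), `mediator`, `outcome`, and attributes
#'   `directions` (the two flags), `n_dropped`, and `treatment_map`.
#'
#' @examples
#' df <- data.frame(school = rep(c("a", "b", "c", "d"), each = 3),
#'                  arm = rep(c("control", "intervention"), each = 6),
#'                  bully = rnorm(12), wellbeing = rnorm(12))
#' td <- as_trial_data(df, cluster = "school", treatment = "arm",
#'                     mediator = "bully", outcome = "wellbeing")
#' @export
as_trial_data <- function(data,
                          cluster = "cluster",
                          treatment = "treatment",
                          mediator = "mediator",
                          outcome = "outcome",
                          mediator_higher_is_worse = TRUE,
                          outcome_higher_is_better = TRUE,
                          quiet = FALSE) {
  stopifnot(is.data.frame(data))
  cols <- c(cluster = cluster, treatment = treatment,
            mediator = mediator, outcome = outcome)
  missing_cols <- setdiff(unname(cols), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) not found in `data`: ",
                 paste(missing_cols, collapse = ", ")),
          class = "hcp_config_error")
  }
  out <- tibble(
    cluster = as.character(data[[cluster]]),
    treatment = data[[treatment]],
    mediator = as.numeric(data[[mediator]]),
    outcome = as.numeric(data[[outcome]])
  )

  treatment_map <- NULL
  tr <- out$treatment
  if (is.numeric(tr) && all(tr %in% c(0, 1, NA))) {
    out$treatment <- as.numeric(tr)
  } else {
    lev <- sort(unique(as.character(tr[!is.na(tr)])))
    if (length(lev) != 2) {
      abort(paste0("`treatment` must be two-valued; found ",
                   length(lev), " distinct values."),
            class = "hcp_validation_error")
    }
    treatment_map <- setNames(c(0, 1), lev)
    if (!quiet) {
      inform(paste0("Recoding treatment: '", lev[1], "' -> 0 (control), '",
                    lev[2], "' -> 1 (intervention)."))
    }
    out$treatment <- as.numeric(treatment_map[as.character(tr)])
  }

  keep <- complete.cases(out) & is.finite(out$mediator) &
    is.finite(out$outcome) & !is.na(out$cluster)
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    inform(paste0("Dropped ", n_dropped,
                  " row(s) with missing analysis variables (listwise deletion)."))
  }
  out <- out[keep, , drop = FALSE]

  validate_trial_data(out)

  structure(out,
            class = c("trial_data", class(tibble())),
            directions = list(
              mediator_higher_is_worse = isTRUE(mediator_higher_is_worse),
              outcome_higher_is_better = isTRUE(outcome_higher_is_better)
            ),
            n_dropped = n_dropped,
            treatment_map = treatment_map)
}

validate_trial_data <- function(data) {
  by_cl <- tapply(data$treatment, data$cluster, function(x) length(unique(x)))
  bad <- names(by_cl)[by_cl > 1]
  if (length(bad) > 0) {
    abort(paste0("Treatment varies within cluster(s): ",
                 paste(head(bad, 5), collapse = ", "),
                 ". Treatment must be allocated at the cluster level."),
          class = "hcp_validation_error")
  }
  arm <- tapply(data$treatment, data$cluster, function(x) x[1])
  if (sum(arm == 0) < 2 || sum(arm == 1) < 2) {
    abort("Need at least 2 clusters in each treatment arm.",
          class = "hcp_validation_error")
  }
  invisible(data)
}

#' Read a two-level trial dataset from CSV
#'
#' Thin wrapper around [readr::read_csv()] + [as_trial_data()].
#'
#' @inheritParams as_trial_data
#' @param path Path to a CSV file with one row per individual.
#' @return A `trial_data` tibble; see [as_trial_data()].
#' @export
read_trial_csv <- function(path,
                           cluster = "cluster",
                           treatment = "treatment",
                           mediator = "mediator",
                           outcome = "outcome",
                           mediator_higher_is_worse = TRUE,
                           outcome_higher_is_better = TRUE,
                           quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "hcp_config_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trial_data(raw, cluster = cluster, treatment = treatment,
                mediator = mediator, outcome = outcome,
                mediator_higher_is_worse = mediator_higher_is_worse,
                outcome_higher_is_better = outcome_higher_is_better,
                quiet = quiet)
}

#' Write a trial dataset to CSV
#'
#' @param data A `trial_data` tibble (any extra columns, e.g. from
#'   [center_within_cluster()], are written too).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Per-cluster summaries of a trial dataset
#'
#' Observed (manifest) cluster means of the mediator and outcome, together
#' with cluster size and arm. The mediator mean is the between-level
#' predictor used throughout the mediation models.
#'
#' @param data A `trial_data` tibble.
#' @return A tibble with one row per cluster: `cluster`, `n`, `treatment`,
#'   `mediator_mean`, `outcome_mean`.
#' @export
cluster_summaries <- function(data) {
  data %>%
    as_tibble() %>%
    group_by(.data$cluster) %>%
    summarise(n = dplyr::n(),
              treatment = .data$treatment[1],
              mediator_mean = mean(.data$mediator),
              outcome_mean = mean(.data$outcome),
              .groups = "drop")
}

#' Cluster-mean centre the mediator
#'
#' Appends the observed cluster mean of the mediator
#' (`mediator_cluster_mean`) and the within-cluster deviation
#' (`mediator_dev = mediator - mediator_cluster_mean`) to the dataset.
#' Within every cluster the deviations sum to zero by construction; applying
#' the transform twice leaves `mediator_dev` unchanged.
#'
#' @param data A `trial_data` tibble.
#' @return `data` with `mediator_cluster_mean` and `mediator_dev` columns
#'   added (replaced if already present).
#' @export
center_within_cluster <- function(data) {
  att <- attributes(data)
  out <- data %>%
    as_tibble() %>%
    select(-dplyr::any_of(c("mediator_cluster_mean", "mediator_dev"))) %>%
    group_by(.data$cluster) %>%
    mutate(mediator_cluster_mean = mean(.data$mediator),
           mediator_dev = .data$mediator - .data$mediator_cluster_mean) %>%
    ungroup()
  structure(out,
            class = c("trial_data", class(tibble())),
            directions = att$directions,
            n_dropped = att$n_dropped,
            treatment_map = att$treatment_map)
}

trial_directions <- function(data) {
  d <- attr(data, "directions")
  if (is.null(d)) {
    d <- list(mediator_higher_is_worse = TRUE, outcome_higher_is_better = TRUE)
  }
  d
}
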