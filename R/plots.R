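#' Plot a baseline mediation fit
#'
#' Dot-and-whisker display of the four paths (a, within and contextual
#' mediator-outcome effects, direct effect) and the three indirect effects
#' with their normal-theory intervals.
#'
#' @param object An `hcp_mediation`.
#' @param conf_level Interval coverage for the path whiskers.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hcp_mediation
#' @export
autoplot.hcp_mediation <- function(object, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  paths <- object$paths %>%
    mutate(conf.low = .data$estimate - z * .data$std.error,
           conf.high = .data$estimate + z * .data$std.error,
           panel = "paths") %>%
    select("term", "estimate", "conf.low", "conf.high", "panel")
  ind <- object$indirect %>%
    mutate(term = paste0("indirect_", .data$effect), panel = "indirect effects") %>%
    select("term", "estimate", "conf.low", "conf.high", "panel")
  df <- dplyr::bind_rows(paths, ind) %>%
    mutate(term = factor(.data$term, levels = rev(unique(.data$term))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = "2-1-1 mediation: paths and indirect effects") +
    ggplot2::theme_minimal()
}

#' Plot a healthy-context-paradox test result
#'
#' Shows the moderation coefficient with its confidence interval against
#' the sign region that would support the paradox.
#'
#' @param object An `hcp_test` from [fit_test1()] or [fit_test2()].
#' @param conf_level Interval coverage.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hcp_test
#' @export
autoplot.hcp_test <- function(object, conf_level = 0.95, ...) {
  m <- object$moderation
  crit <- if (is.finite(m$df)) stats::qt(1 - (1 - conf_level) / 2, m$df) else
    qnorm(1 - (1 - conf_level) / 2)
  df <- tibble(term = if (object$level == "contextual")
    "treatment x cluster mediator mean" else "treatment -> within slope",
    estimate = m$estimate,
    conf.low = m$estimate - crit * m$std.error,
    conf.high = m$estimate + crit * m$std.error)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.1) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = "moderation estimate", y = NULL,
      title = paste0("Healthy context paradox test (", object$level, " level): ",
                     object$classification),
      subtitle = paste0("negative sign would indicate a stronger adverse ",
                        "mediator-outcome link under intervention")) +
    ggplot2::theme_minimal()
}

#' Plot operating characteristics
#'
#' Rejection rates of the two tests with binomial Monte-Carlo error bars
#' and the nominal level.
#'
#' @param object An `hcp_oc` from [operating_characteristics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hcp_oc
#' @export
autoplot.hcp_oc <- function(object, ...) {
  alpha <- attr(object, "alpha")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$rejection_rate)) +
    ggplot2::geom_col(width = 0.5, fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rejection_rate - 2 * .data$mc_se,
                                        ymax = .data$rejection_rate + 2 * .data$mc_se),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2, colour = "red") +
    ggplot2::labs(x = NULL, y = "rejection rate",
                  title = "Monte-Carlo rejection rates",
                  subtitle = paste0("dashed line: nominal alpha = ", alpha)) +
    ggplot2::theme_minimal()
}
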