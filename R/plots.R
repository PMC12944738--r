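#' Plot a kinematic series
#'
#' Faceted time-series view of the computed kinematics (angle, angular
#' velocity, linear velocity, force, power).
#'
#' @param object An `lp_kinematics` object.
#' @param vars Which series to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lp_kinematics
#' @export
autoplot.lp_kinematics <- function(object,
                                   vars = c("theta", "omega", "v", "force",
                                            "power"), ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("t", dplyr::all_of(vars)) |>
    tidyr::pivot_longer(-"t", names_to = "series", values_to = "value") |>
    dplyr::mutate(series = factor(.data$series, levels = vars))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c6e91") +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Differences (a - b) against pair means with the bias line and the 95%
#' limits of agreement.
#'
#' @param report An `lp_agreement` object from [agreement_report()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(report) {
  stopifnot(inherits(report, "lp_agreement"))
  ba <- report$bland_altman
  df <- tibble::tibble(mean = (report$a + report$b) / 2,
                       diff = report$a - report$b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "#c0392b",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        colour = "#2c6e91", linetype = "dashed") +
    ggplot2::labs(x = "mean of methods", y = "difference (a - b)",
                  title = sprintf("Bias %.3g, 95%% LoA [%.3g, %.3g]",
                                  ba$bias, ba$loa_lower, ba$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Scatter with the Deming regression line
#'
#' @inheritParams plot_bland_altman
#' @return A ggplot object.
#' @export
plot_deming <- function(report) {
  stopifnot(inherits(report, "lp_agreement"))
  dm <- report$deming
  df <- tibble::tibble(b = report$b, a = report$a)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = dm$slope, intercept = dm$intercept,
                         colour = "#c0392b") +
    ggplot2::labs(x = report$labels[["b"]], y = report$labels[["a"]],
                  title = sprintf("Deming slope %.3f [%.3f, %.3f]",
                                  dm$slope, dm$slope_lo, dm$slope_hi)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_bland_altman
#' @param object An `lp_agreement` object.
#' @param type `"bland_altman"` or `"deming"`.
#' @param ... Unused.
#' @method autoplot lp_agreement
#' @export
autoplot.lp_agreement <- function(object, type = c("bland_altman", "deming"),
                                  ...) {
  type <- match.arg(type)
  if (type == "bland_altman") plot_bland_altman(object) else plot_deming(object)
}
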