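# ggplot2 views of pipeline outputs.

#' Plot mean intensity versus time per session
#'
#' Cohort-mean fluorescein intensity over the nominal schedule, morning in
#' blue and evening in red, with per-subject traces underlaid.
#'
#' @param records Nominal-binned intensity tibble.
#' @param region Region to plot (default first present).
#' @export
plot_intensity_curves <- function(records, region = NULL) {
  r <- dplyr::filter(records, !is.na(.data$nominal_t))
  if (is.null(region)) region <- r$region[1]
  r <- dplyr::filter(r, .data$region == !!region)
  cohort <- r |>
    dplyr::group_by(.data$session, .data$nominal_t) |>
    dplyr::summarise(mean_intensity = mean(.data$mean_intensity),
                     .groups = "drop")
  ggplot2::ggplot(r, ggplot2::aes(x = .data$nominal_t,
                                  y = .data$mean_intensity,
                                  colour = .data$session)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$subject,
                                                        .data$eye,
                                                        .data$session)),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = cohort, linewidth = 1.1) +
    ggplot2::scale_colour_manual(values = c(AM = "#2166ac", PM = "#b2182b")) +
    ggplot2::labs(x = "Time post-injection (s)", y = "Mean intensity",
                  colour = "Session",
                  title = sprintf("Fluorescein intensity over time (%s)", region)) +
    ggplot2::theme_minimal()
}

#' Plot per-subject AM/PM values per region
#' @param pct Output of [percent_change()].
#' @export
plot_session_pairs <- function(pct) {
  long <- tidyr::pivot_longer(pct, c("am", "pm"), names_to = "session",
                              values_to = "value")
  long$session <- toupper(long$session)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$session, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$subject,
                                                        .data$eye)),
                       alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$session), size = 2) +
    ggplot2::scale_colour_manual(values = c(AM = "#2166ac", PM = "#b2182b"),
                                 guide = "none") +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Metric value",
                  title = "Morning versus evening, per subject") +
    ggplot2::theme_minimal()
}

#' Autoplot method for analysis results
#' @param object `ffa_analysis`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ffa_analysis <- function(object, ...) {
  plot_session_pairs(object$pct_change)
}
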