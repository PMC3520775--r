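#' Plot observed time-activity curves
#'
#' Observed concentration-time profiles per subject and scan, coloured by
#' observation type, on a log10 concentration axis (small values floored for
#' display).
#'
#' @param data a `pk_dataset`.
#' @param subjects optional subject ids to display.
#' @return A ggplot object.
#' @export
plot_tac <- function(data, subjects = NULL) {
  d <- tibble::as_tibble(data)
  if (!is.null(subjects)) d <- d[d$subject_id %in% subjects, ]
  d$value <- pmax(d$value, 1e-3)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$value,
                                  colour = .data$obs_type)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(ggplot2::vars(.data$subject_id),
                        ggplot2::vars(.data$scan),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (min)", y = "Concentration (kBq/ml)",
                  colour = NULL)
}

#' Goodness-of-fit panels for a population fit
#'
#' Standard population-model diagnostics built from [diagnostics_table()]:
#' observations against population (`PRED`) and individual (`IPRED`)
#' predictions with the line of identity, and individual weighted residuals
#' (`IWRES`) against time and against `IPRED`.
#'
#' @param object a `popfit`.
#' @param ... unused.
#' @return A ggplot object with four facets.
#' @exportS3Method ggplot2::autoplot
autoplot.popfit <- function(object, ...) {
  d <- diagnostics_table(object)
  top <- tidyr::pivot_longer(
    d, c("PRED", "IPRED"), names_to = "panel", values_to = "xvar")
  top <- dplyr::transmute(top,
                          panel = paste0("DV vs ", .data$panel),
                          x = .data$xvar, y = .data$value)
  bot <- dplyr::bind_rows(
    dplyr::transmute(d, panel = "IWRES vs time", x = .data$time_min,
                     y = .data$IWRES),
    dplyr::transmute(d, panel = "IWRES vs IPRED", x = .data$IPRED,
                     y = .data$IWRES))
  all <- dplyr::bind_rows(top, bot)
  ref <- tibble::tibble(
    panel = unique(all$panel),
    slope = c(1, 1, 0, 0), intercept = 0)
  ggplot2::ggplot(all, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_abline(data = ref,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept),
                         colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Volume-of-distribution report plot
#'
#' Bar chart of the reported volumes of distribution per region and
#' condition from [vt_nlme_table()].
#'
#' @param object a tibble from [vt_nlme_table()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_vt_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$region, .data$VT,
                                       fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "VT (ml/ml)", fill = NULL)
}
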