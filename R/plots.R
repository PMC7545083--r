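#' Plot a stimulus image
#'
#' Renders an 8-bit luminance matrix (a composite or noise-only
#' stimulus) as a grayscale raster with the pixel aspect preserved.
#'
#' @param image Numeric matrix (grey levels 0-255).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @examples
#' plot_stimulus(generate_pink_noise(64, 64, seed = 1))
#' @export
plot_stimulus <- function(image, title = NULL) {
  stop_if_not_matrix(image, "image")
  df <- tidyr::expand_grid(row = seq_len(nrow(image)),
                           col = seq_len(ncol(image)))
  df$value <- as.numeric(t(image))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Condition means of a subject-level summary
#'
#' Group means (with standard-error bars) of a signal-detection measure
#' by signal category and visual field, in the layout the group analyses
#' use.
#'
#' @param summary A tibble from [subject_condition_summary()] (or
#'   [simulate_cohort_rates()]).
#' @param measure Column to plot (`"dprime"`, `"criterion"`, or an RT
#'   column).
#' @return A ggplot object.
#' @export
plot_condition_means <- function(summary, measure = "dprime") {
  if (!measure %in% names(summary)) {
    abort(sprintf("Column '%s' not found in `summary`.", measure))
  }
  df <- summary |>
    dplyr::group_by(.data$category, .data$visual_field) |>
    dplyr::summarise(
      mean = mean(.data[[measure]], na.rm = TRUE),
      se = sd(.data[[measure]], na.rm = TRUE) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$visual_field, .data$mean,
                                   group = .data$category,
                                   colour = .data$category)) +
    ggplot2::geom_point(size = 2,
                        position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      width = 0.1, position = ggplot2::position_dodge(0.2)
    ) +
    ggplot2::labs(x = "Visual field", y = measure, colour = "Signal type") +
    ggplot2::theme_minimal()
}

#' @describeIn run_scenario Plot a recovery report: per-parameter
#'   replicate estimates with the injected truth overlaid.
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  est <- attr(object, "estimates")
  truths <- object[c("parameter", "truth")]
  ggplot2::ggplot(est, ggplot2::aes(.data$parameter, .data$estimate)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(
      data = truths,
      ggplot2::aes(.data$parameter, .data$truth),
      colour = "red", shape = 4, size = 4, stroke = 1.5
    ) +
    ggplot2::labs(
      x = NULL, y = "Group-level estimate",
      title = paste0("Parameter recovery: ", attr(object, "scenario")),
      subtitle = paste0(attr(object, "reps"), " replicate cohorts; ",
                        "red cross = injected truth")
    ) +
    ggplot2::theme_minimal()
}
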