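#' Plot radial ring profiles
#'
#' Mean paint-signal fraction per concentric ring (ring 1 innermost), one
#' bar series per group, with standard-error bars — the standard way to
#' show radial repositioning of a chromosome territory.
#'
#' @param nuclei Per-nucleus tibble with `ring1..ringN` columns and a
#'   `group` column (as produced by [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(nuclei) {
  long <- tidyr::pivot_longer(nuclei, dplyr::starts_with("ring"),
                              names_to = "ring", names_prefix = "ring",
                              values_to = "fraction")
  long$ring <- as.integer(long$ring)
  summ <- long |>
    group_by(.data$group, .data$ring) |>
    summarise(mean = mean(.data$fraction, na.rm = TRUE),
              se = sd(.data$fraction, na.rm = TRUE) /
                sqrt(sum(!is.na(.data$fraction))),
              .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$ring),
                                     y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.85),
                      width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.85), width = 0.25) +
    ggplot2::labs(x = "concentric ring (1 = central, 6 = peripheral)",
                  y = "fraction of paint signal", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot axial-class proportions
#'
#' Stacked proportion of major- vs minor-parallel territories per group,
#' with an optional horizontal line at the null expectation.
#'
#' @param territories Per-territory tibble with `axial_class` and `group`.
#' @param p_major_null Optional null major-parallel probability to draw.
#' @return A ggplot object.
#' @export
plot_axial_classes <- function(territories, p_major_null = NULL) {
  d <- territories |>
    filter(!is.na(.data$axial_class)) |>
    group_by(.data$group, class = .data$axial_class) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                       y = .data$fraction,
                                       fill = .data$class)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::labs(x = NULL, y = "proportion of territories", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(p_major_null)) {
    p <- p + ggplot2::geom_hline(yintercept = p_major_null,
                                 linetype = "dashed")
  }
  p
}

#' @export
autoplot.ct_segmentation <- function(object, ...) {
  info <- object$info
  ggplot2::ggplot(info, ggplot2::aes(x = .data$area_px,
                                     fill = .data$retained)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "component area (px)", y = "count",
                  fill = "retained") +
    ggplot2::theme_minimal()
}
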