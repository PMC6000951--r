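# ggplot2 presentation methods for the result objects.

#' Plot a radiograph channel
#'
#' @param object An `ionrad_radiograph`.
#' @param channel Channel column to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ionrad_radiograph <- function(object, channel = "mean_energy", ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data[[channel]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]", fill = channel,
                  title = sprintf("Radiograph (%d um bins)",
                                  attr(object, "plane")$pixel_pitch))
}

#' Plot an MTF curve
#'
#' @param object An `mtf_curve`.
#' @param ... Unused.
#' @return A ggplot with the 10% modulation level and f10 marked.
#' @export
autoplot.mtf_curve <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_lp_mm, .data$modulation)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.1, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$f10_lp_mm, linetype = 3) +
    ggplot2::coord_cartesian(xlim = c(0, min(3 * object$f10_lp_mm,
                                             max(df$freq_lp_mm))),
                             ylim = c(0, 1)) +
    ggplot2::labs(x = "spatial frequency [lp/mm]", y = "MTF",
                  title = sprintf("MTF10%% = %.2f lp/mm", object$f10_lp_mm))
}

#' Plot the stage-wise quality comparison
#'
#' @param stages Tibble from [stage_comparison()].
#' @return A ggplot of CNR and spatial resolution per processing stage.
#' @export
plot_stage_comparison <- function(stages) {
  df <- tidyr::pivot_longer(
    stages[, c("stage", "cnr", "sr_f10_lp_mm")],
    cols = c("cnr", "sr_f10_lp_mm"),
    names_to = "metric", values_to = "value")
  df$stage <- factor(df$stage, levels = stages$stage)
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$value,
                                   group = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "processing stage", y = NULL)
}

#' Plot the depth-dose profile of a run
#'
#' @param report A `dose_report` from [compute_dose()].
#' @return A ggplot of dose vs depth.
#' @export
plot_dose_profile <- function(report) {
  ggplot2::ggplot(report$profile,
                  ggplot2::aes(.data$depth_mm, .data$dose_gy * 1e6)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth [mm]", y = "dose [uGy]")
}
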