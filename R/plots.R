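#' Plot a delta-vs-population-size curve
#'
#' Log-log curve of mean delta against cell population size with a +/- 1 sd
#' ribbon; a reference line with slope -1/2 shows the central-limit
#' prediction for intrinsic-noise averaging.
#'
#' @param object tibble from [delta_vs_popsize()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dosevar_delta_curve <- function(object, ...) {
  ref <- object$mean_delta[1] * sqrt(object$size[1] / object$size)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$mean_delta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean_delta - .data$sd_delta, 1e-6),
                                      ymax = .data$mean_delta + .data$sd_delta),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = ref), linetype = "dashed",
                       colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cells in population", y = "mean delta",
                  title = "Population averaging of intrinsic noise",
                  subtitle = "dashed: N^(-1/2) reference")
}

#' Plot delta distributions by dosage-response bin
#'
#' @param object result of [bin_vs_delta()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dosevar_response_bins <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$bin_label, y = .data$delta)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "dosage-response bin", y = "delta",
                  title = "Expression variability by dosage response")
}

#' Boxplot of delta by dose group
#'
#' @param deltas delta table from [delta_table()] with a `dose` column.
#' @return a ggplot object.
#' @export
plot_delta_by_dose <- function(deltas) {
  dat <- dplyr::filter(deltas, .data$dose %in% c(1L, 2L)) |>
    dplyr::mutate(dose = factor(.data$dose, levels = c(1, 2),
                                labels = c("one dose", "two dose")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose, y = .data$delta)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = NULL, y = "delta",
                  title = "Replicate variability by gene dose")
}

#' Histogram of the resampled null medians with the observed value
#'
#' @param object a `dosevar_median_null` from [median_null()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dosevar_median_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_median)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_median,
                        colour = "red") +
    ggplot2::labs(x = "null median delta", y = "draws",
                  title = "Observed one-dose median vs two-dose null",
                  subtitle = paste0("empirical p = ",
                                    format(object$empirical_p, digits = 3)))
}
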