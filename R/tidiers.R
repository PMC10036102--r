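#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a zero-intercept calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return One row per model term (the slope) with its estimate and standard
#'   error (from the through-origin residual variance).
#' @export
tidy.calibration_fit <- function(x, ...) {
  se <- sqrt(sum(x$residuals^2) / (x$n_points - 1) / sum(x$data$simulated^2))
  tibble(term = "slope", estimate = x$slope, std.error = se)
}

#' @rdname tidy.calibration_fit
#' @return `glance()`: a one-row model summary.
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(slope = x$slope, pearson_r = x$pearson_r, r.squared = x$r_squared,
         r.squared.origin = x$r_squared_origin, nobs = x$n_points)
}

#' Tidy / summarize a shield study
#'
#' @param x An `fs_shield_study`.
#' @param ... Unused.
#' @return `tidy()`: the per-cell ROI dose-rate table. `glance()`: one row
#'   with the study dimensions and run size.
#' @export
tidy.fs_shield_study <- function(x, ...) as_tibble(x$report)

#' @rdname tidy.fs_shield_study
#' @export
glance.fs_shield_study <- function(x, ...) {
  tibble(n_patterns = length(x$study$patterns),
         n_projections = length(x$study$projections),
         n_cells = length(x$study$patterns) * length(x$study$projections),
         n_histories_per_cell = x$study$run$n_histories,
         seed = x$study$run$seed)
}

#' Plot a source spectrum
#'
#' @param object An `fs_spectrum`.
#' @param ... Unused.
#' @return A ggplot: fluence per energy bin.
#' @export
autoplot.fs_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$energy_keV, y = .data$fluence)) +
    ggplot2::geom_col(width = attr(object, "bin_keV"), fill = "steelblue") +
    ggplot2::labs(x = "energy (keV)", y = "relative fluence",
                  title = sprintf("%g kVp, mean %.1f keV", attr(object, "kvp"),
                                  mean_energy(object))) +
    ggplot2::theme_minimal()
}

#' Plot an air dose-rate height-slice map
#'
#' @param object An `fs_dose_map`.
#' @param trans Transformation for the fill scale (default `"log10"`).
#' @param ... Unused.
#' @return A ggplot raster of dose rate over the room footprint.
#' @export
autoplot.fs_dose_map <- function(object, trans = "log10", ...) {
  band <- attr(object, "band_cm")
  df <- as_tibble(object)
  df$dose_rate_uGy_h <- pmax(df$dose_rate_uGy_h, 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_m, y = .data$y_m,
                                   fill = .data$dose_rate_uGy_h)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "uGy/h") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = sprintf("air dose rate, %g-%g cm height band",
                                  band[1], band[2])) +
    ggplot2::theme_minimal()
}

#' Plot ROI dose rates across shield patterns
#'
#' @param report A study report tibble (or `fs_shield_study`).
#' @return A ggplot: dose rate with 1-sigma error bars per ROI, colored by
#'   shield pattern and faceted by projection.
#' @export
plot_roi_doses <- function(report) {
  if (inherits(report, "fs_shield_study")) report <- report$report
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$roi, y = .data$dose_rate_uGy_h,
                               fill = .data$pattern)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$dose_rate_uGy_h - .data$sigma_uGy_h,
                   ymax = .data$dose_rate_uGy_h + .data$sigma_uGy_h),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::facet_wrap(~projection) +
    ggplot2::labs(x = NULL, y = "absorbed dose rate (uGy/h)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
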