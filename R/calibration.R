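#' The 12-condition calibration design
#'
#' A deterministic grid of source-to-surface distance (60, 65, 70 cm) by
#' dosimeter depth (0, 5, 10, 15 cm) in a water-equivalent phantom, the
#' dosimeter at the centre of the field of view.
#'
#' @return A tibble with `condition_id`, `ssd_cm`, `depth_cm` (12 rows).
#' @export
#' @examples
#' generate_conditions()
generate_conditions <- function() {
  tibble(condition_id = 1:12,
         ssd_cm = rep(c(60, 65, 70), each = 4),
         depth_cm = rep(c(0, 5, 10, 15), times = 3))
}

#' Zero-intercept calibration fit
#'
#' Least-squares straight line through the origin relating simulated to
#' measured doses: `slope = sum(x*y) / sum(x^2)`. The slope is the factor of
#' scaling on dose conversion used by [dose_conversion()]. `r_squared` is
#' reported as the square of Pearson's product-moment correlation (the
#' regression-through-origin variant is also returned for reference).
#'
#' @param data Optional data frame holding the columns; otherwise pass
#'   numeric vectors.
#' @param simulated,measured Column names (when `data` is given) or numeric
#'   vectors: simulated doses (x) and measured doses (y).
#' @return A `calibration_fit`: slope, `pearson_r`, `r_squared`
#'   (`= pearson_r^2`), `r_squared_origin`, `n_points`, residuals and the
#'   data. Methods: [tidy()], [glance()], `print()`.
#' @export
#' @examples
#' fit_zero_intercept(simulated = c(1, 2), measured = c(1.1, 2.2))
fit_zero_intercept <- function(data = NULL, simulated = "simulated",
                               measured = "measured") {
  if (!is.null(data)) {
    x <- data[[if (is.character(simulated)) simulated else "simulated"]]
    y <- data[[if (is.character(measured)) measured else "measured"]]
  } else {
    x <- simulated; y <- measured
  }
  if (length(x) != length(y) || length(x) < 2)
    abort("need equal-length x and y with at least 2 points")
  if (all(x == 0)) abort("degenerate fit: all simulated doses are zero")
  slope <- sum(x * y) / sum(x * x)
  r <- suppressWarnings(stats::cor(x, y))
  res <- y - slope * x
  r2o <- 1 - sum(res^2) / sum(y^2)
  structure(list(slope = slope, pearson_r = r,
                 r_squared = r^2, r_squared_origin = r2o,
                 n_points = length(x), residuals = res,
                 data = tibble(simulated = x, measured = y)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> y = %.4g x (n = %d)\n", x$slope, x$n_points))
  cat(sprintf("  pearson r = %.4g, r^2 = %.4g\n", x$pearson_r, x$r_squared))
  invisible(x)
}

# water-slab calibration scene: source at the origin shooting up +z through
# air onto a 30 x 30 x 20 cm water phantom whose entrance surface sits at the
# requested SSD; the scoring cell is a 1 cm voxel on the central axis at the
# requested depth.
make_calibration_scene <- function(ssd_cm, depth_cm, spacing_m = 0.01,
                                   field_mm = 156.5, sid_m = 1.0) {
  half <- 0.17
  zmax <- ssd_cm / 100 + 0.22
  origin <- c(-half, -half, 0)
  dims <- c(ceiling(2 * half / spacing_m), ceiling(2 * half / spacing_m),
            ceiling(zmax / spacing_m))
  xs <- voxel_centers(origin[1], spacing_m, dims[1])
  zs <- voxel_centers(origin[3], spacing_m, dims[3])
  idx <- array(1L, dim = dims)
  z_in <- zs >= ssd_cm / 100 & zs < ssd_cm / 100 + 0.20
  in_xy <- abs(xs) <= 0.15
  idx[in_xy, in_xy, z_in] <- 2L
  zd <- ssd_cm / 100 + depth_cm / 100
  k <- which(zs >= zd & zs < zd + spacing_m)[1]
  if (is.na(k)) k <- dims[3]
  i0 <- which.min(abs(xs))
  roi <- as.integer(i0 + dims[1] * ((i0 - 1) + dims[2] * (k - 1)))
  materials <- tibble(code = 1:2, label = c("air", "water"),
                      base = c("air", "water"),
                      density = c(get_material("air")$density, 1.0))
  structure(list(origin = origin, spacing = spacing_m, dims = dims,
                 index = idx, materials = materials,
                 roi = list(dosimeter = roi),
                 meta = list(source = list(
                   type = 0L, pos = c(0, 0, 0), axis = c(0, 0, 1),
                   u = c(1, 0, 0), v = c(0, 1, 0),
                   half_x = field_mm / 2000, half_y = field_mm / 2000,
                   sid = sid_m),
                   ssd_cm = ssd_cm, depth_cm = depth_cm)),
            class = "fs_voxel_scene")
}

#' Simulate the calibration doses
#'
#' One transport run per calibration condition: a water-slab phantom at the
#' condition's SSD with a central-axis scoring cell at the condition's depth.
#'
#' @param conditions A tibble from [generate_conditions()].
#' @param spectrum Source `fs_spectrum`.
#' @param run An [run_config()]; each condition uses a seed offset so the
#'   conditions are independent but reproducible.
#' @param spacing_m Scene voxel size.
#' @return `conditions` with `simulated_dose` (Gy per photon) and `sigma`.
#' @export
simulate_calibration_doses <- function(conditions, spectrum, run,
                                       spacing_m = 0.01) {
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    cond <- conditions[i, ]
    scene <- make_calibration_scene(cond$ssd_cm, cond$depth_cm, spacing_m)
    r <- run_config(run$n_histories, run$n_batches,
                    seed = run$seed + 131 * i, cutoff_keV = run$cutoff_keV)
    tal <- run_histories(scene, spectrum, r, air_spacing_m = 0.1)
    mass <- roi_masses(scene)[["dosimeter"]]
    nb <- batch_histories(r)
    d_b <- tal$roi_batch[1, ] * .keV_to_J / mass / nb
    dplyr::mutate(cond,
                  simulated_dose = sum(tal$roi_batch[1, ]) * .keV_to_J / mass /
                    r$n_histories,
                  sigma = stats::sd(d_b) / sqrt(length(d_b)))
  })
  dplyr::bind_rows(rows)
}

#' Calibration data CSV import/export
#'
#' Columns: `condition_id`, `ssd_cm`, `depth_cm`, `measured_dose`,
#' `simulated_dose`.
#'
#' @param data A data frame with the columns above.
#' @param path File path.
#' @return `read_calibration_csv()` returns a tibble;
#'   `write_calibration_csv()` returns `path` invisibly.
#' @export
write_calibration_csv <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a calibration fit report as JSON
#'
#' @param fit A `calibration_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(slope = fit$slope, pearson_r = fit$pearson_r,
         r_squared = fit$r_squared, r_squared_origin = fit$r_squared_origin,
         n_points = fit$n_points,
         data = as.data.frame(fit$data)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
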