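.keV_to_J <- 1.602176634e-16

voxel_mass_kg <- function(scene) {
  dens <- scene$materials$density[match(as.vector(scene$index),
                                        scene$materials$code)]
  array(dens * scene$spacing^3 * 1000, dim = scene$dims)
}

#' Absorbed dose per source photon
#'
#' `(summed keV x 1.602e-16 J/keV) / voxel mass (kg) / n_histories`.
#'
#' @param tally An `fs_tally`.
#' @param voxel Optional voxel selector (linear index or `c(i, j, k)`); when
#'   omitted the full per-voxel array is returned.
#' @return Gy per source photon (array or scalar).
#' @export
dose_per_photon <- function(tally, voxel = NULL) {
  mass <- voxel_mass_kg(tally$scene)
  if (any(mass <= 0)) abort("zero-mass voxel in scene")
  d <- tally$fine_sum * .keV_to_J / mass / tally$run$n_histories
  if (is.null(voxel)) return(d)
  if (length(voxel) == 3) d[voxel[1], voxel[2], voxel[3]] else d[voxel]
}

#' Dose-rate conversion metadata
#'
#' Bundles the source normalization (`photons_per_mAs`), the tube duty model
#' (`ma` treated as time-averaged current, so mAs/h = ma x 3600; `fps` is
#' carried as metadata only) and the measured-versus-simulated scaling factor.
#'
#' @param photons_per_mAs Photons emitted into the collimated field per mAs;
#'   defaults from `spectrum` when given.
#' @param ma Tube current (mA).
#' @param scaling_factor Calibration scaling factor (see
#'   [fit_zero_intercept()]); defaults to the fitted clinical value 1.10.
#' @param fps Pulse rate, metadata only.
#' @param spectrum Optional `fs_spectrum` supplying `photons_per_mAs`.
#' @return An `fs_dose_conversion` list.
#' @export
dose_conversion <- function(photons_per_mAs = NULL, ma = 3.0,
                            scaling_factor = 1.10, fps = 3.75,
                            spectrum = NULL) {
  if (is.null(photons_per_mAs)) {
    if (is.null(spectrum)) abort(paste0(
      "missing calibration: supply photons_per_mAs (or a spectrum) and a ",
      "scaling_factor, e.g. from fit_zero_intercept()"))
    photons_per_mAs <- attr(spectrum, "photons_per_mAs")
  }
  stopifnot(photons_per_mAs > 0, ma > 0, scaling_factor > 0)
  structure(list(photons_per_mAs = photons_per_mAs, ma = ma,
                 scaling_factor = scaling_factor, fps = fps),
            class = "fs_dose_conversion")
}

#' Convert dose per photon to a dose rate
#'
#' `dose_rate = dose_per_photon x photons_per_mAs x scaling_factor x
#' (ma x 3600 s/h) x 1e6 uGy/Gy`.
#'
#' @param dose_per_photon Gy per source photon (any shape).
#' @param conversion An [dose_conversion()].
#' @return Dose rate(s) in uGy/h.
#' @export
#' @examples
#' to_dose_rate(1e-12, dose_conversion(photons_per_mAs = 1e6))
to_dose_rate <- function(dose_per_photon, conversion) {
  if (!inherits(conversion, "fs_dose_conversion"))
    abort("missing calibration: pass a dose_conversion() object")
  dose_per_photon * conversion$photons_per_mAs * conversion$scaling_factor *
    conversion$ma * 3600 * 1e6
}

roi_masses <- function(scene) {
  mass <- voxel_mass_kg(scene)
  vapply(scene$roi, function(ix) sum(mass[ix]), numeric(1))
}

batch_histories <- function(run) {
  per <- floor(run$n_histories / run$n_batches)
  rem <- run$n_histories - per * run$n_batches
  per + (seq_len(run$n_batches) <= rem)
}

#' Region-of-interest dose rates
#'
#' Mass-weighted mean absorbed dose over each ROI's voxels, converted to
#' uGy/h; the 1-sigma uncertainty is the standard error of the between-batch
#' means.
#'
#' @param tally An `fs_tally` from a scene with ROIs.
#' @param conversion An [dose_conversion()].
#' @param roi Optional character subset of ROI names.
#' @return A tibble: `roi`, `n_voxels`, `mass_kg`, `dose_rate_uGy_h`,
#'   `sigma_uGy_h`.
#' @export
roi_dose_rate <- function(tally, conversion, roi = NULL) {
  scene <- tally$scene
  if (!length(scene$roi)) abort("scene has no ROIs")
  names_all <- names(scene$roi)
  roi <- roi %||% names_all
  bad <- setdiff(roi, names_all)
  if (length(bad)) abort(paste("unknown ROI:", paste(bad, collapse = ", ")))
  mass <- roi_masses(scene)
  nb <- batch_histories(tally$run)
  out <- lapply(roi, function(nm) {
    i <- match(nm, names_all)
    if (mass[i] <= 0 || !length(scene$roi[[nm]])) abort("empty ROI mask")
    d_b <- tally$roi_batch[i, ] * .keV_to_J / mass[i] / nb  # Gy/photon per batch
    dpp <- sum(tally$roi_batch[i, ]) * .keV_to_J / mass[i] /
      tally$run$n_histories
    se <- stats::sd(d_b) / sqrt(length(d_b))
    tibble(roi = nm, n_voxels = length(scene$roi[[nm]]), mass_kg = mass[i],
           dose_rate_uGy_h = to_dose_rate(dpp, conversion),
           sigma_uGy_h = to_dose_rate(se, conversion))
  })
  dplyr::bind_rows(out)
}

#' @describeIn roi_dose_rate Mass-weighted dose rate over the union of
#'   several ROIs (e.g. both lens patches as one lens band).
#' @param rois Character vector of ROI names to pool.
#' @param name Label for the pooled region.
#' @export
roi_union_dose_rate <- function(tally, conversion, rois, name = "union") {
  scene <- tally$scene
  bad <- setdiff(rois, names(scene$roi))
  if (length(bad)) abort(paste("unknown ROI:", paste(bad, collapse = ", ")))
  ix <- match(rois, names(scene$roi))
  mass <- sum(roi_masses(scene)[ix])
  if (mass <= 0) abort("empty ROI union")
  nb <- batch_histories(tally$run)
  e_b <- colSums(tally$roi_batch[ix, , drop = FALSE])
  d_b <- e_b * .keV_to_J / mass / nb
  dpp <- sum(e_b) * .keV_to_J / mass / tally$run$n_histories
  se <- stats::sd(d_b) / sqrt(length(d_b))
  tibble(roi = name, n_voxels = sum(lengths(scene$roi[ix])), mass_kg = mass,
         dose_rate_uGy_h = to_dose_rate(dpp, conversion),
         sigma_uGy_h = to_dose_rate(se, conversion))
}

# air-kerma grid in Gy per source photon, with per-voxel 1-sigma
air_dose_per_photon <- function(tally) {
  vol_cm3 <- (tally$air_spacing * 100)^3
  B <- tally$run$n_batches
  N <- tally$run$n_histories
  conv <- 1.602176634e-13 / vol_cm3 / N     # keV/g units -> Gy, per photon
  mean_ <- tally$air_sum * conv
  varb <- pmax(tally$air_sumsq - tally$air_sum^2 / B, 0) / (B - 1)
  sig <- sqrt(B * varb) * conv
  list(dose = mean_, sigma = sig)
}

#' Air dose-rate map at a height band
#'
#' Averages the track-length air-kerma grid over the voxel layer(s) whose
#' centres fall in the requested height band above the floor. The bands
#' 145-150 cm (eye lens), 130-135 cm (thyroid) and 80-85 cm (ovaries) are the
#' preconfigured operator-relevant heights.
#'
#' @param tally An `fs_tally`.
#' @param band_cm Height band `c(lo, hi)` in cm from the floor.
#' @param conversion An [dose_conversion()].
#' @return An `fs_dose_map` tibble: `x_m`, `y_m`, `dose_rate_uGy_h`,
#'   `sigma_uGy_h`, with band and grid metadata attributes.
#' @export
height_slice_map <- function(tally, band_cm = c(145, 150), conversion) {
  sp <- tally$air_spacing
  o <- tally$scene$origin
  nz <- dim(tally$air_sum)[3]
  zc <- o[3] + (seq_len(nz) - 0.5) * sp
  layers <- which(zc >= band_cm[1] / 100 & zc < band_cm[2] / 100)
  if (!length(layers)) abort("height band outside the air grid")
  adp <- air_dose_per_photon(tally)
  d <- apply(adp$dose[, , layers, drop = FALSE], c(1, 2), mean)
  s <- sqrt(apply(adp$sigma[, , layers, drop = FALSE]^2, c(1, 2), sum)) /
    length(layers)
  nx <- dim(d)[1]; ny <- dim(d)[2]
  out <- tibble(
    x_m = rep(o[1] + (seq_len(nx) - 0.5) * sp, times = ny),
    y_m = rep(o[2] + (seq_len(ny) - 0.5) * sp, each = nx),
    dose_rate_uGy_h = to_dose_rate(as.vector(d), conversion),
    sigma_uGy_h = to_dose_rate(as.vector(s), conversion))
  structure(out, class = c("fs_dose_map", class(out)),
            band_cm = band_cm, spacing_m = sp, origin_m = o,
            dims = c(nx, ny), n_layers = length(layers))
}

#' Area of a dose map above a level
#'
#' The "area above 50 uGy/h" contour summary for comparing dose maps.
#'
#' @param map An `fs_dose_map`.
#' @param level_uGy_h Contour level.
#' @return Area in m^2.
#' @export
area_above <- function(map, level_uGy_h = 50) {
  sum(map$dose_rate_uGy_h > level_uGy_h) * attr(map, "spacing_m")^2
}

# is the straight path from the source to a point blocked by the shield panel?
shield_blocks <- function(scene, pts) {
  cfg <- scene$meta$config
  sh <- cfg$shield
  if (sh$pattern == "absent") return(rep(FALSE, nrow(pts)))
  lay <- scene$meta$layout
  pg <- projection_geometry(cfg)
  sx <- pg$source_pos
  xs <- scene$meta$shield_x
  dx <- pts[, 1] - sx[1]
  t <- (xs - sx[1]) / dx
  hit_y <- sx[2] + t * (pts[, 2] - sx[2])
  hit_z <- sx[3] + t * (pts[, 3] - sx[3])
  crosses <- is.finite(t) & t > 0 & t < 1
  in_panel <- crosses &
    abs(hit_y - lay$cy) <= sh$width_m / 2 &
    hit_z >= sh$floor_offset_m & hit_z < sh$floor_offset_m + sh$height_m
  open <- rep(FALSE, nrow(pts))
  for (ap in sh$aperture) {
    open <- open |
      (abs(hit_y - (lay$cy + ap$offset_cm / 100)) <= ap$width_cm / 200 &
         hit_z >= ap$band_cm[1] / 100 & hit_z < ap$band_cm[2] / 100)
  }
  in_panel & !open
}

#' Shadow structure of an air dose map behind the shield
#'
#' Classifies map cells beyond the shield plane as geometrically shadowed
#' (the ray from the source focal spot to the cell centre at the band
#' mid-height intersects shield material) or open (it passes an aperture or
#' misses the panel), then compares the with-shield to without-shield dose
#' ratio between the classes. A working shield produces a fan-shaped
#' shadowed region with a ratio well below the open-class ratio.
#'
#' @param map_with,map_without `fs_dose_map`s on identical grids, simulated
#'   with and without the shield.
#' @param scene The shielded `fs_voxel_scene` (supplies shield and source
#'   geometry).
#' @return A tibble with one row per class: `n_cells`, mean dose rates, their
#'   `ratio` and its propagated `sigma`.
#' @export
shadow_analysis <- function(map_with, map_without, scene) {
  if (!identical(attr(map_with, "dims"), attr(map_without, "dims")) ||
      !isTRUE(all.equal(attr(map_with, "spacing_m"),
                        attr(map_without, "spacing_m"))))
    abort("maps have mismatched geometry")
  band <- attr(map_with, "band_cm")
  zmid <- mean(band) / 100
  pts <- cbind(map_with$x_m, map_with$y_m, zmid)
  beyond <- pts[, 1] > scene$meta$shield_x
  shadowed <- shield_blocks(scene, pts)
  cls <- ifelse(shadowed, "shadowed", "open")
  out <- lapply(c("shadowed", "open"), function(cl) {
    sel <- beyond & cls == cl
    if (!sum(sel)) return(tibble(class = cl, n_cells = 0L, with_uGy_h = NA_real_,
                                 without_uGy_h = NA_real_, ratio = NA_real_,
                                 sigma = NA_real_))
    mw <- mean(map_with$dose_rate_uGy_h[sel])
    mo <- mean(map_without$dose_rate_uGy_h[sel])
    sw <- sqrt(sum(map_with$sigma_uGy_h[sel]^2)) / sum(sel)
    so <- sqrt(sum(map_without$sigma_uGy_h[sel]^2)) / sum(sel)
    r <- mw / mo
    tibble(class = cl, n_cells = sum(sel), with_uGy_h = mw, without_uGy_h = mo,
           ratio = r, sigma = abs(r) * sqrt((sw / mw)^2 + (so / mo)^2))
  })
  dplyr::bind_rows(out)
}

#' Chord lengths of a segment through a regular grid
#'
#' The half-open voxel traversal used by the track-length air-kerma
#' estimator, exposed for verification.
#'
#' @param p0,p1 Segment endpoints (m).
#' @param dims,origin,spacing_m Grid geometry.
#' @return A tibble with the linear `voxel` index (1-based) and `chord_m`.
#' @export
segment_chords <- function(p0, p1, dims, origin, spacing_m) {
  as_tibble(as.data.frame(segment_chords_cpp(p0, p1, as.integer(dims),
                                             origin, spacing_m)))
}

#' Write an array as an ASCII NRRD file
#'
#' Plain-text NRRD export (spacings and origin recorded) for inspecting
#' scenes and dose grids in external viewers.
#'
#' @param x A 3-D numeric or integer array.
#' @param path Output file.
#' @param spacing_m Voxel spacing (scalar or length 3).
#' @param origin_m Grid origin.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, spacing_m, origin_m = c(0, 0, 0)) {
  stopifnot(length(dim(x)) == 3)
  sp <- rep(spacing_m, length.out = 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("NRRD0004",
               paste0("type: ", if (is.integer(x)) "int" else "double"),
               "dimension: 3",
               paste("sizes:", paste(dim(x), collapse = " ")),
               paste("spacings:", paste(sp, collapse = " ")),
               paste0("axis mins: ", paste(origin_m, collapse = " ")),
               "encoding: ascii", ""), con)
  writeLines(paste(as.vector(x), collapse = " "), con)
  invisible(path)
}

#' Export a dose map as CSV
#'
#' @param map An `fs_dose_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dose_map_csv <- function(map, path) {
  readr::write_csv(as_tibble(map), path)
  invisible(path)
}
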