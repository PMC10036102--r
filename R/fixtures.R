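# Synthetic-data generators: analytic verification scenes, noisy calibration
# datasets and scaled-down operating-room studies. Every stochastic fixture
# takes an explicit seed and records its parameters in the output metadata.

#' Monoenergetic single-bin spectrum (verification source)
#'
#' @param energy_keV Photon energy.
#' @param bin_keV Bin width.
#' @return An `fs_spectrum` with one bin of negligible width around the line.
#' @export
mono_spectrum <- function(energy_keV, bin_keV = 1e-6) {
  tab <- tibble(energy_low = energy_keV - bin_keV / 2,
                energy_high = energy_keV + bin_keV / 2,
                energy_keV = energy_keV, fluence = 1)
  spec <- new_spectrum(tab, kvp = energy_keV + 1, bin_keV = bin_keV,
                       photons_per_mAs = NA_real_, output_uGy_mAs_1m = 30,
                       field_side_m_at_1m = 0.1565)
  attr(spec, "photons_per_mAs") <-
    photons_per_mAs_from_output(spec, 30, 0.1565)
  spec
}

#' Slab verification scene
#'
#' A single slab of material normal to a +z beam, embedded in a near-vacuum
#' box so every non-interacting photon escapes. Used for narrow-beam
#' (Beer-Lambert) transmission oracles.
#'
#' @param material Slab material (registry name).
#' @param thickness_cm Slab thickness (>= 0).
#' @param spacing_cm Voxel size.
#' @param lateral_cm Transverse extent of the box.
#' @param beam `"pencil"` (default) or `"parallel"`.
#' @param standoff_cm Distance from the source plane to the slab face.
#' @return An `fs_voxel_scene` with an embedded source; metadata records the
#'   slab exit plane for transmission scoring.
#' @export
make_slab_scene <- function(material = "water", thickness_cm,
                            spacing_cm = 0.5, lateral_cm = 40,
                            beam = c("pencil", "parallel"),
                            standoff_cm = 5) {
  beam <- match.arg(beam)
  if (thickness_cm < 0) abort("thickness must be >= 0")
  sp <- spacing_cm / 100
  half <- lateral_cm / 200
  zmax <- (standoff_cm + max(thickness_cm, spacing_cm / 2)) / 100 + 0.05
  origin <- c(-half, -half, 0)
  dims <- c(ceiling(2 * half / sp), ceiling(2 * half / sp), ceiling(zmax / sp))
  zs <- voxel_centers(origin[3], sp, dims[3])
  idx <- array(1L, dim = dims)
  z0 <- standoff_cm / 100
  rho <- get_material(material)$density
  if (thickness_cm > 0) {
    sel <- which(zs >= z0 & zs < z0 + thickness_cm / 100)
    if (!length(sel)) sel <- which.min(abs(zs - (z0 + thickness_cm / 200)))
    idx[, , sel] <- 2L
    # preserve the requested areal density exactly under voxelization
    rho <- rho * (thickness_cm / 100) / (length(sel) * sp)
  }
  materials <- tibble(code = 1:2, label = c("void", material),
                      base = c("air", material),
                      density = c(1e-9, rho))
  structure(list(origin = origin, spacing = sp, dims = dims, index = idx,
                 materials = materials, roi = list(),
                 meta = list(source = list(
                   type = if (beam == "pencil") 2L else 3L,
                   pos = c(0, 0, 1e-6), axis = c(0, 0, 1),
                   u = c(1, 0, 0), v = c(0, 1, 0),
                   half_x = half / 2, half_y = half / 2, sid = 1),
                   slab_exit_z = z0 + thickness_cm / 100,
                   fixture = list(name = "slab", material = material,
                                  thickness_cm = thickness_cm,
                                  spacing_cm = spacing_cm, beam = beam))),
            class = "fs_voxel_scene")
}

#' Uncollided transmission through a slab scene
#'
#' Runs a monoenergetic pencil beam through a [make_slab_scene()] and counts
#' the photons that escape beyond the slab exit plane without any real
#' interaction (first-interaction tagging excludes collided photons).
#'
#' @param scene A slab scene.
#' @param energy_keV Beam energy.
#' @param n_histories,seed Run size and seed.
#' @return A list: `transmission`, binomial `sigma`, `n`.
#' @export
measure_transmission <- function(scene, energy_keV = 60, n_histories = 2e4,
                                 seed = 1) {
  run <- run_config(n_histories, n_batches = 2, seed = seed)
  tal <- run_histories(scene, mono_spectrum(energy_keV), run,
                       record_escapes = TRUE, air_spacing_m = 0.1)
  esc <- tal$escapes
  ok <- esc[, 8] == 0 & esc[, 3] >= scene$meta$slab_exit_z & esc[, 6] > 0
  p <- sum(ok) / n_histories
  list(transmission = p, sigma = sqrt(p * (1 - p) / n_histories),
       n = n_histories)
}

#' Noisy synthetic calibration dataset
#'
#' Emulates the 12-condition measured-versus-simulated calibration data:
#' `measured = slope * simulated * (1 + eps)`, `eps ~ N(0, cv^2)`. The
#' simulated doses default to a stylized inverse-square times exponential
#' depth attenuation over the condition grid.
#'
#' @param true_slope True scaling factor.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed RNG seed (mandatory).
#' @param simulated Optional replacement for the simulated-dose vector.
#' @return A 12-row tibble (`condition_id`, `ssd_cm`, `depth_cm`,
#'   `simulated`, `measured`) with the generating parameters as attributes.
#' @export
#' @examples
#' make_noisy_calibration(1.10, 0.05, seed = 7)
make_noisy_calibration <- function(true_slope = 1.10, cv = 0.05, seed,
                                   simulated = NULL) {
  if (missing(seed)) abort("a seed is mandatory for stochastic fixtures")
  stopifnot(true_slope > 0, cv >= 0)
  cond <- generate_conditions()
  x <- simulated %||%
    ((60 / cond$ssd_cm)^2 * exp(-0.18 * cond$depth_cm))
  set.seed(seed)
  y <- true_slope * x * (1 + rnorm(length(x), 0, cv))
  out <- dplyr::mutate(cond, simulated = x, measured = y)
  attr(out, "fixture") <- list(name = "noisy_calibration",
                               true_slope = true_slope, cv = cv, seed = seed)
  out
}

#' Scaled-down operating-room study scene
#'
#' The full clinical scene with the room (and hence the air volume) shrunk
#' laterally by `scale`, while every clinically meaningful distance - SSD,
#' SID, field size, shield placement, staff stance and ROI heights - stays at
#' full scale. Ceiling height is kept so the standing phantom and ROI bands
#' are unaffected. The default spacing keeps the scene at or below two
#' million voxels.
#'
#' @param scale Lateral room scale factor in \[0.25, 1\].
#' @param spacing_m Voxel size.
#' @param shield_pattern,projection Passed to [scene_config()].
#' @param staff_on Include the staff phantom?
#' @return An `fs_scene_config`.
#' @export
#' @examples
#' cfg <- make_scaled_or_scene(0.5)
make_scaled_or_scene <- function(scale = 0.5, spacing_m = 0.05,
                                 shield_pattern = "absent",
                                 projection = "PA", staff_on = TRUE) {
  if (scale < 0.25 || scale > 1) abort("scale must lie in [0.25, 1]")
  cfg <- scene_config(room = c(8.1 * scale, 7.3 * scale, 3.4),
                      projection = projection,
                      shield = shield_spec(shield_pattern),
                      staff = list(height_cm = 160.8, stance_deg = 45,
                                   on = staff_on))
  attr(cfg, "fixture") <- list(name = "scaled_or_scene", scale = scale,
                               spacing_m = spacing_m,
                               shield_pattern = shield_pattern,
                               projection = projection)
  cfg
}

#' Near-vacuum point-source scene (inverse-square oracle)
#'
#' @param half_m Half-extent of the box.
#' @param spacing_m Voxel size.
#' @return An `fs_voxel_scene` with an isotropic point source at the centre.
#' @export
make_point_source_scene <- function(half_m = 1.0, spacing_m = 0.05) {
  n <- ceiling(2 * half_m / spacing_m)
  origin <- rep(-half_m, 3)
  idx <- array(1L, dim = c(n, n, n))
  materials <- tibble(code = 1L, label = "void", base = "air", density = 1e-9)
  structure(list(origin = origin, spacing = spacing_m, dims = c(n, n, n),
                 index = idx, materials = materials, roi = list(),
                 meta = list(source = list(
                   type = 1L, pos = c(0, 0, 0), axis = c(0, 0, 1),
                   u = c(1, 0, 0), v = c(0, 1, 0), half_x = 0, half_y = 0,
                   sid = 1),
                   fixture = list(name = "point_source", half_m = half_m))),
            class = "fs_voxel_scene")
}

#' Write a fixture manifest as JSON
#'
#' Records the name, parameters and seed that reproduce a fixture.
#'
#' @param fixture An object carrying a `fixture` attribute (or metadata).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fixture_manifest <- function(fixture, path) {
  meta <- attr(fixture, "fixture") %||% fixture$meta$fixture
  if (is.null(meta)) abort("object carries no fixture metadata")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fixture_manifest
#' @param path Manifest path.
#' @export
read_fixture_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
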