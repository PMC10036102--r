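#' Shield study configuration
#'
#' The full study design: every shield pattern crossed with every beam
#' projection on a common scene, one transport run per cell.
#'
#' @param base_config An `fs_scene_config` (typically from
#'   [make_scaled_or_scene()]); its shield pattern and projection are
#'   overridden per cell.
#' @param patterns Shield patterns to simulate.
#' @param projections Beam projections to simulate.
#' @param run An [run_config()]; cell c uses seed `seed + 97 * c`.
#' @param spacing_m Scene voxel size.
#' @param air_spacing_m Air-map grid spacing.
#' @param conversion An [dose_conversion()]; defaults to the clinical
#'   technique (3.0 mA) with scaling factor 1.10, taking `photons_per_mAs`
#'   from the study spectrum.
#' @param spectrum Source spectrum; defaults to the filtered 80 kVp clinical
#'   beam.
#' @param bands_cm Height bands for the air-map slices.
#' @return An `fs_study_config`.
#' @export
study_config <- function(base_config = make_scaled_or_scene(),
                         patterns = c("absent", "large", "small",
                                      "none_aperture"),
                         projections = c("PA", "cusp_overlap",
                                         "perpendicular"),
                         run = run_config(2e5, seed = 1),
                         spacing_m = 0.05, air_spacing_m = 0.05,
                         conversion = NULL, spectrum = NULL,
                         bands_cm = list(lens = c(145, 150),
                                         neck = c(130, 135),
                                         waist = c(80, 85))) {
  if (!length(patterns) || !length(projections))
    abort("need at least one pattern and one projection")
  spectrum <- spectrum %||%
    apply_filtration(generate_spectrum(80), technique_filtration())
  conversion <- conversion %||% dose_conversion(spectrum = spectrum)
  structure(list(base_config = base_config, patterns = patterns,
                 projections = projections, run = run, spacing_m = spacing_m,
                 air_spacing_m = air_spacing_m, conversion = conversion,
                 spectrum = spectrum, bands_cm = bands_cm),
            class = "fs_study_config")
}

#' Run the shield study
#'
#' One transport run per (pattern, projection) cell. Produces the ROI
#' dose-rate table over the staff surface regions, the air-map height slices
#' per cell, and a manifest recording the seed and all resolved parameters.
#'
#' @param study An [study_config()].
#' @param out_dir Optional directory; when given, the report (CSV), manifest
#'   (JSON) and per-cell slice maps (CSV) are written there.
#' @param keep_tallies Keep the full `fs_tally` objects (memory-hungry)?
#' @return An `fs_shield_study`: `report` (tibble), `maps` (nested list
#'   `[[pattern]][[projection]][[band]]`), `scenes`, `manifest`.
#' @export
run_shield_study <- function(study, out_dir = NULL, keep_tallies = FALSE) {
  cells <- expand.grid(pattern = study$patterns,
                       projection = study$projections,
                       stringsAsFactors = FALSE)
  report <- list(); maps <- list(); scenes <- list(); tallies <- list()
  for (ci in seq_len(nrow(cells))) {
    pat <- cells$pattern[ci]; prj <- cells$projection[ci]
    cfg <- study$base_config
    cfg$shield <- shield_spec(pat)
    cfg <- set_projection(cfg, prj)
    scene <- build_room_scene(cfg, study$spacing_m)
    run <- run_config(study$run$n_histories, study$run$n_batches,
                      seed = study$run$seed + 97 * ci,
                      cutoff_keV = study$run$cutoff_keV)
    tal <- tryCatch(
      run_histories(scene, study$spectrum, run,
                    air_spacing_m = study$air_spacing_m),
      error = function(e) abort(paste0("cell (", pat, ", ", prj,
                                       ") failed: ", conditionMessage(e))))
    rr <- roi_dose_rate(tal, study$conversion)
    rr$pattern <- pat; rr$projection <- prj
    report[[ci]] <- rr
    maps[[pat]][[prj]] <- lapply(study$bands_cm, function(b)
      height_slice_map(tal, b, study$conversion))
    scenes[[pat]] <- scene
    if (keep_tallies) tallies[[paste(pat, prj, sep = "/")]] <- tal
  }
  report <- dplyr::bind_rows(report)[, c("pattern", "projection", "roi",
                                         "n_voxels", "mass_kg",
                                         "dose_rate_uGy_h", "sigma_uGy_h")]
  manifest <- list(
    seed = study$run$seed, n_histories = study$run$n_histories,
    n_batches = study$run$n_batches, spacing_m = study$spacing_m,
    air_spacing_m = study$air_spacing_m,
    patterns = study$patterns, projections = study$projections,
    kvp = attr(study$spectrum, "kvp"),
    photons_per_mAs = attr(study$spectrum, "photons_per_mAs"),
    ma = study$conversion$ma, fps = study$conversion$fps,
    scaling_factor = study$conversion$scaling_factor,
    bands_cm = study$bands_cm,
    room_m = study$base_config$room,
    shield_voxels = vapply(scenes, function(s)
      sum(s$index == .scene_codes[["shield"]]), numeric(1)),
    package_version = as.character(utils::packageVersion("fluoroshield")))
  out <- structure(list(report = report, maps = maps, scenes = scenes,
                        tallies = if (keep_tallies) tallies,
                        manifest = manifest, study = study),
                   class = "fs_shield_study")
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

write_study_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$report, file.path(out_dir, "roi_dose_rates.csv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (pat in names(result$maps))
    for (prj in names(result$maps[[pat]]))
      for (band in names(result$maps[[pat]][[prj]]))
        write_dose_map_csv(result$maps[[pat]][[prj]][[band]],
                           file.path(out_dir, sprintf("airmap_%s_%s_%s.csv",
                                                      pat, prj, band)))
  invisible(out_dir)
}

#' @export
print.fs_shield_study <- function(x, ...) {
  cat(sprintf("<fs_shield_study> %d patterns x %d projections, %g histories/cell\n",
              length(x$study$patterns), length(x$study$projections),
              x$study$run$n_histories))
  print(x$report, n = 12)
  invisible(x)
}

#' Express a study report relative to a baseline shield pattern
#'
#' Each (projection, ROI) cell becomes `100 x dose / baseline dose`, with
#' first-order propagated sigma. A zero baseline flags the ratio as
#' undefined rather than failing.
#'
#' @param report The `report` tibble of an `fs_shield_study` (or the study).
#' @param baseline Baseline pattern name, default `"absent"`.
#' @return A tibble with `percent`, `sigma_percent` and `undefined_ratio`.
#' @export
compare_patterns <- function(report, baseline = "absent") {
  if (inherits(report, "fs_shield_study")) report <- report$report
  if (!baseline %in% report$pattern)
    abort(paste0("baseline pattern '", baseline, "' not in report"))
  base <- report[report$pattern == baseline,
                 c("projection", "roi", "dose_rate_uGy_h", "sigma_uGy_h")]
  names(base)[3:4] <- c("base_dose", "base_sigma")
  out <- dplyr::left_join(report, base, by = c("projection", "roi"))
  undef <- out$base_dose <= 0
  pct <- ifelse(undef, NA_real_, 100 * out$dose_rate_uGy_h / out$base_dose)
  sig <- ifelse(undef | out$dose_rate_uGy_h <= 0, NA_real_,
                abs(pct) * sqrt((out$sigma_uGy_h / out$dose_rate_uGy_h)^2 +
                                  (out$base_sigma / out$base_dose)^2))
  dplyr::mutate(out, percent = pct, sigma_percent = sig,
                undefined_ratio = undef)
}
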