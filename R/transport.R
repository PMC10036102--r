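#' Transport run configuration
#'
#' @param n_histories Number of source photons (>= `n_batches`).
#' @param n_batches Number of statistical batches (>= 2); batch b uses an
#'   independent substream derived from `seed`, so results depend only on
#'   `seed` and the configuration.
#' @param seed Integer run seed.
#' @param cutoff_keV Photon cut-off energy; photons falling below it deposit
#'   locally and die.
#' @param path_logging Record polyline trajectories for the first few hundred
#'   histories?
#' @return An `fs_run_config`.
#' @export
#' @examples
#' run_config(1e5, seed = 42)
run_config <- function(n_histories, n_batches = 10, seed = 1,
                       cutoff_keV = 5, path_logging = FALSE) {
  if (n_histories < 1) abort("need at least one history")
  if (n_batches < 2 || n_histories < n_batches)
    abort("need n_histories >= n_batches >= 2")
  structure(list(n_histories = as.double(n_histories),
                 n_batches = as.integer(n_batches),
                 seed = as.double(seed), cutoff_keV = cutoff_keV,
                 path_logging = isTRUE(path_logging)),
            class = "fs_run_config")
}

# energy grid the engine interpolates on
.engine_grid <- function() list(e0 = 5, de = 0.25, n = 581)

engine_tables <- function(scene) {
  g <- .engine_grid()
  en <- g$e0 + (seq_len(g$n) - 1) * g$de
  nm <- nrow(scene$materials)
  mu_lin <- matrix(0, g$n, nm)
  cph <- matrix(0, g$n, nm)
  cpi <- matrix(0, g$n, nm)
  for (i in seq_len(nm)) {
    base <- get_material(scene$materials$base[i])
    rho <- scene$materials$density[i]
    mu_lin[, i] <- lookup_mu(base, en) * rho * 100          # 1/m
    ph <- lookup_mu(base, en, "photo")
    ic <- lookup_mu(base, en, "incoh")
    co <- lookup_mu(base, en, "coh")
    tot <- ph + ic + co
    cph[, i] <- ph / tot
    cpi[, i] <- (ph + ic) / tot
  }
  list(mu_lin = mu_lin, cum_photo = cph, cum_pi = cpi,
       muen_air = lookup_mu("air", en, "en"), e0 = g$e0, de = g$de)
}

# default source description from the scene's projection geometry
scene_source <- function(scene) {
  src <- scene$meta$source
  if (!is.null(src)) return(src)
  pg <- projection_geometry(scene$meta$config)
  list(type = 0L, pos = pg$source_pos, axis = pg$axis, u = pg$u, v = pg$v,
       half_x = pg$half_x_m, half_y = pg$half_y_m, sid = pg$sid_m)
}

#' Run photon histories through a voxel scene
#'
#' Transports `n_histories` source photons by Woodcock delta tracking
#' (per-macro-cell majorants), sampling interactions from the embedded
#' cross-section tables: photoelectric absorption deposits the full photon
#' energy locally (electron transport suppressed), Compton scattering follows
#' the free-electron Klein-Nishina law (Kahn sampling) with local deposition
#' of the electron energy, and coherent scattering follows the Thomson angular
#' law. Energy deposition is scored per fine voxel (analog) and an air-kerma
#' track-length estimate is accumulated on a coarse co-registered grid.
#'
#' @param scene An `fs_voxel_scene`.
#' @param spectrum An `fs_spectrum` source spectrum.
#' @param run An [run_config()].
#' @param source Optional source override, a list with `type` (0 collimated
#'   point cone, 1 isotropic point, 2 pencil, 3 parallel beam), `pos`, `axis`,
#'   `u`, `v`, `half_x`, `half_y`, `sid`.
#' @param air_spacing_m Coarse air-map grid spacing (m).
#' @param macro Macro-cell size (voxels per side) for the local majorants.
#' @param record_escapes,record_first_coll Record escaping photons / distances
#'   to first real collision (capped; for verification studies).
#' @return An `fs_tally` with per-voxel batch statistics, ROI energy sums per
#'   batch, the air-kerma grid, an energy-conservation ledger per batch and
#'   run metadata.
#' @export
run_histories <- function(scene, spectrum, run, source = NULL,
                          air_spacing_m = 0.05, macro = 8L,
                          record_escapes = FALSE, record_first_coll = FALSE) {
  stopifnot(inherits(scene, "fs_voxel_scene"), inherits(run, "fs_run_config"))
  tabs <- engine_tables(scene)
  src <- source %||% scene_source(scene)
  src$type <- as.integer(src$type %||% 0L)
  src$sid <- src$sid %||% 1
  src$u <- src$u %||% c(1, 0, 0); src$v <- src$v %||% c(0, 1, 0)
  src$half_x <- src$half_x %||% 0; src$half_y <- src$half_y %||% 0

  edges <- c(spectrum$energy_low[1], spectrum$energy_high)
  cdf <- cumsum(spectrum$fluence) / sum(spectrum$fluence)

  nvox <- prod(scene$dims)
  roi_id <- integer(nvox)
  roi_names <- names(scene$roi)
  for (i in seq_along(scene$roi)) roi_id[scene$roi[[i]]] <- i

  ext <- scene$dims * scene$spacing
  air_dims <- pmax(as.integer(ceiling(round(ext / air_spacing_m, 9))), 1L)

  res <- mc_run_cpp(as.integer(scene$dims), scene$origin, scene$spacing,
                    as.integer(scene$index), nrow(scene$materials),
                    tabs$mu_lin, tabs$cum_photo, tabs$cum_pi, tabs$muen_air,
                    tabs$e0, tabs$de,
                    src, edges, cdf,
                    run$n_histories, run$n_batches, run$seed, run$cutoff_keV,
                    roi_id, length(scene$roi),
                    air_dims, scene$origin, air_spacing_m, as.integer(macro),
                    record_escapes, 200000L,
                    record_first_coll, 200000L,
                    if (run$path_logging) 500L else 0L)

  ledger <- as_tibble(as.data.frame(res$ledger))
  names(ledger) <- c("emitted_keV", "deposited_keV", "escaped_keV",
                     "corrupted_keV", "n_corrupted", "n_virtual", "n_real")
  ledger$batch <- seq_len(nrow(ledger))

  roi_batch <- res$roi_batch
  if (length(roi_names)) rownames(roi_batch) <- roi_names

  structure(list(
    scene = scene,
    fine_sum = array(res$fine_sum, dim = scene$dims),
    fine_sumsq = array(res$fine_sumsq, dim = scene$dims),
    air_sum = array(res$air_sum, dim = air_dims),
    air_sumsq = array(res$air_sumsq, dim = air_dims),
    air_spacing = air_spacing_m,
    roi_batch = roi_batch, ledger = ledger,
    escapes = res$escapes, first_coll = res$first_coll, paths = res$paths,
    run = run,
    spectrum_meta = list(kvp = attr(spectrum, "kvp"),
                         photons_per_mAs = attr(spectrum, "photons_per_mAs"),
                         mean_keV = mean_energy(spectrum))),
    class = "fs_tally")
}

#' @export
print.fs_tally <- function(x, ...) {
  led <- colSums(x$ledger[, 1:4])
  cat(sprintf("<fs_tally> %g histories in %d batches\n",
              x$run$n_histories, x$run$n_batches))
  cat(sprintf("  emitted %.4g keV | deposited %.4g (%.1f%%) | escaped %.4g | corrupted %g\n",
              led[1], led[2], 100 * led[2] / led[1], led[3],
              sum(x$ledger$n_corrupted)))
  invisible(x)
}

#' Energy-conservation check of a transport run
#'
#' @param tally An `fs_tally`.
#' @return A tibble per batch with the relative closure error
#'   `(emitted - deposited - escaped - corrupted) / emitted`.
#' @export
energy_ledger <- function(tally) {
  led <- tally$ledger
  led$closure_rel <- (led$emitted_keV - led$deposited_keV - led$escaped_keV -
                        led$corrupted_keV) / led$emitted_keV
  led
}

#' Klein-Nishina and Thomson angular sampling (verification helpers)
#'
#' Direct access to the engine's scattering-angle samplers.
#'
#' @param energy_keV Photon energy (keV).
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return `kn_sample()`: a tibble with `cos_theta` and the scattered
#'   `energy_out_keV`; `thomson_sample()`: numeric `cos_theta` samples.
#' @export
#' @examples
#' kn_sample(80, 5, seed = 1)
kn_sample <- function(energy_keV, n, seed = 1) {
  as_tibble(as.data.frame(kn_sample_cpp(energy_keV, as.integer(n),
                                        as.double(seed))))
}

#' @rdname kn_sample
#' @export
thomson_sample <- function(n, seed = 1) {
  thomson_sample_cpp(as.integer(n), as.double(seed))
}

#' Compton energy shift (closed form)
#'
#' `E' = E / (1 + (E/511)(1 - cos theta))`.
#'
#' @param energy_keV Incident energy (keV).
#' @param cos_theta Cosine of the scattering angle.
#' @return Scattered photon energy in keV.
#' @export
#' @examples
#' compton_shift(80, -1)
compton_shift <- function(energy_keV, cos_theta) {
  energy_keV / (1 + energy_keV / 510.99895 * (1 - cos_theta))
}

#' Sample interaction branches for a material
#'
#' @param material An `fs_material` or registry name.
#' @param energy_keV Photon energy (keV).
#' @param n Number of samples.
#' @param seed RNG seed (uses the R generator).
#' @return Character vector of `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`.
#' @export
sample_interaction <- function(material, energy_keV, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- interaction_probabilities(material, energy_keV)
  sample(c("photoelectric", "incoherent", "coherent"), n, replace = TRUE,
         prob = c(p$p_photoelectric, p$p_incoherent, p$p_coherent))
}
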