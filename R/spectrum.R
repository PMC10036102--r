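# Tungsten K lines (keV) and relative intensities used when kVp exceeds the
# K ionization threshold.
.w_k_lines <- tibble(
  energy_keV = c(59.318, 57.982, 67.244),
  line = c("Ka1", "Ka2", "Kb1"),
  rel = c(1.00, 0.57, 0.33))
.w_k_edge <- 69.525

new_spectrum <- function(tab, kvp, bin_keV, photons_per_mAs, output_uGy_mAs_1m,
                         field_side_m_at_1m) {
  structure(as_tibble(tab), class = c("fs_spectrum", class(tibble())),
            kvp = kvp, bin_keV = bin_keV, photons_per_mAs = photons_per_mAs,
            output_uGy_mAs_1m = output_uGy_mAs_1m,
            field_side_m_at_1m = field_side_m_at_1m)
}

spectrum_normalize <- function(spec) {
  spec$fluence <- spec$fluence / sum(spec$fluence)
  spec
}

# air kerma per unit fluence at each bin energy, Gy m^2 per photon
kerma_per_fluence <- function(energy_keV) {
  muen <- lookup_mu("air", energy_keV, "en") * 0.1   # cm^2/g -> m^2/kg
  energy_keV * 1.602176634e-16 * muen
}

photons_per_mAs_from_output <- function(spec, output_uGy_mAs_1m, field_side_m) {
  k <- sum(spec$fluence * kerma_per_fluence(spec$energy_keV)) / sum(spec$fluence)
  area <- field_side_m^2
  output_uGy_mAs_1m * 1e-6 * area / k
}

#' Generate a filtered bremsstrahlung tube spectrum
#'
#' Kramers-form bremsstrahlung `N(E) dE` proportional to `(kVp - E)/E`,
#' attenuated by the inherent aluminum filtration, with optional tungsten
#' K-characteristic lines added when the tube voltage exceeds the K edge
#' (69.5 keV). The absolute normalization `photons_per_mAs` (photons emitted
#' into the collimated field per mAs) is set from a nominal reference air-kerma
#' output at 1 m; absolute dose work relies on the measured-versus-simulated
#' calibration factor, not on this constant.
#'
#' @param kvp Tube peak voltage in kV, in \[40, 150\].
#' @param anode_angle_deg Anode angle (degrees); recorded as metadata.
#' @param inherent_filtration_mmAl Inherent filtration in mm of aluminum.
#' @param bin_keV Energy bin width (keV).
#' @param characteristic Add tungsten K lines above the K edge?
#' @param output_uGy_mAs_1m Nominal tube output (air kerma in uGy per mAs at
#'   1 m) used to set `photons_per_mAs`.
#' @param field_side_m_at_1m Side of the square collimated field at 1 m.
#' @return An `fs_spectrum`: a tibble of bins (`energy_low`, `energy_high`,
#'   `energy_keV` midpoint, normalized `fluence`) with attributes `kvp`,
#'   `photons_per_mAs`.
#' @export
#' @examples
#' sp <- generate_spectrum(80)
#' mean_energy(sp)
generate_spectrum <- function(kvp = 80, anode_angle_deg = 12,
                              inherent_filtration_mmAl = 1.0, bin_keV = 1,
                              characteristic = TRUE,
                              output_uGy_mAs_1m = 30,
                              field_side_m_at_1m = 0.1565) {
  if (!is.finite(kvp) || kvp < 40 || kvp > 150)
    abort("kvp must lie in [40, 150] kV")
  lo <- seq(5, kvp - bin_keV, by = bin_keV)
  hi <- lo + bin_keV
  mid <- (lo + hi) / 2
  w <- (kvp - mid) / mid
  mu_al <- lookup_mu("aluminum", mid) * get_material("aluminum")$density
  w <- w * exp(-mu_al * inherent_filtration_mmAl / 10)
  if (characteristic && kvp > .w_k_edge) {
    kfrac <- 0.6 * ((kvp - .w_k_edge) / kvp)^1.5
    ktot <- kfrac * sum(w)
    rel <- .w_k_lines$rel / sum(.w_k_lines$rel)
    for (i in seq_len(nrow(.w_k_lines))) {
      j <- findInterval(.w_k_lines$energy_keV[i], lo)
      w[j] <- w[j] + ktot * rel[i]
    }
  }
  tab <- tibble(energy_low = lo, energy_high = hi, energy_keV = mid,
                fluence = w / sum(w))
  spec <- new_spectrum(tab, kvp, bin_keV, NA_real_, output_uGy_mAs_1m,
                       field_side_m_at_1m)
  attr(spec, "anode_angle_deg") <- anode_angle_deg
  attr(spec, "photons_per_mAs") <-
    photons_per_mAs_from_output(spec, output_uGy_mAs_1m, field_side_m_at_1m)
  spec
}

#' @export
print.fs_spectrum <- function(x, ...) {
  cat(sprintf("<fs_spectrum> %g kVp, %d bins, mean %.1f keV, %.3g photons/mAs\n",
              attr(x, "kvp"), nrow(x), mean_energy(x), attr(x, "photons_per_mAs")))
  NextMethod()
}

#' Build a filtration stack
#'
#' @param material Character vector of registry material names.
#' @param thickness_mm Layer thicknesses in mm (non-negative).
#' @return A tibble with columns `material`, `thickness_mm`.
#' @export
#' @examples
#' technique_filtration()
filtration_stack <- function(material = character(), thickness_mm = numeric()) {
  stopifnot(length(material) == length(thickness_mm))
  if (any(thickness_mm < 0)) abort("filtration thicknesses must be >= 0")
  tibble(material = material, thickness_mm = thickness_mm)
}

#' @describeIn filtration_stack The clinical added filtration used throughout:
#'   2.5 mm Al + 0.4 mm Cu + 1.0 mm Al.
#' @export
technique_filtration <- function() {
  filtration_stack(c("aluminum", "copper", "aluminum"), c(2.5, 0.4, 1.0))
}

#' Clinical fluoroscopy technique factors
#'
#' The pulsed-fluoroscopy technique used for all study scenes: 80 kVp,
#' 3.0 mA (time-averaged), 3.75 frames/s, 156.5 mm square field at the
#' receptor, SSD 60 cm, SID 100 cm, added filtration 2.5 mmAl + 0.4 mmCu +
#' 1.0 mmAl.
#'
#' @return A named list of technique factors.
#' @export
fluoro_technique <- function() {
  list(kvp = 80, ma = 3.0, fps = 3.75, field_mm = 156.5,
       ssd_m = 0.60, sid_m = 1.00, filtration = technique_filtration())
}

#' Attenuate a spectrum through a filtration stack
#'
#' Each bin is scaled by `exp(-sum_i mu_i(E) t_i)`; the fluence weights are
#' renormalized and `photons_per_mAs` is recomputed from the nominal output
#' model for the transmitted beam.
#'
#' @param spectrum An `fs_spectrum`.
#' @param stack A [filtration_stack()].
#' @return The filtered `fs_spectrum`.
#' @export
#' @examples
#' sp <- apply_filtration(generate_spectrum(80), technique_filtration())
apply_filtration <- function(spectrum, stack) {
  stack <- as_tibble(stack)
  w <- spectrum$fluence
  for (i in seq_len(nrow(stack))) {
    m <- get_material(stack$material[i])
    mu <- lookup_mu(m, spectrum$energy_keV) * m$density
    w <- w * exp(-mu * stack$thickness_mm[i] / 10)
  }
  spectrum$fluence <- w / sum(w)
  attr(spectrum, "photons_per_mAs") <- photons_per_mAs_from_output(
    spectrum, attr(spectrum, "output_uGy_mAs_1m"),
    attr(spectrum, "field_side_m_at_1m"))
  spectrum
}

#' Fluence-weighted mean energy of a spectrum (keV)
#' @param spectrum An `fs_spectrum`.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$fluence * spectrum$energy_keV) / sum(spectrum$fluence)
}

#' Half-value layer of a beam
#'
#' Thickness of `material` halving the air-kerma-weighted transmitted
#' fraction, found by bracketed root search to 0.01 mm.
#'
#' @param spectrum An `fs_spectrum`.
#' @param material Absorber (registry name or `fs_material`), default aluminum.
#' @return Thickness in mm.
#' @export
#' @examples
#' half_value_layer(generate_spectrum(80))
half_value_layer <- function(spectrum, material = "aluminum") {
  if (nrow(spectrum) == 0) abort("empty spectrum")
  if (is.character(material)) material <- get_material(material)
  mu <- lookup_mu(material, spectrum$energy_keV) * material$density
  kw <- spectrum$fluence * kerma_per_fluence(spectrum$energy_keV)
  trans <- function(t_mm) sum(kw * exp(-mu * t_mm / 10)) / sum(kw) - 0.5
  if (trans(100) > 0) abort("no half-value bracket within [0, 100] mm")
  uniroot(trans, c(0, 100), tol = 1e-3)$root
}

#' Sample photon energies from a spectrum
#'
#' Inverse-CDF sampling over the bins, uniform within a bin. Uses the R
#' random number generator; fix the seed with [set.seed()] for reproducibility.
#'
#' @param spectrum An `fs_spectrum`.
#' @param n Number of samples (>= 1).
#' @return Numeric vector of energies in keV.
#' @export
#' @examples
#' set.seed(1); head(sample_energy(generate_spectrum(80), 5))
sample_energy <- function(spectrum, n) {
  stopifnot(n >= 1)
  cdf <- cumsum(spectrum$fluence) / sum(spectrum$fluence)
  j <- findInterval(runif(n), c(0, utils::head(cdf, -1)))
  spectrum$energy_low[j] + runif(n) * (spectrum$energy_high[j] -
                                         spectrum$energy_low[j])
}

#' Read / write a spectrum as two-column CSV
#'
#' Columns `energy_keV` (bin midpoints, uniform spacing) and
#' `relative_fluence`, so externally generated spectra can replace the
#' built-in model.
#'
#' @param path File path.
#' @param spectrum An `fs_spectrum` (for writing).
#' @param ... Passed to [generate_spectrum()]-style metadata: `kvp` (defaults
#'   to the highest bin edge), `output_uGy_mAs_1m`, `field_side_m_at_1m`.
#' @return `read_spectrum_csv()` returns an `fs_spectrum`;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, ...) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("energy_keV", "relative_fluence") %in% names(tab)))
  dots <- list(...)
  bw <- if (nrow(tab) > 1) stats::median(diff(tab$energy_keV)) else 1
  kvp <- dots$kvp %||% (max(tab$energy_keV) + bw / 2)
  out <- dots$output_uGy_mAs_1m %||% 30
  fld <- dots$field_side_m_at_1m %||% 0.1565
  spec <- new_spectrum(
    tibble(energy_low = tab$energy_keV - bw / 2,
           energy_high = tab$energy_keV + bw / 2,
           energy_keV = tab$energy_keV,
           fluence = tab$relative_fluence / sum(tab$relative_fluence)),
    kvp, bw, NA_real_, out, fld)
  attr(spec, "photons_per_mAs") <- photons_per_mAs_from_output(spec, out, fld)
  spec
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(energy_keV = spectrum$energy_keV,
                              relative_fluence = spectrum$fluence),
                   path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
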