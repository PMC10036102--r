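#' @useDynLib fluoroshield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif sd var quantile coef lm optimize uniroot
#' @importFrom utils head tail
NULL

.fs_env <- new.env(parent = emptyenv())

# canonical registry: name -> density (g/cm^3) and elemental mass fractions.
# Tissues follow the ICRU reference compositions; concrete is ordinary concrete;
# lead-equivalent acrylic is modelled as the stated 1 mm lead equivalence.
.fs_materials_meta <- list(
  water       = list(density = 1.000,    comp = c(H = 0.1119, O = 0.8881)),
  air         = list(density = 1.205e-3, comp = c(C = 0.000124, N = 0.755267,
                                                  O = 0.231781, Ar = 0.012828)),
  lead        = list(density = 11.35,    comp = c(Pb = 1)),
  lead_acrylic = list(density = 11.35,   comp = c(Pb = 1)),
  aluminum    = list(density = 2.699,    comp = c(Al = 1)),
  copper      = list(density = 8.960,    comp = c(Cu = 1)),
  concrete    = list(density = 2.300,    comp = c(H = 0.010, C = 0.001,
                     O = 0.529107, Na = 0.016, Mg = 0.002, Al = 0.033872,
                     Si = 0.337021, K = 0.013, Ca = 0.044, Fe = 0.014)),
  eye_lens    = list(density = 1.07, comp = c(H = 0.096, C = 0.195, N = 0.057,
                     O = 0.646, Na = 0.001, P = 0.001, S = 0.003, Cl = 0.001)),
  bone        = list(density = 1.92, comp = c(H = 0.034, C = 0.155, N = 0.042,
                     O = 0.435, Na = 0.001, Mg = 0.002, P = 0.103, S = 0.003,
                     Ca = 0.225)),
  skin        = list(density = 1.09, comp = c(H = 0.100, C = 0.204, N = 0.042,
                     O = 0.645, Na = 0.002, P = 0.001, S = 0.002, Cl = 0.003,
                     K = 0.001)),
  soft_tissue = list(density = 1.06, comp = c(H = 0.102, C = 0.143, N = 0.034,
                     O = 0.708, Na = 0.002, P = 0.003, S = 0.003, Cl = 0.002,
                     K = 0.003))
)

.fs_element_density <- c(
  H = 8.375e-5, C = 2.000, N = 1.165e-3, O = 1.332e-3, Na = 0.971, Mg = 1.740,
  Al = 2.699, Si = 2.330, P = 2.200, S = 2.067, Cl = 2.995e-3, Ar = 1.662e-3,
  K = 0.862, Ca = 1.550, Fe = 7.874, Cu = 8.960, Pb = 11.35)

.fs_registry <- names(.fs_materials_meta)

#' List the built-in material registry
#'
#' @return A tibble with one row per registered material: `name`, mass
#'   `density` in g/cm^3 and the number of constituent elements.
#' @export
#' @examples
#' fs_materials()
fs_materials <- function() {
  tibble(
    name = .fs_registry,
    density = vapply(.fs_materials_meta, function(m) m$density, numeric(1)),
    n_elements = vapply(.fs_materials_meta, function(m) length(m$comp), integer(1))
  )
}

xs_file <- function(stem) {
  path <- system.file("extdata", "xs", stem, package = "fluoroshield")
  if (!nzchar(path)) abort(paste0("attenuation table not found: ", stem))
  path
}

read_xs_table <- function(stem) {
  key <- paste0("xs_", stem)
  if (!is.null(.fs_env[[key]])) return(.fs_env[[key]])
  tab <- utils::read.csv(xs_file(stem))
  stopifnot(all(diff(tab$energy_keV) > 0))
  .fs_env[[key]] <- tab
  tab
}

new_fs_material <- function(name, density, composition, table) {
  structure(list(name = name, density = density,
                 composition = composition, table = as_tibble(table)),
            class = "fs_material")
}

validate_material <- function(m) {
  stopifnot(inherits(m, "fs_material"))
  if (m$density <= 0) abort("material density must be > 0")
  if (nrow(m$composition) < 1) abort("material needs at least one element")
  if (abs(sum(m$composition$fraction) - 1) > 1e-6)
    abort("element mass fractions must sum to 1 within 1e-6")
  invisible(m)
}

#' Retrieve a material from the registry
#'
#' Materials carry a mass density, an elemental composition by mass fraction and
#' an attenuation table (`energy_keV`, `mu_total`, `mu_en`, `mu_photo`,
#' `mu_incoh`, `mu_coh`, all mass coefficients in cm^2/g) spanning 5-150 keV.
#' Element symbols (`"H"`, `"O"`, `"Pb"`, ...) are also accepted so that
#' elemental mixtures can be assembled with [mixture_mu()] or [fs_material()].
#'
#' @param name One of `fs_materials()$name` or an element symbol.
#' @return An object of class `fs_material`.
#' @export
#' @examples
#' w <- get_material("water")
#' w$density
get_material <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  key <- paste0("mat_", name)
  if (!is.null(.fs_env[[key]])) return(.fs_env[[key]])
  if (name %in% .fs_registry) {
    meta <- .fs_materials_meta[[name]]
    tab <- read_xs_table(paste0("material_", name, ".csv"))
    m <- new_fs_material(name, meta$density,
                         tibble(element = names(meta$comp),
                                fraction = unname(meta$comp)), tab)
  } else if (name %in% names(.fs_element_density)) {
    tab <- read_xs_table(paste0("element_", name, ".csv"))
    m <- new_fs_material(name, unname(.fs_element_density[[name]]),
                         tibble(element = name, fraction = 1), tab)
  } else {
    abort(paste0("unknown material '", name, "'; valid names: ",
                 paste(.fs_registry, collapse = ", "),
                 " (or an element symbol ",
                 paste(names(.fs_element_density), collapse = " "), ")"))
  }
  validate_material(m)
  .fs_env[[key]] <- m
  m
}

#' @export
print.fs_material <- function(x, ...) {
  cat("<fs_material>", x$name, sprintf("(%.4g g/cm^3)\n", x$density))
  cat("  elements:", paste(sprintf("%s %.4g", x$composition$element,
                                   x$composition$fraction), collapse = ", "), "\n")
  cat("  table:", nrow(x$table), "energies,",
      sprintf("%.4g-%.4g keV\n", min(x$table$energy_keV), max(x$table$energy_keV)))
  invisible(x)
}

#' Construct a custom material from an elemental composition
#'
#' The attenuation table is assembled from the packaged element tables by
#' mass-fraction additivity on the union of the element energy grids.
#'
#' @param name Label for the material.
#' @param density Mass density in g/cm^3.
#' @param composition A data frame with columns `element` (symbol) and
#'   `fraction` (mass fraction, summing to 1).
#' @return An `fs_material`.
#' @export
#' @examples
#' fs_material("thin_air", 1.205e-9, get_material("air")$composition)
fs_material <- function(name, density, composition) {
  composition <- as_tibble(composition)
  stopifnot(all(c("element", "fraction") %in% names(composition)))
  tabs <- lapply(composition$element, function(e) get_material(e)$table)
  grid <- sort(unique(unlist(lapply(tabs, function(t) t$energy_keV))))
  grid <- grid[grid >= 5 & grid <= 150]
  cols <- c("mu_total", "mu_en", "mu_photo", "mu_incoh", "mu_coh")
  mixed <- matrix(0, length(grid), length(cols), dimnames = list(NULL, cols))
  for (i in seq_along(tabs)) {
    for (cn in cols) {
      mixed[, cn] <- mixed[, cn] + composition$fraction[i] *
        loglog_interp(grid, tabs[[i]]$energy_keV, tabs[[i]][[cn]])
    }
  }
  m <- new_fs_material(name, density, composition,
                       cbind(tibble(energy_keV = grid), as_tibble(mixed)))
  validate_material(m)
  m
}

loglog_interp <- function(x, xp, fp) {
  exact <- match(x, xp)
  out <- exp(stats::approx(log(xp), log(pmax(fp, 1e-300)), xout = log(x),
                           rule = 2)$y)
  hit <- !is.na(exact)
  out[hit] <- fp[exact[hit]]
  out
}

check_energy_range <- function(energy) {
  if (any(!is.finite(energy)) || any(energy < 5) || any(energy > 150))
    abort("energy must lie in [5, 150] keV")
  invisible(energy)
}

#' Mass attenuation coefficient lookup
#'
#' Log-log interpolation between bracketing grid points; energies that fall on
#' a grid node return the stored value exactly.
#'
#' @param material An `fs_material` (or registry name).
#' @param energy Photon energy (keV), vectorized; must lie in \[5, 150\].
#' @param quantity One of `"total"`, `"en"` (energy absorption), `"photo"`,
#'   `"incoh"`, `"coh"`.
#' @return Mass coefficient(s) in cm^2/g.
#' @export
#' @examples
#' lookup_mu(get_material("water"), 60)
lookup_mu <- function(material, energy,
                      quantity = c("total", "en", "photo", "incoh", "coh")) {
  if (is.character(material)) material <- get_material(material)
  quantity <- match.arg(quantity)
  check_energy_range(energy)
  col <- paste0("mu_", sub("^en$", "en", quantity))
  loglog_interp(energy, material$table$energy_keV, material$table[[col]])
}

#' Mass-fraction mixture rule for attenuation coefficients
#'
#' @param components A data frame with columns `material` (an `fs_material`
#'   list-column or a character registry name) and `fraction` (mass fractions
#'   summing to 1).
#' @param energy Photon energy (keV), vectorized.
#' @param quantity Coefficient selector, as in [lookup_mu()].
#' @return Mixture mass coefficient(s) in cm^2/g.
#' @export
#' @examples
#' mixture_mu(tibble::tibble(material = c("H", "O"),
#'                           fraction = c(0.1119, 0.8881)), 60)
mixture_mu <- function(components, energy,
                       quantity = c("total", "en", "photo", "incoh", "coh")) {
  quantity <- match.arg(quantity)
  components <- as_tibble(components)
  if (abs(sum(components$fraction) - 1) > 1e-6)
    abort("mixture fractions must sum to 1 within 1e-6")
  mats <- components$material
  if (is.character(mats)) mats <- lapply(mats, get_material)
  out <- 0
  for (i in seq_along(mats))
    out <- out + components$fraction[i] * lookup_mu(mats[[i]], energy, quantity)
  out
}

#' Interaction branch probabilities
#'
#' Normalized probabilities of the photoelectric, incoherent (Compton) and
#' coherent (Rayleigh) branches, proportional to the partial coefficients.
#'
#' @inheritParams lookup_mu
#' @return A tibble with columns `energy_keV`, `p_photoelectric`,
#'   `p_incoherent`, `p_coherent` (each row sums to 1).
#' @export
#' @examples
#' interaction_probabilities(get_material("lead"), 60)
interaction_probabilities <- function(material, energy) {
  if (is.character(material)) material <- get_material(material)
  check_energy_range(energy)
  ph <- lookup_mu(material, energy, "photo")
  ic <- lookup_mu(material, energy, "incoh")
  co <- lookup_mu(material, energy, "coh")
  tot <- ph + ic + co
  tibble(energy_keV = energy, p_photoelectric = ph / tot,
         p_incoherent = ic / tot, p_coherent = co / tot)
}
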