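# shared, lazily built fixtures (cached for the whole test session)
.fs_test_cache <- new.env(parent = emptyenv())

fs_cached <- function(name, expr) {
  if (is.null(.fs_test_cache[[name]])) .fs_test_cache[[name]] <- force(expr)
  .fs_test_cache[[name]]
}

test_beam <- function() {
  fs_cached("beam",
            apply_filtration(generate_spectrum(80), technique_filtration()))
}

test_conversion <- function() dose_conversion(spectrum = test_beam())

# the PA shield study shared by the heavy acceptance checks: one transport run
# per shield pattern on the half-scale operating-room scene
shield_study_pa <- function() {
  fs_cached("study_pa", {
    beam <- test_beam()
    conv <- test_conversion()
    out <- list(tallies = list(), report = list(), maps = list(),
                scenes = list())
    for (pat in c("absent", "large", "small", "none_aperture")) {
      cfg <- make_scaled_or_scene(0.5, shield_pattern = pat)
      sc <- build_room_scene(cfg, 0.05)
      tal <- run_histories(sc, beam, run_config(2e6, seed = 20260))
      rr <- roi_dose_rate(tal, conv)
      rr <- dplyr::bind_rows(
        rr, roi_union_dose_rate(tal, conv, c("lens_left", "lens_right"),
                                "lens_band"))
      rr$pattern <- pat
      out$tallies[[pat]] <- tal
      out$report[[pat]] <- rr
      out$maps[[pat]] <- height_slice_map(tal, c(145, 150), conv)
      out$scenes[[pat]] <- sc
    }
    out$report <- dplyr::bind_rows(out$report)
    out
  })
}

study_dose <- function(study, pat, roi_name) {
  r <- study$report
  r[r$pattern == pat & r$roi == roi_name, ]
}

# ordering within 2 sigma: a >= b, allowing a shortfall of at most 2 sigma
expect_ordered_2sig <- function(a, b) {
  diff <- a$dose_rate_uGy_h - b$dose_rate_uGy_h
  sig <- sqrt(a$sigma_uGy_h^2 + b$sigma_uGy_h^2)
  expect_gte(diff, -2 * sig)
}

# numerically integrated Klein-Nishina CDF of cos(theta) at a given energy
kn_numeric_cdf <- function(energy_keV, n_grid = 4001) {
  k <- energy_keV / 510.99895
  mu <- seq(-1, 1, length.out = n_grid)
  x <- 1 + k * (1 - mu)
  r <- 1 / x
  pdf <- r^2 * (r + 1 / r - (1 - mu^2))
  cum <- c(0, cumsum((pdf[-1] + pdf[-n_grid]) / 2 * diff(mu)))
  stats::approxfun(mu, cum / cum[n_grid], yleft = 0, yright = 1)
}
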