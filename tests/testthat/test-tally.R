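# a minimal hand-built tally for unit arithmetic: one-voxel-cube scenes
fake_tally <- function(fine_keV, spacing_m, material = "water",
                       n_hist = 1, n_batches = 2) {
  dims <- dim(fine_keV)
  scene <- structure(list(
    origin = c(0, 0, 0), spacing = spacing_m, dims = dims, index = array(
      1L, dims),
    materials = tibble::tibble(code = 1L, label = material, base = material,
                               density = get_material(material)$density),
    roi = list(), meta = list()), class = "fs_voxel_scene")
  structure(list(scene = scene, fine_sum = fine_keV,
                 fine_sumsq = fine_keV^2 / n_batches,
                 air_sum = fine_keV, air_sumsq = fine_keV^2 / n_batches,
                 air_spacing = spacing_m,
                 roi_batch = matrix(0, 1, n_batches), ledger = NULL,
                 run = list(n_histories = n_hist, n_batches = n_batches)),
            class = "fs_tally")
}

test_that("dose per photon is exact unit arithmetic", {
  # 1 keV into a 1 g (1 cm^3 water) voxel over 1 history
  tal <- fake_tally(array(1, c(1, 1, 1)), 0.01)
  expect_equal(dose_per_photon(tal, c(1, 1, 1)), 1.602176634e-13)
  expect_equal(dose_per_photon(fake_tally(array(0, c(1, 1, 1)), 0.01),
                               c(1, 1, 1)), 0)
  tal2 <- fake_tally(array(1, c(1, 1, 1)), 0.01, n_hist = 2)
  expect_equal(dose_per_photon(tal2, 1), dose_per_photon(tal, 1) / 2)
})

test_that("dose-rate conversion follows the duty and scaling model", {
  cv <- dose_conversion(photons_per_mAs = 1e6, ma = 3.0, scaling_factor = 1.10)
  expect_equal(to_dose_rate(1e-12, cv), 1.188e4)
  unit <- dose_conversion(photons_per_mAs = 1, ma = 1 / 3600,
                          scaling_factor = 1)
  expect_equal(to_dose_rate(1, unit), 1e6)    # pure Gy -> uGy conversion
  expect_equal(to_dose_rate(2e-12, cv), 2 * to_dose_rate(1e-12, cv))
  cv2 <- dose_conversion(photons_per_mAs = 1e6, ma = 6.0,
                         scaling_factor = 2.20)
  expect_equal(to_dose_rate(1e-12, cv2), 4 * to_dose_rate(1e-12, cv))
  expect_error(to_dose_rate(1e-12, NULL), "calibration")
  expect_error(dose_conversion(), "calibration")
})

test_that("segment chords partition the segment length", {
  g <- list(dims = c(10, 10, 10), origin = c(0, 0, 0), sp = 0.1)
  inside <- segment_chords(c(0.51, 0.52, 0.53), c(0.55, 0.56, 0.57),
                           g$dims, g$origin, g$sp)
  expect_equal(nrow(inside), 1)
  expect_equal(inside$chord_m, sqrt(3 * 0.04^2))
  ax <- segment_chords(c(0.05, 0.55, 0.55), c(0.65, 0.55, 0.55),
                       g$dims, g$origin, g$sp)
  expect_equal(nrow(ax), 7)
  expect_equal(sum(ax$chord_m), 0.6, tolerance = 1e-9)
  expect_equal(max(ax$chord_m[2:6]), 0.1, tolerance = 1e-9)
  diagonal <- segment_chords(c(0.05, 0.05, 0.05), c(0.95, 0.95, 0.95),
                             g$dims, g$origin, g$sp)
  expect_equal(sum(diagonal$chord_m), sqrt(3) * 0.9, tolerance = 1e-9)
})

test_that("track-length kerma agrees with analog scoring at lower variance", {
  sc <- make_slab_scene("air", thickness_cm = 40, spacing_cm = 4,
                        lateral_cm = 60, beam = "parallel", standoff_cm = 4)
  tal <- run_histories(sc, mono_spectrum(60), run_config(4e5, seed = 8),
                       air_spacing_m = 0.04)
  msk <- array(FALSE, sc$dims)
  msk[4:12, 4:12, 3:11] <- TRUE
  vol <- (0.04 * 100)^3
  rho <- get_material("air")$density
  B <- tal$run$n_batches
  analog <- mean(tal$fine_sum[msk]) / (vol * rho)
  tl <- mean(tal$air_sum[msk]) / vol
  va <- pmax(tal$fine_sumsq - tal$fine_sum^2 / B, 0) / (B - 1) * B
  vt <- pmax(tal$air_sumsq - tal$air_sum^2 / B, 0) / (B - 1) * B
  sig <- sqrt(sum(va[msk]) / (vol * rho)^2 + sum(vt[msk]) / vol^2) / sum(msk)
  expect_lt(abs(analog - tl), 3 * sig)
  sel <- msk & tal$fine_sum > 0
  var_ratio <- stats::median(va[sel] / (vol * rho)^2 / (vt[sel] / vol^2))
  expect_gt(var_ratio, 5)
})

test_that("ROI dose rates are mass-weighted with batch-based uncertainty", {
  sc <- fluoroshield:::make_calibration_scene(60, 5)
  # widen the scorer: add a second disjoint ROI and a union
  ix <- sc$roi$dosimeter
  sc$roi$second <- ix + 1L
  tal <- run_histories(sc, test_beam(), run_config(4e4, seed = 9),
                       air_spacing_m = 0.1)
  conv <- test_conversion()
  rr <- roi_dose_rate(tal, conv)
  expect_setequal(rr$roi, c("dosimeter", "second"))
  expect_true(all(rr$sigma_uGy_h >= 0))
  un <- roi_union_dose_rate(tal, conv, c("dosimeter", "second"), "both")
  manual <- sum(rr$dose_rate_uGy_h * rr$mass_kg) / sum(rr$mass_kg)
  expect_equal(un$dose_rate_uGy_h, manual, tolerance = 1e-9)
  expect_error(roi_dose_rate(tal, conv, roi = "nope"), "unknown ROI")
  # uniform synthetic batches: ROI mean equals the voxel dose, sigma ~ 0
  tal$roi_batch[1, ] <- 100
  one <- roi_dose_rate(tal, conv, roi = "dosimeter")
  expect_equal(one$sigma_uGy_h, 0)
})

test_that("batch sigma agrees with a bootstrap over batches", {
  sc <- fluoroshield:::make_calibration_scene(60, 5)
  tal <- run_histories(sc, test_beam(), run_config(2e5, seed = 12),
                       air_spacing_m = 0.1)
  vals <- tal$roi_batch[1, ]
  se_batch <- stats::sd(vals) / sqrt(length(vals))
  set.seed(1)
  boots <- replicate(4000, mean(sample(vals, replace = TRUE)))
  se_boot <- stats::sd(boots)
  # the n/(n-1) bootstrap bias keeps these within a few percent of each other
  expect_lt(abs(se_boot / se_batch - 1), 0.2)
})

test_that("height slices select the half-open voxel layers", {
  # floor-origin 5 cm grid: band 145-150 cm is exactly one layer (the 30th)
  tal <- fake_tally(array(1, c(4, 4, 40)), 0.05)
  conv <- dose_conversion(photons_per_mAs = 1, ma = 1, scaling_factor = 1)
  m <- height_slice_map(tal, c(145, 150), conv)
  expect_equal(attr(m, "n_layers"), 1L)
  expect_equal(nrow(m), 16)
  # uniform tally -> spatially constant map
  expect_equal(max(m$dose_rate_uGy_h), min(m$dose_rate_uGy_h))
  expect_error(height_slice_map(tal, c(300, 310), conv), "band")
  expect_equal(area_above(m, level_uGy_h = max(m$dose_rate_uGy_h) * 2), 0)
  expect_equal(area_above(m, level_uGy_h = 0), 16 * 0.05^2)
})

test_that("unshielded air maps decrease with distance from the beam axis", {
  study <- shield_study_pa()
  m <- study$maps[["absent"]]
  cfg <- study$scenes[["absent"]]$meta$config
  cx <- cfg$room[1] / 2; cy <- cfg$room[2] / 2
  r <- sqrt((m$x_m - cx)^2 + (m$y_m - cy)^2)
  rings <- cut(r, breaks = seq(0.5, 1.8, by = 0.26))
  mu <- tapply(m$dose_rate_uGy_h, rings, mean)
  se <- tapply(seq_along(r), rings, function(i)
    sqrt(sum(m$sigma_uGy_h[i]^2)) / length(i))
  for (i in seq_len(length(mu) - 1))
    expect_gt(mu[i] - mu[i + 1], -2 * sqrt(se[i]^2 + se[i + 1]^2))
})

test_that("PA air maps without staff or shield are mirror-symmetric", {
  beam <- test_beam()
  sc <- build_room_scene(make_scaled_or_scene(0.5, staff_on = FALSE), 0.05)
  tal <- run_histories(sc, beam, run_config(1e6, seed = 13))
  m <- height_slice_map(tal, c(145, 150), test_conversion())
  d <- matrix(m$dose_rate_uGy_h, attr(m, "dims")[1])
  s <- matrix(m$sigma_uGy_h, attr(m, "dims")[1])
  ny <- ncol(d)
  z <- (d - d[, ny:1]) / sqrt(s^2 + s[, ny:1]^2 + 1e-300)
  expect_gt(mean(abs(z) < 3, na.rm = TRUE), 0.97)
})

test_that("analog tally totals equal the transport deposition ledger", {
  sc <- make_slab_scene("water", thickness_cm = 10, spacing_cm = 1,
                        lateral_cm = 40)
  tal <- run_histories(sc, test_beam(), run_config(2e4, seed = 14))
  expect_equal(sum(tal$fine_sum), sum(tal$ledger$deposited_keV),
               tolerance = 1e-12)
})

test_that("NRRD and CSV exports round-trip the essentials", {
  arr <- array(seq_len(24) * 1.5, c(2, 3, 4))
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(arr, f, 0.05, c(-0.1, -0.1, 0))
  lines <- readLines(f)
  expect_equal(lines[1], "NRRD0004")
  expect_true(any(grepl("sizes: 2 3 4", lines)))
  vals <- scan(text = lines[length(lines)], quiet = TRUE)
  expect_equal(vals, as.vector(arr))
  tal <- fake_tally(array(1, c(4, 4, 40)), 0.05)
  m <- height_slice_map(tal, c(145, 150),
                        dose_conversion(photons_per_mAs = 1, ma = 1,
                                        scaling_factor = 1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dose_map_csv(m, f2)
  back <- readr::read_csv(f2, show_col_types = FALSE)
  expect_equal(back$dose_rate_uGy_h, m$dose_rate_uGy_h)
})
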