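test_that("zero-intercept fit has the closed-form slope", {
  f <- fit_zero_intercept(simulated = c(1, 2), measured = c(1.10, 2.20))
  expect_equal(f$slope, 1.10)
  expect_equal(f$pearson_r, 1)
  expect_equal(f$r_squared, 1)
  z <- fit_zero_intercept(simulated = c(1, 2, 3), measured = c(0, 0, 0))
  expect_equal(z$slope, 0)
  expect_error(fit_zero_intercept(simulated = c(0, 0), measured = c(1, 2)),
               "degenerate")
  expect_error(fit_zero_intercept(simulated = 1, measured = 1), "at least 2")
  # slope matches brute-force 1-D least squares
  set.seed(42)
  x <- runif(12, 0.5, 3); y <- 1.3 * x * (1 + rnorm(12, 0, 0.1))
  f2 <- fit_zero_intercept(simulated = x, measured = y)
  brute <- stats::optimize(function(s) sum((y - s * x)^2), c(0, 10),
                           tol = 1e-12)$minimum
  expect_lt(abs(f2$slope - brute), 1e-8)
  # r_squared is the square of Pearson's r by definition
  expect_equal(f2$r_squared, stats::cor(x, y)^2, tolerance = 1e-12)
})

test_that("fit is scale-equivariant and correlation scale-invariant", {
  set.seed(3)
  x <- runif(12, 0.2, 2); y <- 0.8 * x + rnorm(12, 0, 0.02)
  f <- fit_zero_intercept(simulated = x, measured = y)
  f2 <- fit_zero_intercept(simulated = x, measured = 5 * y)
  expect_equal(f2$slope, 5 * f$slope, tolerance = 1e-12)
  expect_equal(f2$pearson_r, f$pearson_r, tolerance = 1e-12)
  f3 <- fit_zero_intercept(simulated = 2 * x, measured = y)
  expect_equal(f3$pearson_r, f$pearson_r, tolerance = 1e-12)
})

test_that("the calibration design is the fixed 12-condition grid", {
  cond <- generate_conditions()
  expect_equal(nrow(cond), 12)
  expect_true(all(cond$ssd_cm >= 60 & cond$ssd_cm <= 70))
  expect_true(all(cond$depth_cm >= 0 & cond$depth_cm <= 15))
  expect_equal(nrow(unique(cond[, c("ssd_cm", "depth_cm")])), 12)
  expect_identical(cond, generate_conditions())
})

test_that("the fit recovers known scaling factors from noisy data", {
  for (s in c(0.5, 1.10, 2.0)) {
    slopes <- vapply(seq_len(200), function(i) {
      d <- make_noisy_calibration(s, cv = 0.05, seed = 5000 + i)
      fit_zero_intercept(d)$slope
    }, numeric(1))
    se <- stats::sd(slopes) / sqrt(200)
    expect_lt(abs(mean(slopes) - s), 3 * se, label = paste("slope", s))
  }
})

test_that("simulated depth doses behave like a photon beam in water", {
  beam <- test_beam()
  cond <- tibble::tibble(condition_id = 1:3, ssd_cm = c(60, 60, 70),
                         depth_cm = c(0, 15, 0))
  sim <- simulate_calibration_doses(cond, beam, run_config(2e5, seed = 21))
  d0_60 <- sim$simulated_dose[1]; d15_60 <- sim$simulated_dose[2]
  d0_70 <- sim$simulated_dose[3]
  expect_gt(d0_60, d15_60)      # attenuation with depth
  expect_gt(d0_60, d0_70)       # inverse square with SSD
  # central-axis decline beyond 2 cm is approximately exponential
  sc <- fluoroshield:::make_calibration_scene(60, 0)
  tal <- run_histories(sc, beam, run_config(2e6, seed = 22),
                       air_spacing_m = 0.1)
  dpp <- dose_per_photon(tal)
  i0 <- which.min(abs(fluoroshield:::voxel_centers(sc$origin[1], sc$spacing, sc$dims[1])))
  zs <- fluoroshield:::voxel_centers(sc$origin[3], sc$spacing, sc$dims[3])
  depth <- zs - 0.60
  sel <- which(depth > 0.02 & depth < 0.15)
  prof <- tibble::tibble(depth_cm = depth[sel] * 100,
                         dose = dpp[i0, i0, sel])
  fit <- stats::lm(log(dose) ~ depth_cm, data = prof)
  expect_gt(summary(fit)$r.squared, 0.98)
  expect_lt(stats::coef(fit)[2], 0)
})

test_that("calibration data and fit reports round-trip through files", {
  d <- make_noisy_calibration(1.10, 0.05, seed = 31)
  d$measured_dose <- d$measured; d$simulated_dose <- d$simulated
  f <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(d[, c("condition_id", "ssd_cm", "depth_cm",
                              "measured_dose", "simulated_dose")], f)
  back <- read_calibration_csv(f)
  expect_equal(back$measured_dose, d$measured)
  fit <- fit_zero_intercept(simulated = back$simulated_dose,
                            measured = back$measured_dose)
  fj <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, fj)
  rep <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(rep$slope, fit$slope)
  expect_equal(rep$n_points, 12)
})

test_that("tidy and glance summarize calibration fits", {
  d <- make_noisy_calibration(1.10, 0.05, seed = 8)
  fit <- fit_zero_intercept(d)
  td <- tidy(fit)
  expect_equal(td$term, "slope")
  expect_equal(td$estimate, fit$slope)
  expect_gt(td$std.error, 0)
  gl <- glance(fit)
  expect_equal(gl$nobs, 12)
  expect_equal(gl$r.squared, fit$pearson_r^2)
})
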