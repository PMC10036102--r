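test_that("run configuration validates its invariants", {
  expect_error(run_config(0), "history")
  expect_error(run_config(5, n_batches = 10), "n_batches")
  expect_error(run_config(10, n_batches = 1), "n_batches")
  rc <- run_config(1e4, seed = 3)
  expect_equal(rc$cutoff_keV, 5)
})

test_that("photons escape a vacuum scene with their full energy", {
  sc <- make_point_source_scene(0.5, 0.05)
  tal <- run_histories(sc, mono_spectrum(60), run_config(1e4, seed = 1),
                       record_escapes = TRUE)
  led <- energy_ledger(tal)
  expect_equal(sum(led$deposited_keV), 0)
  expect_equal(sum(led$escaped_keV), sum(led$emitted_keV))
  expect_true(all(abs(tal$escapes[, 7] - 60) < 1e-6))
  expect_true(all(tal$escapes[, 8] == 0))
})

test_that("free paths in uniform water are exponential", {
  sc <- make_slab_scene("water", thickness_cm = 100, spacing_cm = 2,
                        lateral_cm = 200, standoff_cm = 0.01)
  mu <- lookup_mu("water", 60)                 # 1/cm at unit density
  tal <- run_histories(sc, mono_spectrum(60), run_config(5e4, seed = 4),
                       record_first_coll = TRUE)
  d_cm <- tal$first_coll * 100
  ks <- suppressWarnings(
    stats::ks.test(d_cm, function(x) stats::pexp(x, rate = mu)))
  expect_lt(unname(ks$statistic), 0.01)
  # single-material scene: the majorant equals the local attenuation, so no
  # virtual collisions occur
  expect_equal(sum(tal$ledger$n_virtual), 0)
})

test_that("Compton kinematics: closed-form shift and Klein-Nishina angles", {
  expect_equal(compton_shift(80, 1), 80)
  expect_lt(abs(compton_shift(80, -1) / (80 / (1 + 160 / 510.99895)) - 1),
            1e-6)
  expect_equal(compton_shift(80, -1), 60.9, tolerance = 1e-3)
  ks <- kn_sample(80, 1e5, seed = 3)
  # energies follow the Compton relation exactly
  expect_equal(ks$energy_out_keV, compton_shift(80, ks$cos_theta),
               tolerance = 1e-12)
  cdf <- kn_numeric_cdf(80)
  d <- suppressWarnings(stats::ks.test(ks$cos_theta, cdf))$statistic
  expect_lt(unname(d), 0.01)
})

test_that("coherent scattering is symmetric and elastic", {
  mu <- thomson_sample(1e5, seed = 5)
  expect_lt(abs(mean(mu)), 3 * stats::sd(mu) / sqrt(1e5))
  expect_true(all(abs(mu) <= 1))
  # elastic: a coherent-dominated history chain conserves photon energy by
  # construction; verified through the ledger of any run (deposit excludes
  # coherent events) in the conservation test below
})

test_that("interaction branches follow the partial cross sections", {
  p <- interaction_probabilities("water", 60)
  s <- sample_interaction("water", 60, 1e5, seed = 8)
  emp <- table(factor(s, c("photoelectric", "incoherent", "coherent"))) / 1e5
  theo <- c(p$p_photoelectric, p$p_incoherent, p$p_coherent)
  for (i in 1:3) {
    sig <- sqrt(theo[i] * (1 - theo[i]) / 1e5)
    expect_lt(abs(emp[i] - theo[i]), 3 * sig)
  }
  # a material with a single open branch always takes it
  m <- get_material("water")
  m$table$mu_incoh[] <- 1e-300
  m$table$mu_coh[] <- 1e-300
  expect_true(all(sample_interaction(m, 60, 500, seed = 1) ==
                    "photoelectric"))
  expect_identical(sample_interaction("water", 60, 100, seed = 2),
                   sample_interaction("water", 60, 100, seed = 2))
})

test_that("energy is conserved and runs are deterministic", {
  sc <- make_slab_scene("water", thickness_cm = 10, spacing_cm = 1,
                        lateral_cm = 40)
  tal <- run_histories(sc, test_beam(), run_config(2e4, seed = 6))
  expect_lt(max(abs(energy_ledger(tal)$closure_rel)), 1e-6)
  expect_equal(sum(tal$ledger$n_corrupted), 0)
  tal2 <- run_histories(sc, test_beam(), run_config(2e4, seed = 6))
  expect_identical(tal$fine_sum, tal2$fine_sum)
  expect_identical(tal$air_sum, tal2$air_sum)
  expect_identical(tal$roi_batch, tal2$roi_batch)
  tal3 <- run_histories(sc, test_beam(), run_config(2e4, seed = 7))
  expect_false(identical(tal$fine_sum, tal3$fine_sum))
})

test_that("narrow-beam transmission matches Beer-Lambert at 1-3 mean free paths", {
  mu <- lookup_mu("water", 60)
  mfp <- 1 / mu
  for (k in 1:3) {
    sl <- make_slab_scene("water", thickness_cm = k * mfp, spacing_cm = 0.5)
    tr <- measure_transmission(sl, 60, 2e4, seed = 10 + k)
    expect_lt(abs(tr$transmission - exp(-k)), 3 * tr$sigma + 1e-9,
              label = paste("thickness", k, "mfp"))
  }
})

test_that("point-source fluence falls off as inverse square", {
  sc <- make_point_source_scene(0.7, 0.03)
  tal <- run_histories(sc, mono_spectrum(60), run_config(3e5, seed = 7),
                       air_spacing_m = 0.03)
  o <- sc$origin
  d <- dim(tal$air_sum)
  cc <- function(n) o[1] + (seq_len(n) - 0.5) * 0.03
  r <- sqrt(outer(cc(d[1])^2, outer(cc(d[2])^2, cc(d[3])^2, "+"), "+"))
  stats_at <- function(rr) {
    sel <- abs(r - rr) < 0.03
    t <- tal$air_sum[sel] * r[sel]^2
    c(m = mean(t), se = stats::sd(t) / sqrt(sum(sel)))
  }
  s1 <- stats_at(0.35); s2 <- stats_at(0.45); s3 <- stats_at(0.55)
  expect_lt(abs(s1["m"] - s2["m"]), 3 * sqrt(s1["se"]^2 + s2["se"]^2))
  expect_lt(abs(s2["m"] - s3["m"]), 3 * sqrt(s2["se"]^2 + s3["se"]^2))
})

test_that("per-voxel standard error shrinks as one over root N", {
  sc <- make_slab_scene("air", thickness_cm = 40, spacing_cm = 4,
                        lateral_cm = 60, beam = "parallel", standoff_cm = 4)
  msk <- array(FALSE, sc$dims)
  msk[4:12, 4:12, 3:11] <- TRUE
  rel_se <- function(n, seed) {
    tal <- run_histories(sc, mono_spectrum(60), run_config(n, seed = seed),
                         air_spacing_m = 0.04)
    B <- tal$run$n_batches
    v <- pmax(tal$air_sumsq - tal$air_sum^2 / B, 0) / (B - 1) * B
    sqrt(mean(v[msk])) / mean(tal$air_sum[msk])
  }
  ratio <- rel_se(1e5, 9) / rel_se(4e5, 9)
  expect_lt(abs(ratio - 2), 0.2 * 2)
})

test_that("path logging emits polyline records", {
  sc <- make_slab_scene("water", thickness_cm = 10, spacing_cm = 1,
                        lateral_cm = 40)
  tal <- run_histories(sc, mono_spectrum(60),
                       run_config(500, seed = 1, path_logging = TRUE))
  expect_gt(length(tal$paths), 0)
  p <- tal$paths[[1]]
  expect_equal(ncol(p), 4)          # x, y, z, energy at each vertex
  expect_gte(nrow(p), 2)
  expect_equal(p[1, 4], 60)
})
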