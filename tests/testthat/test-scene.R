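test_that("projection geometry composes the clinical C-arm rotations", {
  cfg <- scene_config()
  pa <- projection_geometry(set_projection(cfg, "PA"))
  expect_equal(pa$axis, c(0, 0, 1), tolerance = 1e-12)
  expl <- projection_geometry(set_projection(cfg, list(rao_lao = 0,
                                                       cra_cau = 0)))
  expect_equal(expl$source_pos, pa$source_pos)
  expect_equal(expl$axis, pa$axis)
  # rotation-composition oracle: RAO about x then CRA/CAU about y
  rotx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                               0, -sin(a), cos(a)), 3, 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)
  co <- projection_geometry(set_projection(cfg, "cusp_overlap"))
  want <- as.vector(roty(-1 * pi / 180) %*% rotx(9 * pi / 180) %*% c(0, 0, 1))
  expect_equal(co$axis, want, tolerance = 1e-12)
  pp <- projection_geometry(set_projection(cfg, "perpendicular"))
  want2 <- as.vector(roty(13 * pi / 180) %*%
                       rotx(-16 * pi / 180) %*% c(0, 0, 1))
  expect_equal(pp$axis, want2, tolerance = 1e-12)
  expect_error(set_projection(cfg, list(rao_lao = 50, cra_cau = 0)),
               "angulation")
  # collimation: 156.5 mm square field at the receptor
  expect_equal(2 * pa$half_x_m * 1000, 156.5)
})

test_that("collimated beam covers the receptor field within one voxel", {
  sc <- make_point_source_scene(0.8, 0.05)
  pg <- projection_geometry(scene_config())
  src <- list(type = 0L, pos = c(0, 0, -0.5), axis = c(0, 0, 1),
              u = c(1, 0, 0), v = c(0, 1, 0),
              half_x = pg$half_x_m, half_y = pg$half_y_m, sid = 1)
  tal <- run_histories(sc, mono_spectrum(60), run_config(5e3, seed = 2),
                       source = src, record_escapes = TRUE)
  esc <- tal$escapes
  # project each escape direction to the receptor plane 1 m from the source
  x1 <- 0 + (esc[, 4] / esc[, 6]) * 1.0
  y1 <- 0 + (esc[, 5] / esc[, 6]) * 1.0
  expect_lt(max(abs(x1)), pg$half_x_m + 1e-9)
  expect_lt(max(abs(y1)), pg$half_y_m + 1e-9)
  expect_gt(max(abs(x1)), pg$half_x_m * 0.95)
})

test_that("shield patterns carve the published aperture bands", {
  solid <- build_shield(shield_spec("none_aperture"), 0.05)
  expect_true(all(solid$occupied))
  expect_equal(unname(solid$aperture_voxels), c(0L, 0L))
  small <- build_shield(shield_spec("small"), 0.05)
  zs <- (seq_len(dim(small$occupied)[3]) - 0.5) * 0.05
  ys <- (seq_len(dim(small$occupied)[2]) - 0.5) * 0.05 - 0.5
  anes_open <- which(!small$occupied[1, , ], arr.ind = TRUE)
  anes_open <- anes_open[ys[anes_open[, 1]] < 0, , drop = FALSE]
  expect_true(all(zs[anes_open[, 2]] > 0.95 & zs[anes_open[, 2]] < 1.15))
  echo_open <- which(!small$occupied[1, , ], arr.ind = TRUE)
  echo_open <- echo_open[ys[echo_open[, 1]] > 0, , drop = FALSE]
  expect_true(all(zs[echo_open[, 2]] > 1.05 & zs[echo_open[, 2]] < 1.25))
  large <- build_shield(shield_spec("large"), 0.05)
  expect_true(all(large$aperture_voxels > small$aperture_voxels))
  absent <- build_shield(shield_spec("absent"), 0.05)
  expect_equal(length(absent$occupied), 0)
  expect_error(shield_spec("large", aperture = list(
    echo = list(band_cm = c(100, 200), width_cm = 35, offset_cm = 25))),
    "outside")
  expect_error(shield_spec("none_aperture", aperture = list(
    echo = list(band_cm = c(100, 140), width_cm = 35, offset_cm = 25))),
    "admits no apertures")
})

test_that("room voxelization has the expected dimensions and structure", {
  cfg <- scene_config(patient = list(on = FALSE), staff = list(on = FALSE))
  sc <- build_room_scene(cfg, 0.05)
  # interior 8.1 x 7.3 x 3.4 m at 5 cm -> 162 x 146 x 68, plus 4 wall voxels
  # on each side (20 cm concrete)
  expect_equal(sc$dims, c(162 + 8, 146 + 8, 68 + 8))
  expect_equal(sc$index[1, 1, 1], 2L)          # corner: concrete
  expect_equal(sc$index[5, 5, 75], 2L)         # ceiling
  mid <- round(sc$dims / 2)
  expect_equal(sc$index[mid[1], mid[2], 60], 1L)  # interior air above table
  sc2 <- build_room_scene(cfg, 0.05)
  expect_identical(sc$index, sc2$index)
  expect_error(build_room_scene(scene_config(room = c(1.5, 1.5, 3.4))),
               "room too small")
})

test_that("tabletop is homogenized to preserve areal density", {
  cfg <- scene_config(patient = list(on = FALSE), staff = list(on = FALSE))
  sc <- build_room_scene(cfg, 0.05)
  n_tab <- sum(sc$index == 7L)
  expect_gt(n_tab, 0)
  rho_eff <- sc$materials$density[sc$materials$code == 7L]
  # areal density rho * t preserved: 0.55 g/cm^3 * 2 cm over a 5 cm voxel
  expect_equal(rho_eff * 0.05, 0.55 * 0.02, tolerance = 1e-9)
})

test_that("staff phantom bands, stance rotation and ROI geometry", {
  ph <- build_staff_phantom(160.8, 45, 0.02)
  expect_equal(ph$bands_cm$lens, c(145, 150))
  expect_equal(ph$bands_cm$waist, c(80, 85))
  ph0 <- build_staff_phantom(160.8, 0, 0.02)
  expect_lt(abs(ph0$volume_m3 / ph$volume_m3 - 1), 0.02)
  tall <- build_staff_phantom(180, 45, 0.02)
  expect_equal(tall$bands_cm$lens, c(145, 150) * 180 / 160.8)
  expect_error(build_staff_phantom(120), "height")

  sc <- build_room_scene(make_scaled_or_scene(0.5), 0.05)
  rois <- sc$roi
  expect_setequal(names(rois),
                  c("lens_left", "lens_right", "neck", "chest_left",
                    "chest_right", "waist"))
  all_ix <- unlist(rois)
  expect_equal(length(all_ix), length(unique(all_ix)))  # disjoint
  expect_true(all(sc$index[all_ix] %in% c(4L, 6L)))     # on skin/lens voxels
})

test_that("phantom mass converges under voxel refinement", {
  fine <- build_staff_phantom(160.8, 45, 0.002)
  coarse <- build_staff_phantom(160.8, 45, 0.005)
  expect_lt(abs(coarse$mass_kg / fine$mass_kg - 1), 0.03)
})

test_that("PA scene without staff or shield is left-right symmetric", {
  cfg <- make_scaled_or_scene(0.5, staff_on = FALSE)
  sc <- build_room_scene(cfg, 0.05)
  idx <- sc$index
  expect_identical(idx, idx[, rev(seq_len(dim(idx)[2])), ])
})

test_that("scene masses are physically plausible", {
  sc <- build_room_scene(make_scaled_or_scene(0.5), 0.05)
  m <- scene_mass(sc)
  staff_patient <- sum(m$mass_kg[m$label %in% c("water", "skin", "bone",
                                                "eye_lens")])
  expect_gt(staff_patient, 80)    # two adult phantoms
  expect_lt(staff_patient, 220)
  expect_equal(m$mass_kg[m$label == "shield"], 0)   # pattern "absent"
  scs <- build_room_scene(make_scaled_or_scene(0.5,
                                               shield_pattern = "none_aperture"),
                          0.05)
  ms <- scene_mass(scs)
  # 1 mm Pb over 1.0 x 1.8 m: ~20 kg regardless of voxel homogenization
  expect_equal(ms$mass_kg[ms$label == "shield"], 11.35 * 0.1 * 100 * 180 / 1000,
               tolerance = 0.05)
})
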