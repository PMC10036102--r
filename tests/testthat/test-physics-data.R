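test_that("registry materials are complete and internally consistent", {
  reg <- fs_materials()
  expect_setequal(reg$name,
                  c("water", "air", "lead", "aluminum", "copper", "concrete",
                    "lead_acrylic", "eye_lens", "bone", "skin", "soft_tissue"))
  for (nm in reg$name) {
    m <- get_material(nm)
    expect_gt(m$density, 0)
    expect_gte(nrow(m$composition), 1)
    expect_lt(abs(sum(m$composition$fraction) - 1), 1e-6)
    tab <- m$table
    expect_true(all(diff(tab$energy_keV) > 0))
    expect_lte(min(tab$energy_keV), 5)
    expect_gte(max(tab$energy_keV), 150)
    expect_true(all(tab$mu_total > 0 & tab$mu_photo > 0 &
                      tab$mu_incoh > 0 & tab$mu_coh > 0))
    # partial coefficients sum to the total within 2% at every grid point
    rel <- abs(tab$mu_photo + tab$mu_incoh + tab$mu_coh - tab$mu_total) /
      tab$mu_total
    expect_lt(max(rel), 0.02)
  }
  expect_error(get_material("kryptonite"), "valid names")
})

test_that("reference compositions and densities match published tissue data", {
  w <- get_material("water")
  expect_equal(w$density, 1.00)
  expect_equal(sort(w$composition$element), c("H", "O"))
  expect_equal(w$composition$fraction[w$composition$element == "H"], 0.1119)
  pb <- get_material("lead")
  expect_equal(nrow(pb$composition), 1)
  expect_equal(pb$composition$fraction, 1)
  # ICRU reference eye lens: density 1.07, H 9.6% / C 19.5% / O 64.6% by mass
  lens <- get_material("eye_lens")
  expect_lt(abs(lens$density / 1.07 - 1), 0.01)
  frac <- function(m, e) m$composition$fraction[m$composition$element == e]
  expect_lt(abs(frac(lens, "H") / 0.096 - 1), 0.01)
  expect_lt(abs(frac(lens, "C") / 0.195 - 1), 0.01)
  expect_lt(abs(frac(lens, "O") / 0.646 - 1), 0.01)
  expect_lt(abs(get_material("bone")$density / 1.92 - 1), 0.01)
  expect_lt(abs(frac(get_material("bone"), "Ca") / 0.225 - 1), 0.01)
})

test_that("coefficient lookup interpolates log-log and is exact at nodes", {
  w <- get_material("water")
  nodes <- w$table$energy_keV[c(3, 17, 40)]
  expect_identical(lookup_mu(w, nodes), w$table$mu_total[c(3, 17, 40)])
  # cross-checks against the NIST photon cross-section compilation
  expect_lt(abs(lookup_mu(w, 60) / 0.206 - 1), 0.02)
  expect_lt(abs(lookup_mu(get_material("lead"), 60) / 5.0 - 1), 0.05)
  expect_error(lookup_mu(w, 3), "energy")
  expect_error(lookup_mu(w, 200), "energy")
  # between-node value lies between the bracketing node values
  i <- findInterval(47.3, w$table$energy_keV)
  v <- lookup_mu(w, 47.3)
  expect_true(v <= w$table$mu_total[i] && v >= w$table$mu_total[i + 1])
})

test_that("total attenuation decreases with energy away from absorption edges", {
  en <- seq(15, 80, by = 0.5)
  for (nm in c("water", "air", "aluminum", "copper", "bone", "concrete"))
    expect_true(all(diff(lookup_mu(nm, en)) < 0), label = nm)
  # lead: monotone outside the L-edge cluster below 16 keV
  expect_true(all(diff(lookup_mu("lead", seq(16.5, 80, by = 0.5))) < 0))
})

test_that("mixture rule is additive in mass fractions", {
  w <- get_material("water")
  al <- get_material("aluminum")
  en <- c(20, 60, 120)
  one <- mixture_mu(tibble::tibble(material = list(w), fraction = 1), en)
  expect_equal(one, lookup_mu(w, en))
  half <- mixture_mu(tibble::tibble(material = list(w, al),
                                    fraction = c(0.5, 0.5)), en)
  expect_equal(half, (lookup_mu(w, en) + lookup_mu(al, en)) / 2)
  elems <- mixture_mu(tibble::tibble(material = c("H", "O"),
                                     fraction = c(0.1119, 0.8881)), en)
  expect_lt(max(abs(elems / lookup_mu(w, en) - 1)), 0.02)
  expect_error(mixture_mu(tibble::tibble(material = c("H", "O"),
                                         fraction = c(0.4, 0.4)), 60),
               "sum to 1")
})

test_that("interaction branch probabilities are normalized and physical", {
  for (nm in c("water", "lead", "bone")) {
    p <- interaction_probabilities(nm, c(10, 60, 100, 149))
    expect_lt(max(abs(p$p_photoelectric + p$p_incoherent + p$p_coherent - 1)),
              1e-9)
  }
  pw <- interaction_probabilities("water", 100)
  expect_true(pw$p_incoherent > pw$p_photoelectric &&
                pw$p_incoherent > pw$p_coherent)
  pl <- interaction_probabilities("lead", 60)
  expect_true(pl$p_photoelectric > pl$p_incoherent &&
                pl$p_photoelectric > pl$p_coherent)
})

test_that("custom materials validate their invariants", {
  thin <- fs_material("thin_air", 1e-9, get_material("air")$composition)
  expect_s3_class(thin, "fs_material")
  expect_equal(lookup_mu(thin, 60), lookup_mu("air", 60), tolerance = 1e-3)
  expect_error(fs_material("bad", 1,
                           tibble::tibble(element = "H", fraction = 0.5)),
               "sum to 1")
  expect_error(fs_material("bad", -1,
                           tibble::tibble(element = "H", fraction = 1)),
               "density")
})
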