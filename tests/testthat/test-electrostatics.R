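test_that("uniform slab reproduces the 1-D Laplace solution exactly", {
  sl <- tiny_slab(voltage = 1, thickness = 0.01)
  g <- sl$grid
  sig <- effective_sigma(g, sl$scenario$materials, sl$scenario$conductivity)
  phi <- solve_potential(g, sig, 1, tol = 1e-12)
  tis <- g$label == pulseheat:::LABEL_LEVELS[["TUMOR"]]
  # linear potential: phi at cell centres matches V * (1 - x/d)
  d <- 0.01
  expected <- 1 - (g$xc[arrayInd(which(tis), g$dim)[, 1]]) / d
  expect_equal(unname(phi[tis]), expected, tolerance = 1e-9)
  fj <- field_and_joule(phi, g, sig)
  expect_equal(unname(fj$e_magnitude[tis]), rep(100, sum(tis)),
               tolerance = 1e-9)
  expect_equal(unname(fj$joule_density[tis]),
               rep(sig[which(tis)[1]] * 100^2, sum(tis)), tolerance = 1e-9)
})

test_that("two-layer slab splits the field by conductivity (series circuit)", {
  sl <- tiny_slab(voltage = 1, thickness = 0.01, n_cells = 8)
  g <- sl$grid
  sig <- effective_sigma(g, sl$scenario$materials, sl$scenario$conductivity)
  # first half sigma1 = 0.067, second half sigma2 = 0.134
  xi <- arrayInd(seq_len(prod(g$dim)), g$dim)[, 1]
  tis <- g$label == pulseheat:::LABEL_LEVELS[["TUMOR"]]
  sig[tis & xi <= 5] <- 0.067
  sig[tis & xi > 5] <- 0.134
  phi <- solve_potential(g, sig, 1, tol = 1e-12)
  fj <- field_and_joule(phi, g, sig)
  e1 <- fj$e_magnitude[tis & xi <= 5]
  e2 <- fj$e_magnitude[tis & xi > 5]
  expect_equal(unname(e1 / rep(e2, length.out = length(e1))),
               rep(2, length(e1)), tolerance = 1e-9)
  # current continuity: sigma1 E1 = sigma2 E2
  expect_equal(unname(0.067 * e1[1]), unname(0.134 * e2[1]),
               tolerance = 1e-9)
})

test_that("zero voltage gives an identically zero potential", {
  sl <- tiny_slab(voltage = 0)
  g <- sl$grid
  sig <- effective_sigma(g, sl$scenario$materials, sl$scenario$conductivity)
  phi <- solve_potential(g, sig, 0)
  tis <- g$label == pulseheat:::LABEL_LEVELS[["TUMOR"]]
  expect_true(all(phi[tis] == 0))
})

test_that("joule density follows Q = sigma E^2 voxel-wise", {
  # direct formula check at the porated-tumor working point
  expect_equal(0.426 * 1.852e5^2, 1.461e10, tolerance = 1e-3)
  sl <- tiny_slab(voltage = 540)
  fs <- porate_fixed_point(sl$grid, sl$scenario$materials,
                           sl$scenario$conductivity, 540)
  tis <- sl$grid$label == pulseheat:::LABEL_LEVELS[["TUMOR"]]
  expect_equal(fs$joule_density[tis],
               fs$sigma_effective[tis] * fs$e_magnitude[tis]^2)
  # doubling the voltage quadruples Q everywhere (fixed conductivity state)
  fs2 <- porate_fixed_point(sl$grid, sl$scenario$materials,
                            sl$scenario$conductivity, 1080)
  expect_equal(fs2$joule_density[tis], 4 * fs$joule_density[tis],
               tolerance = 1e-9)
})

test_that("poration switch: uniform slabs above and below threshold", {
  # 540 V over 5.4 mm = 1000 V/cm >= 800 V/cm: everything porates at once
  hot <- tiny_slab(voltage = 540)
  fs <- porate_fixed_point(hot$grid, hot$scenario$materials,
                           hot$scenario$conductivity, 540)
  tis <- hot$grid$label == pulseheat:::LABEL_LEVELS[["TUMOR"]]
  expect_true(all(fs$porated[tis]))
  expect_false(any(fs$porated[!tis]))
  expect_equal(fs$iterations, 2L)  # switch, then confirm fixed point
  expect_equal(max(fs$joule_density[tis]), hot$expected$joule_density,
               tolerance = 1e-6)
  # 400 V over 5.4 mm ~ 741 V/cm: nothing porates, single pass
  cold <- tiny_slab(voltage = 400)
  fs2 <- porate_fixed_point(cold$grid, cold$scenario$materials,
                            cold$scenario$conductivity, 400)
  expect_false(any(fs2$porated))
  expect_equal(fs2$iterations, 1L)
})

test_that("discrete maximum principle and charge conservation on the needle grid", {
  g <- coarse_needle_grid()
  scn <- coarse_scenario()
  fs <- porate_fixed_point(g, scn$materials, scn$conductivity, 4000,
                           tol = 1e-10)
  phi <- fs$potential
  tis <- g$label %in% pulseheat:::TISSUE_CODES()
  expect_gte(min(phi[tis]), -1e-6 * 4000)
  expect_lte(max(phi[tis]), 4000 * (1 + 1e-6))
  # current into A equals current out of B
  expect_equal(unname(fs$currents[["A"]] / fs$currents[["B"]]), 1,
               tolerance = 1e-6)
  # poration never marks electrode or insulation voxels
  expect_false(any(fs$porated[!tis]))
})

test_that("porated set grows monotonically with voltage", {
  g <- coarse_needle_grid()
  scn <- coarse_scenario()
  prev <- NULL
  for (v in c(1000, 2000, 3000, 4000)) {
    fs <- porate_fixed_point(g, scn$materials, scn$conductivity, v)
    if (!is.null(prev)) expect_true(all(fs$porated[prev]))
    prev <- fs$porated
  }
  # at 4 kV the whole tumor is electroporated
  expect_true(all(prev[g$label == pulseheat:::LABEL_LEVELS[["TUMOR"]]]))
})

test_that("temperature coefficient scales conductivity about 37 degC", {
  g <- tiny_slab()$grid
  mats <- default_materials()
  cm <- conductivity_model()
  s37 <- effective_sigma(g, mats, cm, temperature = 37)
  s47 <- effective_sigma(g, mats, cm, temperature = 47)
  tis <- g$label == pulseheat:::LABEL_LEVELS[["TUMOR"]]
  expect_equal(s47[tis] / s37[tis], rep(1.15, sum(tis)))
})
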