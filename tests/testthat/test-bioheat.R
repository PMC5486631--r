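test_that("pennes_rhs vanishes at equilibrium and matches source closed forms", {
  bx <- make_uniform_block(conduction = TRUE, perfusion = TRUE)
  g <- bx$grid
  Teq <- array(37, g$dim)
  rhs <- pennes_rhs(Teq, g, bx$scenario$materials, bx$scenario$blood)
  expect_equal(max(abs(rhs)), 0)
  # metabolism only: rhs = Q_m / (rho c) everywhere
  bm <- make_uniform_block(metabolism = TRUE)
  rhs2 <- pennes_rhs(array(37, bm$grid$dim), bm$grid,
                     bm$scenario$materials, bm$scenario$blood)
  expect_equal(unname(rhs2[1, 1, 1]), 42000 / (1220 * 4180),
               tolerance = 1e-12)
  expect_equal(42000 / (1220 * 4180), 8.24e-3, tolerance = 1e-2)
  # perfusion only at 47 degC: relaxation toward blood temperature
  bp <- make_uniform_block(material = default_materials()$LIVER,
                           perfusion = TRUE, initial_T = 47)
  rhs3 <- pennes_rhs(array(47, bp$grid$dim), bp$grid,
                     bp$scenario$materials, bp$scenario$blood)
  lam <- 1000 * 4200 * 5e-4 / (1080 * 3540)
  expect_equal(unname(rhs3[1, 1, 1]), -lam * 10, tolerance = 1e-12)
  expect_equal(lam, 5.49e-4, tolerance = 1e-2)
})

test_that("zero-dimensional block fixtures match their closed forms", {
  # metabolism-only linear rise over 1 s
  bm <- make_uniform_block(metabolism = TRUE)
  br <- simulate_burst(bm$scenario, bm$grid)
  expect_equal(br$t_max_1s, bm$closed_form(1), tolerance = 0.005)
  expect_equal(bm$closed_form(1) - 37, 8.24e-3, tolerance = 0.01)
  # perfusion-only exponential decay from 47 degC
  bp <- make_uniform_block(material = default_materials()$LIVER,
                           perfusion = TRUE, initial_T = 47)
  brp <- simulate_burst(bp$scenario, bp$grid)
  expect_equal(brp$t_max_1s - 37, bp$closed_form(1) - 37, tolerance = 0.005)
  # all terms off: stays at the blood temperature
  b0 <- make_uniform_block()
  br0 <- simulate_burst(b0$scenario, b0$grid)
  expect_equal(br0$t_max_1s, 37, tolerance = 1e-9)
})

test_that("zero-voltage burst stays at the initial temperature", {
  sl <- tiny_slab(voltage = 0)
  br <- simulate_burst(sl$scenario, sl$grid)
  expect_equal(br$t_max_100us, 37, tolerance = 1e-3)
  expect_true(all(diff(br$series$time) > 0))
})

test_that("slab burst reproduces the adiabatic closed-form rise", {
  for (v in c(540, 270)) {
    sl <- tiny_slab(voltage = v)
    br <- simulate_burst(sl$scenario, sl$grid, mode = "averaged")
    expect_equal(br$t_max_100us - 37, sl$expected$dt_burst,
                 tolerance = 1e-6)
  }
})

test_that("exact and averaged modes agree within one single-pulse increment", {
  sl <- tiny_slab(voltage = 540)
  m <- sl$scenario$materials$TUMOR
  bra <- simulate_burst(sl$scenario, sl$grid, mode = "averaged")
  bre <- simulate_burst(sl$scenario, sl$grid, mode = "exact")
  pulse_inc <- sl$expected$joule_density * 500e-9 / (m$rho * m$cp)
  expect_lt(abs(bre$t_max_100us - bra$t_max_100us), 2 * pulse_inc)
  # the exact-mode series shows the stepwise staircase: strictly more
  # spread within the burst than the averaged ramp
  expect_gte(max(bre$series$max_tumor), max(bra$series$max_tumor) - 1e-9)
})

test_that("global maximum is non-increasing after source-off", {
  sl <- tiny_slab(voltage = 540)
  br <- simulate_burst(sl$scenario, sl$grid)
  cool <- br$series[br$series$time > 101e-6, ]
  expect_true(all(diff(cool$max_domain) <= 1e-9))
})

test_that("implicit cooling conserves thermal energy with sources off", {
  # insulated conducting block, nonuniform start, no perfusion/metabolism
  bx <- make_uniform_block(conduction = TRUE, n_cells = 5)
  g <- bx$grid
  sys <- pulseheat:::thermal_system(g, bx$scenario$materials,
                                    bx$scenario$blood)
  set.seed(3)
  Tv <- array(37 + 10 * runif(prod(g$dim)), g$dim)
  e0 <- sum(sys$cheat * Tv)
  cur <- as.numeric(Tv)
  for (step in 1:20) {
    res <- pulseheat:::cool_phase(as.integer(g$dim), sys$gx, sys$gy, sys$gz,
                                  sys$cheat, sys$perf * 0, sys$s_base * 0,
                                  as.integer(sys$active), 37, 0.05, 1L, 0,
                                  cur, numeric(length(cur)), 7.39e39,
                                  2.577e5 / 8.314,
                                  as.integer(sys$tumor_cells), 1L,
                                  1e-13, 100000L)
    e1 <- sum(sys$cheat * res$temperature)
    expect_lt(abs(e1 / e0 - 1), 1e-10)
    cur <- res$temperature
    e0 <- e1
  }
  # and the field actually mixed toward the mean
  expect_lt(diff(range(cur)), diff(range(Tv)))
})

test_that("violating the explicit stability limit raises a step error", {
  sl <- tiny_slab(voltage = 540)
  sl$scenario$solver$dt_burst <- 10
  sl$scenario$solver$macro_stride <- 100
  expect_error(simulate_burst(sl$scenario, sl$grid),
               class = "pulseheat_step_error")
})

test_that("the printed perfusion sign heats above blood temperature", {
  bp <- make_uniform_block(material = default_materials()$LIVER,
                           perfusion = TRUE, initial_T = 40)
  bp$scenario$solver$printed_perfusion_sign <- TRUE
  br <- simulate_burst(bp$scenario, bp$grid)
  expect_gt(br$t_max_1s, 40)  # runaway, the reason the sign is corrected
})
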