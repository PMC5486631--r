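test_that("noiseless synthetic sweep recovers the law coefficient exactly", {
  sw <- make_synthetic_sweep(1.5e-12)
  expect_equal(nrow(sw), 64)
  fit <- fit_power_law(sw, "t_max_100us")
  expect_equal(fit$coefficient, 1.5e-12, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # zero coefficient: flat sweep at baseline
  sw0 <- make_synthetic_sweep(0)
  expect_true(all(sw0$t_max_100us == 37))
})

test_that("noisy synthetic fits recover the coefficient within sampling error", {
  # slope standard error for a through-origin fit: sd / sqrt(sum x^2)
  a <- 1.5e-12
  sds <- vapply(1:50, function(s) {
    sw <- make_synthetic_sweep(a, noise_sd = 0.1, seed = s)
    fit_power_law(sw, "t_max_100us")$coefficient
  }, numeric(1))
  x <- with(make_synthetic_sweep(a), pulse_width * rep_rate * voltage^2)
  se <- 0.1 / sqrt(sum(x^2))
  expect_equal(mean(sds), a, tolerance = 3 * se / sqrt(50) / a)
  expect_equal(sd(sds), se, tolerance = 0.4)
})

test_that("degenerate designs are rejected", {
  sw <- make_synthetic_sweep(1e-12, voltages = 1000, widths = 100,
                             rates = 100)
  expect_error(fit_power_law(sw), class = "pulseheat_fit_error")
})

test_that("temperature prediction follows the fitted law", {
  expect_equal(predict_temperature(1.5e-12, 500, 1000, 4000), 49)
  expect_equal(predict_temperature(4.8e-13, 500, 1000, 4000), 40.84)
  expect_equal(predict_temperature(1.5e-12, 0 , 1000, 4000), 37)
  # linear in burst count
  r1 <- predict_temperature(1.5e-12, 500, 1000, 4000, n_bursts = 1) - 37
  r2 <- predict_temperature(1.5e-12, 500, 1000, 4000, n_bursts = 2) - 37
  expect_equal(r2, 2 * r1)
  expect_error(predict_temperature(1e-12, 500, 1000, 4000, n_bursts = 0),
               class = "pulseheat_input_error")
  # accepts a fit_result too
  fit <- fit_power_law(make_synthetic_sweep(1.5e-12))
  expect_equal(predict_temperature(fit, 500, 1000, 4000), 49)
})

test_that("44 degC contour inverts the exact law in closed form", {
  a <- 1.5e-12
  sw <- make_synthetic_sweep(a)
  # free rep rate at fixed (4 kV, 500 ns): f* = 7 / (a pw V^2)
  ct <- threshold_contour(sw, free = "rep_rate",
                          fixed = list(voltage = 4000, pulse_width = 500))
  expect_equal(ct$status, "ok")
  expect_equal(ct$rep_rate_max, 7 / (a * 500 * 4000^2), tolerance = 1e-9)
  expect_equal(ct$rep_rate_max, 583.3, tolerance = 1e-3)
  # free pulse width at fixed (4 kV, 1 MHz)
  ct2 <- threshold_contour(sw, free = "pulse_width",
                           fixed = list(voltage = 4000, rep_rate = 1000))
  expect_equal(ct2$pulse_width_max, 7 / (a * 1000 * 4000^2), tolerance = 1e-9)
  # free voltage (interpolation runs in V^2)
  ct3 <- threshold_contour(sw, free = "voltage",
                           fixed = list(pulse_width = 500, rep_rate = 1000))
  expect_equal(ct3$voltage_max, sqrt(7 / (a * 500 * 1000)), tolerance = 1e-9)
  # contour points evaluate to the limit under the law
  expect_equal(37 + a * 500 * ct$rep_rate_max * 4000^2, 44, tolerance = 1e-9)
})

test_that("unbracketed combinations report unbounded, not an error", {
  sw <- make_synthetic_sweep(1e-14)  # response never reaches 44
  ct <- threshold_contour(sw, free = "rep_rate")
  expect_true(all(ct$status == "unbounded"))
  expect_true(all(!is.finite(ct$rep_rate_max)))
})

test_that("44 degC isosurface vertices satisfy the exact law", {
  a <- 1.5e-12
  sw <- make_synthetic_sweep(a)
  surf <- threshold_surface(sw, n_grid = 11)
  expect_gt(nrow(surf$vertices), 0)
  expect_gt(nrow(surf$triangles), 0)
  lawval <- with(surf$vertices, a * pulse_width * rep_rate * voltage^2)
  expect_true(all(abs(lawval / 7 - 1) < 0.005))
  # a limit above the sweep maximum produces an empty surface
  surf2 <- threshold_surface(sw, limit = 37 + 2 * max(
    a * sw$pulse_width * sw$rep_rate * sw$voltage^2))
  expect_equal(nrow(surf2$vertices), 0)
})
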