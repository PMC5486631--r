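test_that("default scenario carries the reference parameter set", {
  scn <- default_scenario()
  expect_equal(scn$materials$LIVER$sigma_base, 0.067)
  expect_equal(scn$materials$LIVER$sigma_porated, 0.241)
  expect_equal(scn$materials$TUMOR$sigma_base, 0.135)
  expect_equal(scn$materials$TUMOR$sigma_porated, 0.426)
  expect_equal(scn$conductivity$e_threshold, 8e4)  # 800 V/cm
  expect_equal(scn$conductivity$alpha, 0.015)
  expect_equal(scn$blood$t_b, 37)
  expect_equal(scn$initial_temperature, scn$blood$t_b)
  expect_equal(scn$geometry$electrode_spacing, 0.0054)
  expect_equal(scn$protocol$burst_length, 100)
})

test_that("material and geometry invariants are enforced", {
  expect_error(material_properties(1000, 3500, 0.5, 0.2, sigma_porated = 0.1),
               class = "pulseheat_validation_error")
  expect_error(material_properties(-1, 3500, 0.5, 0.2),
               class = "pulseheat_validation_error")
  expect_error(tissue_geometry(electrode_spacing = 5e-4),
               class = "pulseheat_validation_error")
  expect_error(tissue_geometry(tumor_center = c(0.048, 0, 0)),
               class = "pulseheat_validation_error")
  expect_error(blood_model(rho_b = 0), class = "pulseheat_validation_error")
})

test_that("pulse arithmetic: duty cycle, on-time and gate function", {
  expect_equal(duty_cycle(pulse_protocol(4000, 50, 1000)), 0.05)
  expect_equal(duty_cycle(pulse_protocol(4000, 500, 1000)), 0.5)
  expect_equal(duty_cycle(pulse_protocol(4000, 100, 100)), 0.01)
  expect_equal(total_on_time(pulse_protocol(4000, 50, 1000)), 5)
  expect_equal(total_on_time(pulse_protocol(4000, 500, 1000)), 50)
  expect_equal(total_on_time(pulse_protocol(4000, 500, 100)), 5)
  # impossible train: 2000 ns at 1 MHz is duty 2
  expect_error(pulse_protocol(4000, 2000, 1000),
               class = "pulseheat_validation_error")
  p <- pulse_protocol(4000, 500, 1000)
  expect_equal(pulse_schedule(p, 250e-9), 1)  # inside first pulse
  expect_equal(pulse_schedule(p, 750e-9), 0)  # inside first gap
  expect_equal(pulse_schedule(p, 200e-6), 0)  # after the burst
})

test_that("on-time identities hold across random valid protocols", {
  set.seed(42)
  for (i in 1:25) {
    # whole number of pulses per burst, as in the reference protocols
    bl <- sample(c(50, 100, 200), 1)
    n_pulses <- sample(5:100, 1)
    f <- n_pulses / bl * 1000            # kHz
    period_ns <- 1e6 / f
    pw <- runif(1, 10, min(800, 0.9 * period_ns))
    p <- pulse_protocol(runif(1, 100, 5000), pw, f, burst_length = bl)
    expect_equal(total_on_time(p), duty_cycle(p) * p$burst_length)
    # on-time equals pulses-per-burst times pulse width
    expect_equal(total_on_time(p), n_pulses * pw * 1e-3)
    # quadrature of the gate at 1 ns resolution matches the on-time to
    # within the sampling error (up to 2 ns per pulse)
    tt <- seq(0, p$burst_length * 1e-6 - 1e-9, by = 1e-9)
    on_us <- sum(pulse_schedule(p, tt)) * 1e-9 * 1e6
    n_pulses <- p$burst_length * p$rep_rate * 1e-3
    expect_lt(abs(on_us - total_on_time(p)), 2e-3 * n_pulses + 1e-6)
  }
})

test_that("empty config yields the all-defaults scenario", {
  scn <- load_scenario(text = "")
  expect_equal(scn$materials$LIVER$sigma_base, 0.067)
  expect_equal(scn$materials$TUMOR$sigma_base, 0.135)
  expect_equal(scn$protocol$voltage, 4000)
})

test_that("config overrides parse and validate", {
  scn <- load_scenario(text = "
protocol:
  voltage: 4000
  pulse_width: 500
  rep_rate: 1000
materials:
  liver:
    sigma_base: 0.08
")
  expect_equal(duty_cycle(scn$protocol), 0.5)
  expect_equal(scn$materials$LIVER$sigma_base, 0.08)
  # overfull duty cycle rejected with the offending field named
  expect_error(load_scenario(text = "protocol: {pulse_width: 2000, rep_rate: 1000}"),
               "pulse_width", class = "pulseheat_validation_error")
  expect_error(load_scenario(text = "protocl: {voltage: 1}"),
               "protocl", class = "pulseheat_config_error")
  expect_error(load_scenario(text = "geometry: {livr_diameter: 0.1}"),
               class = "pulseheat_config_error")
  expect_error(load_scenario(text = "a: [1, 2,"),
               class = "pulseheat_config_error")
})

test_that("scenario serialization round-trips", {
  scn <- default_scenario(voltage = 2500, pulse_width = 120, rep_rate = 250)
  scn$materials$LIVER$sigma_base <- 0.071
  txt <- write_scenario(scn)
  back <- load_scenario(text = txt)
  expect_equal(back, scn, tolerance = 1e-12)
  # and via file
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(scn, f)
  expect_equal(load_scenario(path = f), scn, tolerance = 1e-12)
})

test_that("shipped reference config matches the package defaults", {
  p <- system.file("extdata", "default_scenario.yaml", package = "pulseheat")
  expect_true(nzchar(p))
  expect_equal(load_scenario(path = p), scenario(), tolerance = 1e-12)
})
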