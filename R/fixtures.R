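# Analytic verification fixtures: scenarios with closed-form answers that
# exercise the production solvers (the slab runs through the same voxel
# machinery as the needle model, with planar electrode slabs instead of
# cylinders).

uniform_edges <- function(len, n, offset = 0) offset + seq(0, len, length.out = n + 1)

manual_grid <- function(x_edges, y_edges, z_edges, label, geometry) {
  structure(list(x_edges = x_edges, y_edges = y_edges, z_edges = z_edges,
                 xc = (x_edges[-1] + x_edges[-length(x_edges)]) / 2,
                 yc = (y_edges[-1] + y_edges[-length(y_edges)]) / 2,
                 zc = (z_edges[-1] + z_edges[-length(z_edges)]) / 2,
                 dx = diff(x_edges), dy = diff(y_edges), dz = diff(z_edges),
                 dim = dim(label), label = label,
                 geometry = geometry, resolution = NULL,
                 cache = new.env(parent = emptyenv())),
            class = "voxel_grid")
}

#' Planar-electrode slab fixture
#'
#' A uniform tissue slab of the given thickness between two plate
#' electrodes, whose exact solution is a uniform field `|E| = V/d`, Joule
#' density `Q = sigma V^2 / d^2` and adiabatic temperature rise
#' `dT = Q t_on / (rho c)` per burst on-time (the uniform field has no
#' gradients, so conduction is inert). The slab is labelled `TUMOR` so
#' burst maxima track it; perfusion and metabolism default to zero and
#' the conductivity temperature coefficient is disabled so the closed
#' form is exact.
#'
#' @param thickness slab thickness (m).
#' @param material tissue [material_properties()]; defaults to the tumor
#'   properties with perfusion and metabolic heat zeroed.
#' @param voltage plate potential difference (V).
#' @param pulse_width,rep_rate burst protocol (ns, kHz).
#' @param n_cells tissue layers across the slab.
#' @param e_threshold poration threshold (V/m).
#' @return list with the `scenario`, the slab `grid` and `expected`
#'   closed-form values (`e_magnitude`, `porated`, `sigma`,
#'   `joule_density`, `dt_burst` adiabatic rise over one burst).
#' @export
make_slab <- function(thickness = 0.0054, material = NULL, voltage = 540,
                      pulse_width = 500, rep_rate = 1000, n_cells = 12,
                      e_threshold = 8e4) {
  stopifnot(thickness > 0)
  if (is.null(material)) {
    tm <- default_materials()$TUMOR
    material <- material_properties(tm$rho, tm$cp, tm$k, tm$sigma_base,
                                    tm$sigma_porated)
  }
  h <- thickness / n_cells
  wid <- 3 * h
  xe <- uniform_edges(thickness + 2 * h, n_cells + 2, offset = -h)
  ye <- uniform_edges(wid, 3)
  ze <- uniform_edges(wid, 3)
  lab <- array(LABEL_LEVELS[["TUMOR"]], c(n_cells + 2, 3, 3))
  lab[1, , ] <- LABEL_LEVELS[["ELECTRODE_A"]]
  lab[n_cells + 2, , ] <- LABEL_LEVELS[["ELECTRODE_B"]]
  grid <- manual_grid(xe, ye, ze, lab, tissue_geometry())
  mats <- default_materials()
  mats$TUMOR <- material
  scn <- scenario(materials = mats,
                  protocol = pulse_protocol(voltage, pulse_width, rep_rate),
                  conductivity = conductivity_model(e_threshold = e_threshold,
                                                    alpha = 0))
  e <- voltage / thickness
  porated <- e >= e_threshold
  sigma <- if (porated) material$sigma_porated else material$sigma_base
  q <- sigma * e^2
  t_on <- total_on_time(scn$protocol) * 1e-6
  list(scenario = scn, grid = grid,
       expected = list(e_magnitude = e, porated = porated, sigma = sigma,
                       joule_density = q,
                       dt_burst = q * t_on / (material$rho * material$cp)))
}

#' Zero-dimensional uniform tissue block fixture
#'
#' A small homogeneous block with selected Pennes terms switched on,
#' packaged with its exact zero-dimensional solution: metabolism only
#' gives a linear rise `T0 + Q_m t / (rho c)`; perfusion (with or without
#' metabolism) relaxes exponentially at rate
#' `rho_b c_b omega_b / (rho c)` toward `T_b + Q_m / (rho_b c_b
#' omega_b)`. Joule heating is not supported here (use [make_slab()]).
#'
#' @param material tissue [material_properties()] template; defaults to
#'   the tumor properties.
#' @param initial_T initial temperature (degC).
#' @param conduction,perfusion,metabolism term toggles; disabled terms
#'   are zeroed in the material.
#' @param n_cells cells per edge of the block.
#' @return list with the `scenario`, the block `grid` and `closed_form`,
#'   a function of time (s) returning the exact temperature (degC).
#' @export
make_uniform_block <- function(material = NULL, initial_T = 37,
                               conduction = FALSE, perfusion = FALSE,
                               metabolism = FALSE, n_cells = 3) {
  if (is.null(material)) material <- default_materials()$TUMOR
  m <- material_properties(
    rho = material$rho, cp = material$cp,
    k = if (conduction) material$k else 0,
    sigma_base = material$sigma_base,
    sigma_porated = material$sigma_porated,
    omega_b = if (perfusion) material$omega_b else 0,
    q_met = if (metabolism) material$q_met else 0)
  if (perfusion && m$omega_b == 0)
    fail("pulseheat_fixture_error",
         "perfusion toggle requires a material with omega_b > 0")
  if (metabolism && m$q_met == 0)
    fail("pulseheat_fixture_error",
         "metabolism toggle requires a material with q_met > 0")
  side <- 0.01
  e <- uniform_edges(side, n_cells)
  lab <- array(LABEL_LEVELS[["TUMOR"]], rep(n_cells, 3))
  grid <- manual_grid(e, e, e, lab, tissue_geometry())
  mats <- default_materials()
  mats$TUMOR <- m
  bl <- blood_model()
  scn <- scenario(materials = mats,
                  protocol = pulse_protocol(0, 500, 1000),
                  blood = bl, initial_temperature = initial_T)
  rc <- m$rho * m$cp
  closed_form <- if (perfusion) {
    lam <- bl$rho_b * bl$c_b * m$omega_b / rc
    t_inf <- bl$t_b + m$q_met / (bl$rho_b * bl$c_b * m$omega_b)
    function(t) t_inf + (initial_T - t_inf) * exp(-lam * t)
  } else {
    function(t) initial_T + m$q_met * t / rc
  }
  list(scenario = scn, grid = grid, closed_form = closed_form,
       rate = if (perfusion) bl$rho_b * bl$c_b * m$omega_b / rc else
         m$q_met / rc)
}

#' Synthetic parameter sweep with a known coefficient
#'
#' Generates a sweep table whose chosen observable follows the exact law
#' `37 + a * p_w * f * V^2` plus optional Gaussian noise, emulating the
#' structure of the simulated response (linear in pulse width and
#' frequency, square law in voltage) for fitting tests.
#'
#' @param coefficient the true law coefficient `a` (degC per ns kHz V^2).
#' @param voltages,widths,rates lattice axes (V, ns, kHz).
#' @param noise_sd Gaussian noise standard deviation (degC).
#' @param seed integer seed used for the noise draw (no global state is
#'   consumed).
#' @param observable which column carries the law.
#' @return a `sweep_result` data.frame.
#' @export
make_synthetic_sweep <- function(coefficient,
                                 voltages = c(1000, 2000, 3000, 4000),
                                 widths = c(50, 100, 250, 500),
                                 rates = c(100, 250, 500, 1000),
                                 noise_sd = 0, seed = 1L,
                                 observable = "t_max_100us") {
  stopifnot(noise_sd >= 0)
  lattice <- expand.grid(voltage = voltages, pulse_width = widths,
                         rep_rate = rates, KEEP.OUT.ATTRS = FALSE)
  x <- lattice$pulse_width * lattice$rep_rate * lattice$voltage^2
  noise <- if (noise_sd > 0) {
    withr_seed <- .Random.seed_exists()
    old <- if (withr_seed) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    n <- stats::rnorm(nrow(lattice), 0, noise_sd)
    if (withr_seed) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    n
  } else 0
  lattice$t_max_100us <- T_BASELINE
  lattice$t_max_1s <- T_BASELINE
  lattice[[observable]] <- T_BASELINE + coefficient * x + noise
  lattice$omega_max_1s <- 0
  structure(lattice, class = c("sweep_result", "data.frame"))
}

.Random.seed_exists <- function() exists(".Random.seed", globalenv())

#' Constant-temperature series with closed-form damage
#'
#' @param temperature held temperature (degC).
#' @param duration hold time (s).
#' @param dt sampling step (s).
#' @param params a [damage_params()].
#' @return list with `times`, `temperatures` and the closed-form
#'   `expected_omega = A duration exp(-E/(R T_K))`.
#' @export
make_constant_T_series <- function(temperature, duration, dt = 1e-3,
                                   params = damage_params()) {
  stopifnot(dt > 0, duration >= 0)
  times <- unique(c(seq(0, duration, by = dt), duration))
  list(times = times,
       temperatures = rep(temperature, length(times)),
       expected_omega = arrhenius_rate(temperature, params) * duration)
}
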