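#' @useDynLib pulseheat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils write.csv modifyList packageVersion
NULL

# Material label codes used throughout the voxel machinery.
LABEL_LEVELS <- c(OUTSIDE = 0L, LIVER = 1L, TUMOR = 2L, ELECTRODE_A = 3L,
                  ELECTRODE_B = 4L, INSULATION = 5L)

fail <- function(class, msg, ...) {
  stop(structure(class = c(class, "pulseheat_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

validation_error <- function(field, msg, ...) {
  fail("pulseheat_validation_error", paste0("invalid `", field, "`: ", msg), ...)
}

#' Tissue, electrode and insulation material properties
#'
#' Bundles the thermal and electrical properties of one material: mass
#' density, heat capacity, thermal conductivity, baseline and
#' post-electroporation electrical conductivity, blood perfusion rate and
#' metabolic heat production.
#'
#' @param rho mass density (kg/m^3).
#' @param cp specific heat capacity (J kg^-1 K^-1).
#' @param k thermal conductivity (W m^-1 K^-1).
#' @param sigma_base baseline electrical conductivity (S/m).
#' @param sigma_porated electrical conductivity after electroporation (S/m);
#'   must be at least `sigma_base`. Defaults to `sigma_base` (no step).
#' @param omega_b blood perfusion rate (1/s).
#' @param q_met metabolic heat production (W/m^3).
#' @return an object of class `material_properties`.
#' @export
material_properties <- function(rho, cp, k, sigma_base,
                                sigma_porated = sigma_base,
                                omega_b = 0, q_met = 0) {
  m <- list(rho = rho, cp = cp, k = k, sigma_base = sigma_base,
            sigma_porated = sigma_porated, omega_b = omega_b, q_met = q_met)
  for (f in names(m)) {
    if (!is.numeric(m[[f]]) || length(m[[f]]) != 1L || is.na(m[[f]]))
      validation_error(f, "must be a single finite number")
    if (m[[f]] < 0) validation_error(f, "must be non-negative, got %g", m[[f]])
  }
  if (sigma_porated < sigma_base)
    validation_error("sigma_porated", "must be >= sigma_base (%g < %g)",
                     sigma_porated, sigma_base)
  structure(m, class = "material_properties")
}

#' Default material set for the liver-with-tumor model
#'
#' Rat-liver and tumor properties with the stepped electroporation
#' conductivities (liver 0.067 -> 0.241 S/m, tumor 0.135 -> 0.426 S/m),
#' stainless-steel electrodes and an insulating needle sheath.
#'
#' @return named list with `LIVER`, `TUMOR`, `ELECTRODE`, `INSULATION`
#'   entries, each a [material_properties()] object.
#' @export
default_materials <- function() {
  list(
    LIVER = material_properties(rho = 1080, cp = 3540, k = 0.52,
                                sigma_base = 0.067, sigma_porated = 0.241,
                                omega_b = 5e-4, q_met = 4200),
    TUMOR = material_properties(rho = 1220, cp = 4180, k = 0.6,
                                sigma_base = 0.135, sigma_porated = 0.426,
                                omega_b = 2e-3, q_met = 42000),
    ELECTRODE = material_properties(rho = 7010, cp = 450, k = 18,
                                    sigma_base = 1e8),
    INSULATION = material_properties(rho = 6450, cp = 840, k = 0.026,
                                     sigma_base = 1e-5)
  )
}

#' Arterial blood model for the Pennes perfusion term
#'
#' @param rho_b blood density (kg/m^3).
#' @param c_b blood heat capacity (J kg^-1 K^-1).
#' @param t_b arterial blood temperature (degrees C).
#' @return object of class `blood_model`.
#' @export
blood_model <- function(rho_b = 1000, c_b = 4200, t_b = 37) {
  if (rho_b <= 0) validation_error("rho_b", "must be positive")
  if (c_b <= 0) validation_error("c_b", "must be positive")
  structure(list(rho_b = rho_b, c_b = c_b, t_b = t_b), class = "blood_model")
}

#' Liver/tumor/needle geometry
#'
#' Cylindrical liver domain with a centred spherical tumor punctured by two
#' parallel needle electrodes. All lengths in metres. The energised
#' (active) electrode segments straddle the tumor's equatorial plane; the
#' needles continue to the liver surface as insulated shaft.
#'
#' @param liver_diameter,liver_height liver cylinder size (m).
#' @param tumor_diameter tumor sphere diameter (m).
#' @param needle_diameter electrode needle diameter (m).
#' @param electrode_spacing centre-to-centre distance between needles (m).
#' @param active_length energised electrode segment length (m).
#' @param tumor_center 3-vector position of the tumor centre (m) in
#'   coordinates where the liver axis is x = y = 0 and z spans
#'   `c(-liver_height, liver_height)/2`.
#' @return object of class `tissue_geometry`.
#' @export
tissue_geometry <- function(liver_diameter = 0.10, liver_height = 0.10,
                            tumor_diameter = 0.01, needle_diameter = 0.001,
                            electrode_spacing = 0.0054, active_length = 0.006,
                            tumor_center = c(0, 0, 0)) {
  g <- list(liver_diameter = liver_diameter, liver_height = liver_height,
            tumor_diameter = tumor_diameter, needle_diameter = needle_diameter,
            electrode_spacing = electrode_spacing,
            active_length = active_length,
            tumor_center = as.numeric(tumor_center))
  for (f in setdiff(names(g), "tumor_center"))
    if (g[[f]] <= 0) validation_error(f, "must be positive, got %g", g[[f]])
  if (length(g$tumor_center) != 3L)
    validation_error("tumor_center", "must be a 3-vector")
  if (electrode_spacing <= needle_diameter)
    validation_error("electrode_spacing",
                     "must exceed needle_diameter (%g <= %g)",
                     electrode_spacing, needle_diameter)
  rt <- tumor_diameter / 2
  if (sqrt(sum(g$tumor_center[1:2]^2)) + rt > liver_diameter / 2 ||
      abs(g$tumor_center[3]) + rt > liver_height / 2)
    validation_error("tumor_center",
                     "tumor sphere must lie fully inside the liver cylinder")
  structure(g, class = "tissue_geometry")
}

#' Nanosecond pulse burst protocol
#'
#' A burst is a train of unipolar rectangular pulses: `pulse_width`
#' nanoseconds high at `rep_rate` kHz repetition for a total burst of
#' `burst_length` microseconds; bursts repeat at `burst_rate` Hz and
#' `n_bursts` counts how many are delivered. These are the units the
#' fitted temperature laws are expressed in, so the protocol stores them
#' directly; solvers convert to SI at their boundary.
#'
#' @param voltage electrode potential amplitude (V).
#' @param pulse_width single-pulse high-level duration (ns).
#' @param rep_rate intra-burst repetition frequency (kHz).
#' @param burst_length total burst duration (us).
#' @param burst_rate burst repetition frequency (Hz).
#' @param n_bursts number of bursts.
#' @return object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(voltage, pulse_width, rep_rate, burst_length = 100,
                           burst_rate = 1, n_bursts = 1L) {
  if (voltage < 0) validation_error("voltage", "must be non-negative")
  if (pulse_width <= 0) validation_error("pulse_width", "must be positive")
  if (rep_rate <= 0) validation_error("rep_rate", "must be positive")
  if (burst_length <= 0) validation_error("burst_length", "must be positive")
  if (n_bursts < 1) validation_error("n_bursts", "must be >= 1")
  p <- structure(list(voltage = voltage, pulse_width = pulse_width,
                      rep_rate = rep_rate, burst_length = burst_length,
                      burst_rate = burst_rate, n_bursts = as.integer(n_bursts)),
                 class = "pulse_protocol")
  dc <- duty_cycle(p)
  if (dc > 1 + 1e-12)
    validation_error("pulse_width",
                     "duty cycle pulse_width * rep_rate = %g exceeds 1", dc)
  p
}

#' Stepped electroporation conductivity model
#'
#' Tissue conductivity switches from its baseline to its porated value
#' wherever the local field magnitude reaches `e_threshold` (the
#' irreversible-electroporation threshold, 800 V/cm by default), and both
#' states carry a linear temperature coefficient `alpha` about `t_ref`.
#'
#' @param e_threshold poration field threshold (V/m).
#' @param alpha temperature coefficient of conductivity (1/degC).
#' @param t_ref reference temperature for the coefficient (degC).
#' @return object of class `conductivity_model`.
#' @export
conductivity_model <- function(e_threshold = 8e4, alpha = 0.015, t_ref = 37) {
  if (e_threshold <= 0) validation_error("e_threshold", "must be positive")
  if (alpha < 0) validation_error("alpha", "must be non-negative")
  structure(list(e_threshold = e_threshold, alpha = alpha, t_ref = t_ref),
            class = "conductivity_model")
}

#' Numerical solver settings
#'
#' @param fine_h voxel spacing near the needles (m); must not exceed the
#'   needle radius.
#' @param tumor_h voxel spacing over the tumor bounding box (m).
#' @param coarse_h far-field voxel spacing (m).
#' @param fine_margin padding of the fine region beyond the needle
#'   surfaces (m).
#' @param grade_ratio maximum adjacent cell-size ratio of the graded grid.
#' @param dt_burst explicit time step during the burst (s).
#' @param dt_cool implicit time step during cooling (s).
#' @param t_end end of the observation window (s).
#' @param cg_tol relative residual tolerance of the conjugate-gradient
#'   solves.
#' @param cg_maxit iteration cap per conjugate-gradient solve.
#' @param refresh_dT temperature drift (degC) that triggers a re-solve of
#'   the electric field during the burst.
#' @param porate_maxit iteration cap of the poration fixed point; set to 1
#'   to evaluate the threshold on the initial-conductivity field only.
#' @param macro_stride interval (s) at which the burst phase records the
#'   running maxima, accumulates damage and checks the refresh criterion.
#' @param printed_perfusion_sign if `TRUE`, use the perfusion term with the
#'   sign `+rho_b c_b omega_b (T - T_b)` instead of the standard Pennes
#'   sink `(T_b - T)`; intended only for sensitivity checks.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(fine_h = 3e-4, tumor_h = 1e-3, coarse_h = 3.5e-3,
                            fine_margin = 1.2e-3, grade_ratio = 1.5,
                            dt_burst = 1e-8, dt_cool = 1e-3, t_end = 1,
                            cg_tol = 1e-8, cg_maxit = 50000,
                            refresh_dT = 1, porate_maxit = 50,
                            macro_stride = 1e-6,
                            printed_perfusion_sign = FALSE) {
  s <- list(fine_h = fine_h, tumor_h = tumor_h, coarse_h = coarse_h,
            fine_margin = fine_margin, grade_ratio = grade_ratio,
            dt_burst = dt_burst, dt_cool = dt_cool, t_end = t_end,
            cg_tol = cg_tol, cg_maxit = cg_maxit, refresh_dT = refresh_dT,
            porate_maxit = porate_maxit, macro_stride = macro_stride,
            printed_perfusion_sign = isTRUE(printed_perfusion_sign))
  for (f in c("fine_h", "tumor_h", "coarse_h", "dt_burst", "dt_cool",
              "t_end", "cg_tol", "refresh_dT", "macro_stride"))
    if (s[[f]] <= 0) validation_error(f, "must be positive")
  if (grade_ratio <= 1) validation_error("grade_ratio", "must exceed 1")
  structure(s, class = "solver_settings")
}

#' Full simulation scenario
#'
#' @param geometry a [tissue_geometry()].
#' @param materials named list with `LIVER`, `TUMOR`, `ELECTRODE`,
#'   `INSULATION` entries of class `material_properties`.
#' @param blood a [blood_model()].
#' @param protocol a [pulse_protocol()].
#' @param conductivity a [conductivity_model()].
#' @param initial_temperature uniform initial tissue temperature (degC);
#'   defaults to the arterial blood temperature.
#' @param solver a [solver_settings()].
#' @return object of class `scenario`.
#' @export
scenario <- function(geometry = tissue_geometry(),
                     materials = default_materials(),
                     blood = blood_model(),
                     protocol = pulse_protocol(4000, 500, 1000),
                     conductivity = conductivity_model(),
                     initial_temperature = blood$t_b,
                     solver = solver_settings()) {
  need <- c("LIVER", "TUMOR", "ELECTRODE", "INSULATION")
  if (!all(need %in% names(materials)))
    validation_error("materials", "must contain labels %s",
                     paste(setdiff(need, names(materials)), collapse = ", "))
  for (nm in need)
    if (!inherits(materials[[nm]], "material_properties"))
      validation_error(paste0("materials$", nm),
                       "must be a material_properties object")
  stopifnot(inherits(geometry, "tissue_geometry"),
            inherits(blood, "blood_model"),
            inherits(protocol, "pulse_protocol"),
            inherits(conductivity, "conductivity_model"),
            inherits(solver, "solver_settings"))
  structure(list(geometry = geometry, materials = materials[need],
                 blood = blood, protocol = protocol,
                 conductivity = conductivity,
                 initial_temperature = initial_temperature,
                 solver = solver),
            class = "scenario")
}

#' Reference scenario with all defaults
#'
#' The two-needle liver-with-tumor model at its default parameter set:
#' 10 cm liver, 1 cm tumor, 5.4 mm electrode spacing, 6 mm active length,
#' 100 us burst at 1 Hz, 800 V/cm poration threshold and 37 degC initial
#' and arterial temperature.
#'
#' @param voltage,pulse_width,rep_rate protocol overrides (V, ns, kHz).
#' @param ... further arguments passed to [scenario()].
#' @return object of class `scenario`.
#' @export
default_scenario <- function(voltage = 4000, pulse_width = 500,
                             rep_rate = 1000, ...) {
  scenario(protocol = pulse_protocol(voltage, pulse_width, rep_rate), ...)
}

#' @export
print.scenario <- function(x, ...) {
  g <- x$geometry; p <- x$protocol
  cat("<scenario>\n")
  cat(sprintf("  liver %.0f x %.0f mm, tumor d=%.0f mm, spacing %.1f mm\n",
              g$liver_diameter * 1e3, g$liver_height * 1e3,
              g$tumor_diameter * 1e3, g$electrode_spacing * 1e3))
  cat(sprintf("  protocol: %g V, %g ns @ %g kHz, burst %g us (duty %.3g)\n",
              p$voltage, p$pulse_width, p$rep_rate, p$burst_length,
              duty_cycle(p)))
  cat(sprintf("  poration threshold %g V/cm, alpha %.1f %%/degC, T0 %g degC\n",
              x$conductivity$e_threshold / 100, x$conductivity$alpha * 100,
              x$initial_temperature))
  invisible(x)
}

# ---- pulse-train arithmetic -------------------------------------------------

#' Duty cycle of a pulse protocol
#'
#' Fraction of the burst during which the voltage is high:
#' `pulse_width * rep_rate` in consistent units.
#'
#' @param protocol a [pulse_protocol()].
#' @return dimensionless fraction in (0, 1].
#' @export
duty_cycle <- function(protocol) {
  protocol$pulse_width * 1e-9 * protocol$rep_rate * 1e3
}

#' Total high-level time within one burst
#'
#' @param protocol a [pulse_protocol()].
#' @return on-time in microseconds; equals
#'   `duty_cycle(protocol) * burst_length`.
#' @export
total_on_time <- function(protocol) {
  duty_cycle(protocol) * protocol$burst_length
}

#' Pulse train gate function
#'
#' Indicator of whether the voltage is high at time `t` after burst start.
#'
#' @param protocol a [pulse_protocol()].
#' @param t time since burst start (s); vectorised.
#' @return 0/1 vector.
#' @export
pulse_schedule <- function(protocol, t) {
  stopifnot(all(t >= 0))
  period <- 1 / (protocol$rep_rate * 1e3)
  width <- protocol$pulse_width * 1e-9
  blen <- protocol$burst_length * 1e-6
  as.numeric((t %% period) < width & t < blen)
}

# ---- config parsing / serialization ----------------------------------------

scenario_schema <- function() {
  list(geometry = names(unclass(tissue_geometry())),
       materials = c("liver", "tumor", "electrode", "insulation"),
       material = names(unclass(material_properties(1, 1, 1, 1))),
       blood = names(unclass(blood_model())),
       protocol = names(unclass(pulse_protocol(1, 1, 1))),
       conductivity = names(unclass(conductivity_model())),
       solver = names(unclass(solver_settings())))
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    fail("pulseheat_config_error", "unknown key(s) in %s: %s", where,
         paste(bad, collapse = ", "))
}

#' Load a scenario from a YAML configuration
#'
#' Parses a nested key-value document with sections `geometry`,
#' `materials` (subsections `liver`, `tumor`, `electrode`, `insulation`),
#' `blood`, `protocol`, `conductivity`, `solver` and the scalar
#' `initial_temperature`. Omitted fields take the package defaults;
#' unknown keys are rejected. A reference config documenting every
#' default ships at
#' `system.file("extdata", "default_scenario.yaml", package = "pulseheat")`.
#'
#' @param path path to a YAML file, or
#' @param text YAML text (used when `path` is `NULL`).
#' @return a validated [scenario()].
#' @export
load_scenario <- function(path = NULL, text = NULL) {
  doc <- tryCatch(
    if (!is.null(path)) yaml::read_yaml(path) else
      yaml::yaml.load(if (is.null(text)) "" else text),
    error = function(e) fail("pulseheat_config_error",
                             "config parse failure: %s", conditionMessage(e)))
  if (is.null(doc)) doc <- list()
  if (!is.list(doc))
    fail("pulseheat_config_error", "config must be a key-value mapping")
  sch <- scenario_schema()
  check_keys(doc, c("geometry", "materials", "blood", "protocol",
                    "conductivity", "solver", "initial_temperature"),
             "top level")
  check_keys(doc$geometry, sch$geometry, "geometry")
  check_keys(doc$materials, sch$materials, "materials")
  for (m in names(doc$materials))
    check_keys(doc$materials[[m]], sch$material, paste0("materials.", m))
  check_keys(doc$blood, sch$blood, "blood")
  check_keys(doc$protocol, sch$protocol, "protocol")
  check_keys(doc$conductivity, sch$conductivity, "conductivity")
  check_keys(doc$solver, sch$solver, "solver")

  mats <- default_materials()
  for (m in names(doc$materials)) {
    M <- toupper(m)
    mats[[M]] <- do.call(material_properties,
                         modifyList(unclass(mats[[M]]), doc$materials[[m]]))
  }
  blood <- do.call(blood_model,
                   modifyList(unclass(blood_model()), as.list(doc$blood)))
  scn <- scenario(
    geometry = do.call(tissue_geometry,
                       modifyList(unclass(tissue_geometry()),
                                  as.list(doc$geometry))),
    materials = mats,
    blood = blood,
    protocol = do.call(pulse_protocol,
                       modifyList(unclass(pulse_protocol(4000, 500, 1000)),
                                  as.list(doc$protocol))),
    conductivity = do.call(conductivity_model,
                           modifyList(unclass(conductivity_model()),
                                      as.list(doc$conductivity))),
    solver = do.call(solver_settings,
                     modifyList(unclass(solver_settings()),
                                as.list(doc$solver))),
    initial_temperature = if (!is.null(doc$initial_temperature))
      doc$initial_temperature else blood$t_b)
  scn
}

#' Serialize a scenario back to YAML
#'
#' Round-trips with [load_scenario()]: the serialized text parses to an
#' equal scenario.
#'
#' @param scn a [scenario()].
#' @param path optional output file; when `NULL` the YAML text is returned.
#' @return YAML text (invisibly when written to `path`).
#' @export
write_scenario <- function(scn, path = NULL) {
  stopifnot(inherits(scn, "scenario"))
  doc <- list(
    geometry = unclass(scn$geometry),
    materials = setNames(lapply(scn$materials, unclass),
                         tolower(names(scn$materials))),
    blood = unclass(scn$blood),
    protocol = unclass(scn$protocol),
    conductivity = unclass(scn$conductivity),
    solver = unclass(scn$solver),
    initial_temperature = scn$initial_temperature)
  txt <- yaml::as.yaml(doc, precision = 15L)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
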