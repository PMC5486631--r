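# Pennes bioheat integration: explicit forward-Euler through the burst with
# the pulse-gated Joule source, implicit backward-Euler through the cooling
# window, with Arrhenius damage accumulated on the fly.  The thermal
# stencil lives on the full grid box as face-conductance arrays (gx, gy,
# gz give the +axis face of each cell), which the compiled kernels sweep
# with fixed index offsets.

thermal_system <- function(grid, materials, blood, printed_sign = FALSE) {
  key <- list(k = lapply(materials, function(m) m[c("k", "rho", "cp",
                                                    "omega_b", "q_met")]),
              blood = unclass(blood), sign = printed_sign)
  cached <- grid$cache$thermal_sys
  if (!is.null(cached) && identical(cached$key, key)) return(cached)
  d <- grid$dim
  active <- grid$label > 0
  kcell <- material_field(grid, materials, "k")
  kcell[!active] <- 0
  fc <- face_conductances(grid, kcell)
  vol <- voxel_volumes(grid)
  rho <- material_field(grid, materials, "rho")
  cp <- material_field(grid, materials, "cp")
  wb <- material_field(grid, materials, "omega_b")
  qm <- material_field(grid, materials, "q_met")
  zero_na <- function(x) { x[is.na(x)] <- 0; x }
  cheat <- zero_na(rho * cp * vol)
  perf <- zero_na(blood$rho_b * blood$c_b * wb * vol)
  if (printed_sign) perf <- -perf
  s_base <- zero_na(qm * vol)
  gsum <- array(0, d)
  for (ax in 1:3) {
    s <- shift_op(d, ax)
    g <- fc[[ax]]
    gface <- do.call(`[`, c(list(g), s$l))
    gsum <- do.call(`[<-`, c(list(gsum), s$l,
                             list(do.call(`[`, c(list(gsum), s$l)) + gface)))
    gsum <- do.call(`[<-`, c(list(gsum), s$r,
                             list(do.call(`[`, c(list(gsum), s$r)) + gface)))
  }
  sys <- list(key = key, dim = d, active = active,
              gx = fc$gx, gy = fc$gy, gz = fc$gz, gsum = gsum,
              cheat = cheat, perf = perf, s_base = s_base, vol = vol,
              tumor_cells = which(grid$label == LABEL_LEVELS[["TUMOR"]]))
  grid$cache$thermal_sys <- sys
  sys
}

# conduction operator K T on the full box (R-side, for pennes_rhs and tests)
apply_conduction <- function(sys, temp) {
  d <- sys$dim
  acc <- array(0, d)
  for (ax in 1:3) {
    s <- shift_op(d, ax)
    g <- sys[[c("gx", "gy", "gz")[ax]]]
    f <- do.call(`[`, c(list(g), s$l)) *
      (do.call(`[`, c(list(temp), s$r)) - do.call(`[`, c(list(temp), s$l)))
    acc <- do.call(`[<-`, c(list(acc), s$l,
                            list(do.call(`[`, c(list(acc), s$l)) + f)))
    acc <- do.call(`[<-`, c(list(acc), s$r,
                            list(do.call(`[`, c(list(acc), s$r)) - f)))
  }
  acc
}

#' Right-hand side of the Pennes bioheat equation
#'
#' Evaluates `[div(k grad T) + rho_b c_b omega_b (T_b - T) + Q_m + source]
#' / (rho c)` per voxel with harmonic face-averaged conductivity and
#' zero-flux outer boundaries.
#'
#' @param temperature per-voxel temperature array (degC).
#' @param grid a [build_grid()] result.
#' @param materials material list as in [scenario()].
#' @param blood a [blood_model()].
#' @param source per-voxel volumetric heat source (W/m^3); scalar or array.
#' @param printed_perfusion_sign use the non-standard perfusion sign
#'   `+(T - T_b)` (sensitivity checks only).
#' @return array of temperature rates (degC/s); `NA` outside the domain.
#' @export
pennes_rhs <- function(temperature, grid, materials, blood, source = 0,
                       printed_perfusion_sign = FALSE) {
  sys <- thermal_system(grid, materials, blood, printed_perfusion_sign)
  acc <- apply_conduction(sys, temperature)
  src <- if (length(source) == 1) array(source, sys$dim) else source
  out <- (acc + sys$perf * (blood$t_b - temperature) + sys$s_base +
            src * sys$vol) / sys$cheat
  out[!sys$active] <- NA_real_
  out
}

#' Simulate one pulse burst and the cooling window
#'
#' Integrates the Pennes equation from 0 to `burst_length` with explicit
#' forward-Euler steps (`dt_burst`, 10 ns by default) and the Joule source
#' either gated pulse-by-pulse (`mode = "exact"`) or scaled by the duty
#' cycle and applied continuously (`mode = "averaged"`), then from
#' `burst_length` to `t_end` with implicit backward-Euler steps
#' (`dt_cool`, 1 ms by default) and the source off. The electric field is
#' solved self-consistently with the poration switch at burst start and
#' refreshed whenever the temperature has drifted more than `refresh_dT`
#' since the last solve. Arrhenius damage is accumulated trapezoidally
#' alongside the integration.
#'
#' Two peak-temperature observables are reported for the tumor: the
#' maximum over all tumor voxels (`tumor_peak_100us` / `tumor_peak_1s`)
#' and the maximum over the tumor's equatorial cross-section
#' (`t_max_100us` / `t_max_1s`), the plane the reference spatial maps are
#' evaluated on. The flat electrode tips end in a singular edge whose
#' pointwise temperature grows without bound under grid refinement, so
#' the volume maximum is mesh-defined; the equatorial-plane maximum sits
#' in a regular part of the field and is the headline dosimetric
#' quantity (see the methods vignette).
#'
#' @param scn a [scenario()].
#' @param grid optional pre-built [build_grid()]; defaults to the
#'   scenario's resolution settings.
#' @param mode `"averaged"` or `"exact"`.
#' @param damage a [damage_params()] kinetics set.
#' @return object of class `burst_result`: the (time, max tumor T, max
#'   domain T) series, temperature fields at the end of the burst and at
#'   `t_end`, the damage field, peak tumor temperatures and damage, and
#'   the final [porate_fixed_point()] field solution.
#' @export
simulate_burst <- function(scn, grid = NULL, mode = c("averaged", "exact"),
                           damage = damage_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(scn, "scenario"))
  if (is.null(grid))
    grid <- build_grid(scn$geometry, grid_spec_from_solver(scn$solver))
  sv <- scn$solver
  prot <- scn$protocol
  sys <- thermal_system(grid, scn$materials, scn$blood,
                        sv$printed_perfusion_sign)
  d <- sys$dim
  active <- sys$active

  dt <- sv$dt_burst
  burst_s <- prot$burst_length * 1e-6
  stab <- min((sys$cheat / (sys$gsum + pmax(sys$perf, 0)))[active])
  if (dt >= stab)
    fail("pulseheat_step_error",
         "explicit step %g s violates the stability limit %g s", dt, stab)
  idt <- array(0, d)
  idt[active] <- dt / sys$cheat[active]
  macro <- sv$macro_stride
  steps_per_macro <- max(1L, as.integer(round(macro / dt)))
  n_macro <- max(1L, as.integer(round(burst_s / (steps_per_macro * dt))))

  Tv <- array(scn$initial_temperature, d)
  omega <- array(0, d)
  e_over_r <- damage$e_activation / damage$r_gas

  field_solves <- 0L
  refresh_field <- function(Tarr, fs_prev) {
    fs <- porate_fixed_point(grid, scn$materials, scn$conductivity,
                             prot$voltage, temperature = Tarr,
                             porated = if (is.null(fs_prev)) NULL else
                               fs_prev$porated,
                             tol = sv$cg_tol, maxit = sv$cg_maxit,
                             porate_maxit = sv$porate_maxit,
                             phi0 = if (is.null(fs_prev)) NULL else
                               fs_prev$potential)
    field_solves <<- field_solves + fs$iterations
    fs
  }
  fs <- refresh_field(Tv, NULL)
  s_joule <- fs$joule_density * sys$vol
  s_joule[!active] <- 0
  T_at_solve <- Tv

  duty <- duty_cycle(prot)
  n_steps <- n_macro * steps_per_macro
  gate_all <- if (mode == "averaged") rep(duty, n_steps) else
    pulse_schedule(prot, (seq_len(n_steps) - 1) * dt)
  rate_prev <- as.numeric(arrhenius_rate(Tv, damage))
  ser_t <- ser_tum <- ser_dom <- numeric(0)
  step_at <- 0L
  Tvv <- as.numeric(Tv)
  omv <- as.numeric(omega)
  while (step_at < n_steps) {
    bp <- burst_phase(as.integer(d), sys$gx, sys$gy, sys$gz, idt,
                      sys$perf, sys$s_base, as.numeric(s_joule),
                      gate_all[(step_at + 1):n_steps], scn$blood$t_b, dt,
                      step_at, Tvv, omv, rate_prev, damage$a_factor,
                      e_over_r, as.integer(active),
                      as.integer(sys$tumor_cells),
                      steps_per_macro, as.numeric(T_at_solve),
                      sv$refresh_dT)
    Tvv <- bp$temperature
    omv <- bp$omega
    rate_prev <- bp$rate_prev
    step_at <- step_at + bp$steps_done
    ser_t <- c(ser_t, bp$series_t)
    ser_tum <- c(ser_tum, bp$series_max_tumor)
    ser_dom <- c(ser_dom, bp$series_max_domain)
    if (bp$diverged)
      fail("pulseheat_blowup_error",
           "temperature field diverged at t = %g s", step_at * dt)
    if (step_at < n_steps) {
      Tv <- array(Tvv, d)
      fs <- refresh_field(Tv, fs)
      s_joule <- fs$joule_density * sys$vol
      s_joule[!active] <- 0
      T_at_solve <- Tv
    }
  }
  Tv <- array(Tvv, d)
  omega <- array(omv, d)
  t100 <- Tv
  plane <- equatorial_cells(grid)

  # cooling: source off, implicit stepping to t_end
  n_cool <- max(1L, as.integer(round((sv$t_end - burst_s) / sv$dt_cool)))
  dt2 <- (sv$t_end - burst_s) / n_cool
  rec <- max(1L, as.integer(round(0.01 / dt2)))
  cp_res <- cool_phase(as.integer(d), sys$gx, sys$gy, sys$gz, sys$cheat,
                       sys$perf, sys$s_base, as.integer(active),
                       scn$blood$t_b, dt2, n_cool, burst_s,
                       as.numeric(Tv), as.numeric(omega),
                       damage$a_factor, e_over_r,
                       as.integer(sys$tumor_cells), rec,
                       sv$cg_tol, as.integer(sv$cg_maxit))
  Tend <- array(cp_res$temperature, d)
  omega <- array(cp_res$omega, d)
  omega[!active] <- 0

  series <- data.frame(
    time = c(ser_t, cp_res$series_t),
    max_tumor = c(ser_tum, cp_res$series_max_tumor),
    max_domain = c(ser_dom, cp_res$series_max_domain))
  t100[!active] <- NA_real_
  Tend[!active] <- NA_real_

  structure(list(
    series = series,
    t_max_100us = max(t100[plane]),
    t_max_1s = max(Tend[plane]),
    omega_max_1s = max(omega[plane]),
    tumor_peak_100us = max(t100[sys$tumor_cells]),
    tumor_peak_1s = max(Tend[sys$tumor_cells]),
    tumor_peak_omega_1s = max(omega[sys$tumor_cells]),
    domain_max_100us = max(t100, na.rm = TRUE),
    domain_max_1s = max(Tend, na.rm = TRUE),
    temperature_100us = t100,
    temperature_1s = Tend,
    omega = omega,
    field = fs,
    porated_count = sum(fs$porated),
    mode = mode, field_solves = field_solves,
    burst_length = prot$burst_length, t_end = sv$t_end,
    protocol = prot),
    class = "burst_result")
}

# tumor voxels in the layer(s) straddling the tumor's equatorial plane
equatorial_cells <- function(grid) {
  zc0 <- grid$geometry$tumor_center[3]
  dz <- abs(grid$zc - zc0)
  layers <- which(dz <= min(dz) + 1e-12)
  sel <- array(FALSE, grid$dim)
  sel[, , layers] <- TRUE
  which(sel & grid$label == LABEL_LEVELS[["TUMOR"]])
}

#' @export
print.burst_result <- function(x, ...) {
  cat(sprintf("<burst_result> %g V, %g ns @ %g kHz (%s mode)\n",
              x$protocol$voltage, x$protocol$pulse_width,
              x$protocol$rep_rate, x$mode))
  cat(sprintf("  peak tumor T (equatorial plane): %.2f degC at %g us, %.2f degC at %g s\n",
              x$t_max_100us, x$burst_length, x$t_max_1s, x$t_end))
  cat(sprintf("  peak tumor T (full volume, tip-edge limited): %.2f / %.2f degC\n",
              x$tumor_peak_100us, x$tumor_peak_1s))
  cat(sprintf("  peak tumor damage Omega at %g s: %.3g; %d porated voxels\n",
              x$t_end, x$omega_max_1s, x$porated_count))
  invisible(x)
}
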