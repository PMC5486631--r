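# Quasi-static electric solve: -div(sigma grad phi) = 0 on the tissue
# voxels (LIVER, TUMOR), Dirichlet phi = V on electrode-A-adjacent faces and
# phi = 0 on electrode-B-adjacent faces, zero normal current elsewhere.
# The electrode interiors are equipotential bodies excluded from the solve;
# the insulating sheath (sigma ~ 1e-5 S/m, four orders below tissue) is
# treated as a zero-current boundary.

TISSUE_CODES <- function() unname(LABEL_LEVELS[c("LIVER", "TUMOR")])

# Dirichlet face conductances toward each electrode, per cell: a face
# between a tissue cell and an electrode body carries conductance
# area * sigma_cell / h_cell (the electrode side has no resistance).
# The face geometry is cached on the grid; only sigma varies per call.
electrode_faces <- function(grid) {
  if (!is.null(grid$cache$elec_faces)) return(grid$cache$elec_faces)
  d <- grid$dim
  tissue <- array(grid$label %in% TISSUE_CODES(), d)
  aa <- axis_arrays(grid)
  lin <- array(seq_len(prod(d)), d)
  cell <- integer(0); geo <- numeric(0); elec <- integer(0)
  for (ax in 1:3) {
    s <- shift_op(d, ax)
    gl <- slab_get(grid$label, s$l); gr <- slab_get(grid$label, s$r)
    tl <- slab_get(tissue, s$l); tr <- slab_get(tissue, s$r)
    gface <- slab_get(aa$area[[ax]], s$l)
    hl <- slab_get(aa$h[[ax]], s$l); hr <- slab_get(aa$h[[ax]], s$r)
    cl <- slab_get(lin, s$l); cr <- slab_get(lin, s$r)
    for (code in unname(LABEL_LEVELS[c("ELECTRODE_A", "ELECTRODE_B")])) {
      m <- tl & (gr == code)   # tissue left of an electrode body
      cell <- c(cell, cl[m]); geo <- c(geo, (gface / hl)[m])
      elec <- c(elec, rep.int(code, sum(m)))
      m2 <- tr & (gl == code)  # tissue right of an electrode body
      cell <- c(cell, cr[m2]); geo <- c(geo, (gface / hr)[m2])
      elec <- c(elec, rep.int(code, sum(m2)))
    }
  }
  ef <- list(cell = cell, geo = geo, elec = elec, tissue = tissue)
  grid$cache$elec_faces <- ef
  ef
}

electrode_coupling <- function(grid, sigma) {
  ef <- electrode_faces(grid)
  d <- grid$dim
  gdA <- array(0, d); gdB <- array(0, d)
  gd <- ef$geo * sigma[ef$cell]
  isA <- ef$elec == LABEL_LEVELS[["ELECTRODE_A"]]
  add_faces <- function(arr, cells, vals) {
    if (length(cells)) {
      s <- rowsum(vals, cells)
      arr[as.integer(rownames(s))] <- arr[as.integer(rownames(s))] + s[, 1]
    }
    arr
  }
  gdA <- add_faces(gdA, ef$cell[isA], gd[isA])
  gdB <- add_faces(gdB, ef$cell[!isA], gd[!isA])
  list(gdA = gdA, gdB = gdB, tissue = ef$tissue)
}

#' Effective per-voxel electrical conductivity
#'
#' Baseline or post-electroporation conductivity depending on the porated
#' mask, scaled by the linear temperature coefficient
#' `1 + alpha (T - t_ref)`.
#'
#' @param grid a [build_grid()] result.
#' @param materials material list as in [scenario()].
#' @param conductivity a [conductivity_model()].
#' @param porated logical array of porated voxels (or `NULL` for none).
#' @param temperature per-voxel temperature array in degC (or a scalar).
#' @return array of conductivities (S/m); `NA` outside the domain.
#' @export
effective_sigma <- function(grid, materials, conductivity,
                            porated = NULL, temperature = NULL) {
  sb <- material_field(grid, materials, "sigma_base")
  sp <- material_field(grid, materials, "sigma_porated")
  sig <- sb
  if (!is.null(porated)) sig[porated] <- sp[porated]
  if (!is.null(temperature)) {
    fac <- 1 + conductivity$alpha * (temperature - conductivity$t_ref)
    sig <- sig * fac
  }
  sig
}

#' Solve the quasi-static potential equation
#'
#' Seven-point finite-volume discretisation of `-div(sigma grad phi) = 0`
#' with harmonic averaging of sigma on faces, solved by
#' Jacobi-preconditioned conjugate gradient. Dirichlet conditions are
#' applied on tissue faces adjacent to the electrode bodies (`voltage` at
#' electrode A, 0 at electrode B); all remaining boundaries carry zero
#' normal current.
#'
#' @param grid a [build_grid()] result.
#' @param sigma per-voxel conductivity array (S/m), positive on tissue.
#' @param voltage applied electrode potential (V).
#' @param tol,maxit conjugate-gradient relative tolerance and iteration
#'   cap.
#' @param phi0 optional warm-start potential array.
#' @return array of potentials (V) on tissue voxels; electrode voxels carry
#'   their fixed potential, other voxels `NA`. Attributes `iterations`,
#'   `relres` and `currents` (total current through each electrode
#'   surface, A) record the solve.
#' @export
solve_potential <- function(grid, sigma, voltage, tol = 1e-8, maxit = 50000,
                            phi0 = NULL) {
  d <- grid$dim
  ec <- electrode_coupling(grid, sigma)
  tissue <- ec$tissue
  if (any(!is.finite(sigma[tissue])) || any(sigma[tissue] <= 0))
    fail("pulseheat_validation_error",
         "sigma must be positive on all tissue voxels")
  sig <- sigma
  sig[!tissue] <- 0
  fc <- face_conductances(grid, sig)
  gsum <- face_rowsum(d, fc)
  adiag <- ec$gdA + ec$gdB
  adiag[!tissue] <- 1
  pdiag <- adiag + gsum
  b <- ec$gdA * voltage
  b[!tissue] <- 0
  x0 <- if (!is.null(phi0)) phi0 else array(0, d)
  x0[is.na(x0)] <- 0
  x0[!tissue] <- 0
  sol <- box_pcg(as.integer(d), fc$gx, fc$gy, fc$gz, adiag, pdiag,
                 as.numeric(b), as.numeric(x0), tol, as.integer(maxit))
  if (sol$relres > tol * 10 && sol$iterations >= maxit)
    fail("pulseheat_solver_error",
         "potential solve did not converge: relres %.3g after %d iterations",
         sol$relres, sol$iterations)
  phi <- array(sol$x, d)
  curr <- c(A = sum(ec$gdA * (voltage - phi)),
            B = sum(ec$gdB * phi))
  phi[!tissue] <- NA_real_
  phi[grid$label == LABEL_LEVELS[["ELECTRODE_A"]]] <- voltage
  phi[grid$label == LABEL_LEVELS[["ELECTRODE_B"]]] <- 0
  structure(phi, iterations = sol$iterations, relres = sol$relres,
            currents = curr)
}

#' Electric field magnitude, current density and Joule heating
#'
#' Per-voxel field from a Green-Gauss cell-gradient reconstruction of the
#' solved potential: each axis component is the difference of the two
#' face potentials across the full cell width, with interface potentials
#' taken flux-consistently (conductance-weighted, exact for layered 1-D
#' profiles), electrode faces at their fixed potential and zero-current
#' faces at the cell value. The averaging support of the reconstruction
#' is thus the whole cell, which sets the effective regularisation scale
#' of the singular field at the electrode edges. `|J| = sigma |E|` and
#' `Q = sigma |E|^2` follow voxel-wise.
#'
#' @param potential potential array from [solve_potential()].
#' @param grid a [build_grid()] result.
#' @param sigma the conductivity array the potential was solved with.
#' @return list with arrays `e_magnitude` (V/m), `current_density`
#'   (A/m^2) and `joule_density` (W/m^3); zero outside tissue.
#' @export
field_and_joule <- function(potential, grid, sigma) {
  d <- grid$dim
  tissue <- array(grid$label %in% TISSUE_CODES(), d)
  voltage <- attr_voltage(potential, grid)
  phi <- potential
  phi[!tissue] <- 0
  aa <- axis_arrays(grid)
  e2 <- array(0, d)
  codeA <- LABEL_LEVELS[["ELECTRODE_A"]]
  codeB <- LABEL_LEVELS[["ELECTRODE_B"]]
  for (ax in 1:3) {
    s <- shift_op(d, ax)
    hl <- slab_get(aa$h[[ax]], s$l); hr <- slab_get(aa$h[[ax]], s$r)
    sl <- slab_get(sigma, s$l); sr <- slab_get(sigma, s$r)
    sl[is.na(sl)] <- 0; sr[is.na(sr)] <- 0
    tl <- slab_get(tissue, s$l); tr <- slab_get(tissue, s$r)
    pl <- slab_get(phi, s$l); pr <- slab_get(phi, s$r)
    ll <- slab_get(grid$label, s$l); lr <- slab_get(grid$label, s$r)
    al <- sl / hl; ar <- sr / hr
    # face potential seen from each side: flux-weighted between tissue
    # cells, the fixed potential against electrodes, the cell value
    # elsewhere (zero-current face)
    pf <- (al * pl + ar * pr) / (al + ar)
    both <- tl & tr
    face_l <- pf; face_l[!both] <- pl[!both]
    face_l[lr == codeA] <- voltage; face_l[lr == codeB] <- 0
    face_r <- pf; face_r[!both] <- pr[!both]
    face_r[ll == codeA] <- voltage; face_r[ll == codeB] <- 0
    # gradient contribution: (phi_c - phi_face)/(2 h_c) on the +axis side
    comp <- array(0, d)
    comp <- slab_set(comp, s$l, slab_get(comp, s$l) + (pl - face_l) / (2 * hl))
    comp <- slab_set(comp, s$r, slab_get(comp, s$r) + (face_r - pr) / (2 * hr))
    e2 <- e2 + comp^2
  }
  emag <- sqrt(e2)
  emag[!tissue] <- 0
  sig0 <- sigma
  sig0[!tissue] <- 0
  sig0[is.na(sig0)] <- 0
  list(e_magnitude = emag, current_density = sig0 * emag,
       joule_density = sig0 * emag^2)
}

# the applied voltage is recoverable from the electrode-A voxels
attr_voltage <- function(potential, grid) {
  a <- which(grid$label == LABEL_LEVELS[["ELECTRODE_A"]])
  if (length(a)) potential[a[1]] else 0
}

#' Self-consistent electroporation field solution
#'
#' Iterates potential solve, field evaluation and the 800 V/cm poration
#' switch until the porated voxel set is stationary. The set only grows:
#' poration is irreversible within a burst. Conductivity combines the
#' two-state step model with the linear temperature coefficient.
#'
#' @param grid a [build_grid()] result.
#' @param materials material list as in [scenario()].
#' @param conductivity a [conductivity_model()].
#' @param voltage applied electrode potential (V).
#' @param temperature per-voxel temperature (degC array or scalar, default
#'   the reference temperature).
#' @param porated initial porated mask (logical array), grown in place.
#' @param tol,maxit conjugate-gradient controls.
#' @param porate_maxit fixed-point iteration cap; 1 evaluates the
#'   threshold on the initial-conductivity field without re-solving.
#' @param phi0 optional warm-start potential array.
#' @return object of class `field_solution`: arrays `potential`,
#'   `e_magnitude`, `current_density`, `joule_density`, `sigma_effective`,
#'   logical `porated`, plus the iteration count and electrode currents.
#' @export
porate_fixed_point <- function(grid, materials, conductivity, voltage,
                               temperature = NULL, porated = NULL,
                               tol = 1e-8, maxit = 50000, porate_maxit = 50,
                               phi0 = NULL) {
  if (is.null(porated)) porated <- array(FALSE, grid$dim)
  tissue <- array(grid$label %in% TISSUE_CODES(), grid$dim)
  phi <- phi0
  it <- 0L
  repeat {
    it <- it + 1L
    sigma <- effective_sigma(grid, materials, conductivity, porated,
                             temperature)
    phi <- solve_potential(grid, sigma, voltage, tol, maxit, phi0 = phi)
    fj <- field_and_joule(phi, grid, sigma)
    newly <- tissue & !porated & (fj$e_magnitude >= conductivity$e_threshold)
    if (!any(newly) || it >= porate_maxit) {
      if (any(newly) && it >= porate_maxit && porate_maxit > 1)
        fail("pulseheat_convergence_error",
             "poration fixed point not reached after %d iterations (%d voxels still switching)",
             it, sum(newly))
      porated <- porated | newly
      break
    }
    porated <- porated | newly
  }
  structure(list(potential = phi, e_magnitude = fj$e_magnitude,
                 current_density = fj$current_density,
                 joule_density = fj$joule_density,
                 sigma_effective = sigma, porated = porated,
                 iterations = it, currents = attr(phi, "currents"),
                 voltage = voltage),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> V = %g V, %d porated voxels, %d fixed-point iteration(s)\n",
              x$voltage, sum(x$porated), x$iterations))
  cat(sprintf("  currents: A %.4g A, B %.4g A; max |E| %.4g V/m\n",
              x$currents[["A"]], x$currents[["B"]],
              max(x$e_magnitude, na.rm = TRUE)))
  invisible(x)
}
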