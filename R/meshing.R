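# Graded structured voxel grid over the liver cylinder.
#
# Each axis is discretised independently: a target-spacing field takes the
# fine spacing inside refinement windows (needle neighbourhoods, the tumor
# box, the active-segment z range) and grows linearly with distance from the
# nearest window at slope (r - 1)/r, capped at the coarse spacing.  Marching
# through that field yields adjacent cell-size ratios bounded by the grade
# ratio r in both directions.

#' Grid resolution specification
#'
#' @param fine_h spacing near the needle surfaces (m); must not exceed the
#'   needle radius.
#' @param tumor_h spacing over the tumor bounding box (m).
#' @param coarse_h far-field spacing (m).
#' @param fine_margin padding of the fine region beyond the needle
#'   surfaces (m).
#' @param grade_ratio maximum adjacent cell-size ratio.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(fine_h = 3e-4, tumor_h = 1e-3, coarse_h = 3.5e-3,
                      fine_margin = 1.2e-3, grade_ratio = 1.5) {
  stopifnot(fine_h > 0, tumor_h >= fine_h, coarse_h >= tumor_h,
            fine_margin >= 0, grade_ratio > 1)
  structure(list(fine_h = fine_h, tumor_h = tumor_h, coarse_h = coarse_h,
                 fine_margin = fine_margin, grade_ratio = grade_ratio),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> fine %.2g mm / tumor %.2g mm / coarse %.2g mm, ratio %.2f\n",
              x$fine_h * 1e3, x$tumor_h * 1e3, x$coarse_h * 1e3, x$grade_ratio))
  invisible(x)
}

grid_spec_from_solver <- function(s) {
  grid_spec(fine_h = s$fine_h, tumor_h = s$tumor_h, coarse_h = s$coarse_h,
            fine_margin = s$fine_margin, grade_ratio = s$grade_ratio)
}

# windows: data.frame(lo, hi, h).  Target spacing at x is the minimum over
# windows of h_w + slope * distance(x, window), capped at coarse_h.
graded_axis <- function(lo, hi, windows, coarse_h, ratio) {
  slope <- (ratio - 1) / ratio
  target <- function(x) {
    h <- rep(coarse_h, length(x))
    if (nrow(windows))
      for (w in seq_len(nrow(windows))) {
        d <- pmax(0, pmax(windows$lo[w] - x, x - windows$hi[w]))
        h <- pmin(h, windows$h[w] + slope * d)
      }
    h
  }
  march <- function(from, to) {
    edges <- from
    x <- from
    while (x < to - 1e-12) {
      x <- x + target(x)
      edges <- c(edges, x)
    }
    # rescale uniformly so the last edge lands exactly on `to`
    widths <- diff(edges) * (to - from) / (edges[length(edges)] - from)
    cumsum(c(from, widths))
  }
  # mirror-symmetric window sets get a mirror-symmetric axis
  mid <- (lo + hi) / 2
  refl <- data.frame(lo = sort(2 * mid - windows$hi),
                     hi = sort(2 * mid - windows$lo),
                     h = windows$h[order(-windows$hi)])
  symmetric <- nrow(windows) == 0 ||
    (isTRUE(all.equal(sort(windows$lo), refl$lo, tolerance = 1e-9)) &&
       isTRUE(all.equal(sort(windows$hi), refl$hi, tolerance = 1e-9)))
  if (symmetric) {
    half <- march(mid, hi)
    c(rev((2 * mid - half)[-1]), half)
  } else {
    march(lo, hi)
  }
}

#' Build a graded voxel grid and label every voxel
#'
#' Covers the bounding box of the liver cylinder with a tensor-product
#' graded grid and labels each voxel by a containment test of its centre,
#' in order: electrode / insulation cylinders, tumor sphere, liver
#' cylinder, else `OUTSIDE`. Electrode A sits at negative x relative to
#' the tumor centre, electrode B at positive x; the energised segments of
#' length `active_length` are centred on the tumor's equatorial plane and
#' the needles continue to the liver surface as `INSULATION`.
#'
#' @param geometry a [tissue_geometry()].
#' @param resolution a [grid_spec()].
#' @return object of class `voxel_grid`: edge coordinate vectors, the
#'   integer label array (levels `OUTSIDE`, `LIVER`, `TUMOR`,
#'   `ELECTRODE_A`, `ELECTRODE_B`, `INSULATION`) and cached cell metrics.
#' @export
build_grid <- function(geometry = tissue_geometry(), resolution = grid_spec()) {
  stopifnot(inherits(geometry, "tissue_geometry"),
            inherits(resolution, "grid_spec"))
  rn <- geometry$needle_diameter / 2
  if (resolution$fine_h > rn)
    fail("pulseheat_resolution_error",
         "fine spacing %g m exceeds the needle radius %g m; needles would vanish",
         resolution$fine_h, rn)
  R <- geometry$liver_diameter / 2
  H <- geometry$liver_height / 2
  tc <- geometry$tumor_center
  rt <- geometry$tumor_diameter / 2
  s2 <- geometry$electrode_spacing / 2
  aL <- geometry$active_length / 2
  m <- resolution$fine_margin
  fh <- resolution$fine_h; th <- resolution$tumor_h
  xa <- tc[1] - s2; xb <- tc[1] + s2

  wx <- data.frame(lo = c(xa - rn - m, xb - rn - m, tc[1] - rt),
                   hi = c(xa + rn + m, xb + rn + m, tc[1] + rt),
                   h = c(fh, fh, th))
  wy <- data.frame(lo = c(tc[2] - rn - m, tc[2] - rt),
                   hi = c(tc[2] + rn + m, tc[2] + rt),
                   h = c(fh, th))
  wz <- data.frame(lo = c(tc[3] - aL - m, tc[3] - rt),
                   hi = c(tc[3] + aL + m, tc[3] + rt),
                   h = c(fh, th))

  xe <- graded_axis(-R, R, wx, resolution$coarse_h, resolution$grade_ratio)
  ye <- graded_axis(-R, R, wy, resolution$coarse_h, resolution$grade_ratio)
  ze <- graded_axis(-H, H, wz, resolution$coarse_h, resolution$grade_ratio)
  xc <- (xe[-1] + xe[-length(xe)]) / 2
  yc <- (ye[-1] + ye[-length(ye)]) / 2
  zc <- (ze[-1] + ze[-length(ze)]) / 2
  nx <- length(xc); ny <- length(yc); nz <- length(zc)

  X <- array(xc, c(nx, ny, nz))
  Y <- array(rep(yc, each = nx), c(nx, ny, nz))
  Z <- array(rep(zc, each = nx * ny), c(nx, ny, nz))

  lab <- array(LABEL_LEVELS[["OUTSIDE"]], c(nx, ny, nz))
  in_liver <- (X^2 + Y^2 <= R^2) & (abs(Z) <= H)
  lab[in_liver] <- LABEL_LEVELS[["LIVER"]]
  in_tumor <- ((X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2) <= rt^2
  lab[in_tumor] <- LABEL_LEVELS[["TUMOR"]]
  # needle cylinders override tissue; active segment about the tumor equator
  for (side in c("A", "B")) {
    x0 <- if (side == "A") xa else xb
    in_shaft <- ((X - x0)^2 + (Y - tc[2])^2 <= rn^2) & (Z <= H) & in_liver
    act <- in_shaft & (Z >= tc[3] - aL) & (Z <= tc[3] + aL)
    ins <- in_shaft & (Z > tc[3] + aL)
    lab[act] <- LABEL_LEVELS[[paste0("ELECTRODE_", side)]]
    lab[ins] <- LABEL_LEVELS[["INSULATION"]]
  }

  structure(list(x_edges = xe, y_edges = ye, z_edges = ze,
                 xc = xc, yc = yc, zc = zc,
                 dx = diff(xe), dy = diff(ye), dz = diff(ze),
                 dim = c(nx, ny, nz), label = lab,
                 geometry = geometry, resolution = resolution,
                 cache = new.env(parent = emptyenv())),
            class = "voxel_grid")
}

#' Per-voxel volumes
#'
#' @param grid a [build_grid()] result.
#' @return array of voxel volumes (m^3) matching `grid$dim`.
#' @export
voxel_volumes <- function(grid) {
  if (!is.null(grid$cache$vol)) return(grid$cache$vol)
  v <- array(grid$dx, grid$dim) *
    array(rep(grid$dy, each = grid$dim[1]), grid$dim) *
    array(rep(grid$dz, each = grid$dim[1] * grid$dim[2]), grid$dim)
  grid$cache$vol <- v
  v
}

#' Voxel counts per material label
#'
#' @param grid a [build_grid()] result.
#' @return named integer vector over all labels.
#' @export
label_counts <- function(grid) {
  n <- vapply(LABEL_LEVELS, function(l) sum(grid$label == l), integer(1))
  names(n) <- names(LABEL_LEVELS)
  n
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d = %d voxels\n",
              x$dim[1], x$dim[2], x$dim[3], prod(x$dim)))
  print(label_counts(x))
  invisible(x)
}

# per-cell scalar from a named-by-label lookup (e.g. material property)
label_lookup <- function(grid, values) {
  out <- array(NA_real_, grid$dim)
  for (nm in names(LABEL_LEVELS)) {
    key <- if (nm %in% c("ELECTRODE_A", "ELECTRODE_B")) "ELECTRODE" else nm
    if (!is.null(values[[key]]))
      out[grid$label == LABEL_LEVELS[[nm]]] <- values[[key]]
  }
  out
}

material_field <- function(grid, materials, field) {
  vals <- lapply(materials, function(m) m[[field]])
  label_lookup(grid, vals)
}

#' Grid-convergence report for the single-burst pipeline
#'
#' Runs the full electric/bioheat pipeline at each resolution and reports
#' the peak tumor temperature at the end of the burst together with the
#' successive differences, as a practical check on the staircase
#' discretisation error of the voxel geometry.
#'
#' @param scenario a [scenario()].
#' @param resolutions list of at least two [grid_spec()] objects, ordered
#'   from coarse to fine.
#' @param mode burst integration mode passed to [simulate_burst()].
#' @return data.frame with one row per resolution: voxel count, peak tumor
#'   temperature at the end of the burst (degC) and the difference from
#'   the previous resolution.
#' @export
grid_convergence <- function(scenario, resolutions, mode = "averaged") {
  if (length(resolutions) < 2)
    fail("pulseheat_precondition_error",
         "grid_convergence needs at least two resolutions")
  rows <- lapply(resolutions, function(res) {
    grid <- build_grid(scenario$geometry, res)
    br <- simulate_burst(scenario, grid, mode = mode)
    data.frame(fine_h = res$fine_h, n_voxels = prod(grid$dim),
               t_max_100us = br$t_max_100us,
               tumor_peak_100us = br$tumor_peak_100us)
  })
  out <- do.call(rbind, rows)
  out$diff <- c(NA, diff(out$t_max_100us))
  out
}
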