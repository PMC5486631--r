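# Multi-parameter analysis: the (voltage, pulse width, repetition rate)
# lattice sweep, the closed-form temperature-law fit
# T = T0 + a * p_w * f * V^2 * N (p_w in ns, f in kHz, V in volts), the
# 44 degC safe-parameter contours and the 3-D threshold surface.

T_BASELINE <- 37

#' Run the pulse-parameter lattice sweep
#'
#' One [simulate_burst()] per lattice point, reusing a single grid (and
#' its cached assemblies) across points. Failed points are reported and
#' skipped, not fatal. When `cache_dir` is given, each point's result row
#' is cached on disk keyed by a hash of the scenario and parameters, so
#' re-running an unchanged sweep is a no-op.
#'
#' @param scn template [scenario()]; its protocol voltage/width/rate are
#'   replaced per lattice point.
#' @param voltages voltages (V).
#' @param widths pulse widths (ns).
#' @param rates repetition rates (kHz).
#' @param mode burst integration mode (sweeps default to `"averaged"`).
#' @param grid optional pre-built grid shared by all points.
#' @param cache_dir optional directory for per-point result caching.
#' @param quiet suppress per-point progress messages.
#' @return object of class `sweep_result`: a data.frame with one row per
#'   lattice point and columns `voltage`, `pulse_width`, `rep_rate`,
#'   `t_max_100us`, `t_max_1s`, `omega_max_1s`.
#' @export
run_sweep <- function(scn, voltages = c(1000, 2000, 3000, 4000),
                      widths = c(50, 100, 250, 500),
                      rates = c(100, 250, 500, 1000),
                      mode = "averaged", grid = NULL, cache_dir = NULL,
                      quiet = TRUE) {
  stopifnot(length(voltages) > 0, length(widths) > 0, length(rates) > 0)
  bad <- outer(widths, rates) * 1e-6 > 1 + 1e-12
  if (any(bad))
    fail("pulseheat_validation_error",
         "lattice contains (width, rate) pairs with duty cycle > 1")
  if (is.null(grid))
    grid <- build_grid(scn$geometry, grid_spec_from_solver(scn$solver))
  lattice <- expand.grid(voltage = voltages, pulse_width = widths,
                         rep_rate = rates, KEEP.OUT.ATTRS = FALSE)
  lattice <- lattice[order(lattice$voltage, lattice$pulse_width,
                           lattice$rep_rate), , drop = FALSE]
  failed <- character(0)
  rows <- vector("list", nrow(lattice))
  for (i in seq_len(nrow(lattice))) {
    v <- lattice$voltage[i]; pw <- lattice$pulse_width[i]
    f <- lattice$rep_rate[i]
    key <- if (!is.null(cache_dir))
      sweep_cache_key(scn, grid, v, pw, f, mode) else NULL
    cached <- sweep_cache_read(cache_dir, key)
    if (!is.null(cached)) {
      rows[[i]] <- cached
      next
    }
    scn_i <- scn
    scn_i$protocol <- pulse_protocol(v, pw, f,
                                     burst_length = scn$protocol$burst_length,
                                     burst_rate = scn$protocol$burst_rate,
                                     n_bursts = scn$protocol$n_bursts)
    row <- tryCatch({
      br <- simulate_burst(scn_i, grid, mode = mode)
      data.frame(voltage = v, pulse_width = pw, rep_rate = f,
                 t_max_100us = br$t_max_100us, t_max_1s = br$t_max_1s,
                 omega_max_1s = br$omega_max_1s)
    }, pulseheat_error = function(e) {
      failed <<- c(failed, sprintf("(%g V, %g ns, %g kHz): %s", v, pw, f,
                                   conditionMessage(e)))
      data.frame(voltage = v, pulse_width = pw, rep_rate = f,
                 t_max_100us = NA_real_, t_max_1s = NA_real_,
                 omega_max_1s = NA_real_)
    })
    if (!quiet)
      message(sprintf("sweep %d/%d: %g V, %g ns, %g kHz -> %.2f degC",
                      i, nrow(lattice), v, pw, f, row$t_max_100us))
    sweep_cache_write(cache_dir, key, row)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(failed))
    warning("sweep points failed: ", paste(failed, collapse = "; "))
  structure(out, failed = failed, mode = mode,
            class = c("sweep_result", "data.frame"))
}

sweep_cache_key <- function(scn, grid, v, pw, f, mode) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(scn = write_scenario(scn), dim = grid$dim,
               v = v, pw = pw, f = f, mode = mode), tf)
  unname(tools::md5sum(tf))
}

sweep_cache_read <- function(cache_dir, key) {
  if (is.null(cache_dir)) return(NULL)
  p <- file.path(cache_dir, paste0(key, ".csv"))
  if (file.exists(p)) utils::read.csv(p) else NULL
}

sweep_cache_write <- function(cache_dir, key, row) {
  if (is.null(cache_dir)) return(invisible())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(row, file.path(cache_dir, paste0(key, ".csv")),
                   row.names = FALSE)
  invisible()
}

#' Fit the closed-form temperature law to a sweep
#'
#' Least-squares slope of `(observable - 37)` against
#' `x = pulse_width * rep_rate * voltage^2` (ns, kHz, V) through the
#' origin: the response is linear in pulse width and frequency and
#' follows a square law in voltage, so a single coefficient captures the
#' lattice.
#'
#' @param sweep a [run_sweep()] result (or compatible data.frame).
#' @param observable `"t_max_100us"` (end-of-burst peak) or `"t_max_1s"`.
#' @return object of class `fit_result` with the slope `coefficient`
#'   (degC per ns kHz V^2), `r_squared` and the observable name. The
#'   intercept is fixed at 37 degC.
#' @export
fit_power_law <- function(sweep, observable = c("t_max_100us", "t_max_1s")) {
  observable <- match.arg(observable)
  x <- sweep$pulse_width * sweep$rep_rate * sweep$voltage^2
  y <- sweep[[observable]] - T_BASELINE
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2)
    fail("pulseheat_fit_error",
         "degenerate design: need at least two distinct pulse-energy values")
  a <- sum(x * y) / sum(x^2)
  r2 <- 1 - sum((y - a * x)^2) / sum(y^2)
  structure(list(coefficient = a, r_squared = r2, observable = observable,
                 n = length(x)), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s = 37 + %.4g * p_w * f * V^2 (R^2 = %.4f, n = %d)\n",
              x$observable, x$coefficient, x$r_squared, x$n))
  invisible(x)
}

#' Predict peak temperature from the fitted law
#'
#' `T = 37 + a * p_w * f * V^2 * N`. Multi-burst behaviour is the
#' analytic extrapolation linear in the burst count `N`; because each
#' burst in reality starts from a partially cooled state, the prediction
#' is an upper bound, valid while `N` is not too large.
#'
#' @param fit a [fit_power_law()] result, or a bare numeric coefficient.
#' @param pulse_width pulse width (ns).
#' @param rep_rate repetition rate (kHz).
#' @param voltage voltage (V).
#' @param n_bursts burst count N (>= 1).
#' @return predicted peak tumor temperature (degC).
#' @export
predict_temperature <- function(fit, pulse_width, rep_rate, voltage,
                                n_bursts = 1) {
  if (any(n_bursts < 1))
    fail("pulseheat_input_error", "n_bursts must be >= 1")
  a <- if (inherits(fit, "fit_result")) fit$coefficient else fit
  T_BASELINE + a * pulse_width * rep_rate * voltage^2 * n_bursts
}

# piecewise-linear crossing of y = limit along increasing x
interp_crossing <- function(x, y, limit) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (max(y) < limit) return(list(status = "unbounded", x = Inf))
  if (min(y) > limit) return(list(status = "exceeded", x = NA_real_))
  i <- which(y >= limit)[1]
  if (i == 1) return(list(status = "ok", x = x[1]))
  w <- (limit - y[i - 1]) / (y[i] - y[i - 1])
  list(status = "ok", x = x[i - 1] + w * (x[i] - x[i - 1]))
}

#' Safe-parameter boundary along one pulse-parameter axis
#'
#' For each combination of the two pinned parameters, interpolates the
#' sweep response to locate where the observable crosses `limit`
#' (44 degC by default). The response is linear in pulse width and
#' repetition rate and quadratic in voltage, so the interpolation runs in
#' the free parameter directly (or in V^2 when voltage is free), making
#' the crossing exact under those scaling laws. Points below the boundary
#' satisfy the limit. Combinations whose response never reaches the
#' limit inside the sweep range are reported as `"unbounded"` rather than
#' an error.
#'
#' @param sweep a [run_sweep()] result.
#' @param observable response column, default the end-of-burst peak.
#' @param limit temperature limit (degC).
#' @param free which parameter to solve for: `"rep_rate"`,
#'   `"pulse_width"` or `"voltage"`.
#' @param fixed optional named list pinning the other two parameters to
#'   subsets of their lattice values.
#' @return data.frame with the pinned values, the admissible boundary of
#'   the free parameter and a `status` column (`ok` / `unbounded` /
#'   `exceeded`).
#' @export
threshold_contour <- function(sweep, observable = "t_max_100us", limit = 44,
                              free = c("rep_rate", "pulse_width", "voltage"),
                              fixed = NULL) {
  free <- match.arg(free)
  pins <- setdiff(c("voltage", "pulse_width", "rep_rate"), free)
  combos <- unique(sweep[, pins, drop = FALSE])
  if (!is.null(fixed))
    for (p in names(fixed))
      combos <- combos[combos[[p]] %in% fixed[[p]], , drop = FALSE]
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- sweep[[pins[1]]] == combos[[pins[1]]][i] &
      sweep[[pins[2]]] == combos[[pins[2]]][i]
    rows <- sweep[sel & is.finite(sweep[[observable]]), , drop = FALSE]
    if (nrow(rows) < 2) return(NULL)
    xv <- rows[[free]]
    xi <- if (free == "voltage") xv^2 else xv
    cr <- interp_crossing(xi, rows[[observable]], limit)
    bound <- if (free == "voltage" && is.finite(cr$x)) sqrt(cr$x) else cr$x
    cbind(combos[i, , drop = FALSE],
          data.frame(boundary = bound, status = cr$status))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  names(out)[names(out) == "boundary"] <- paste0(free, "_max")
  out
}

# trilinear interpolation of the temperature rise on the (V^2, p_w, f)
# lattice; exact for responses of the form a * p_w * f * V^2
sweep_interpolant <- function(sweep, observable) {
  vs <- sort(unique(sweep$voltage))
  ws <- sort(unique(sweep$pulse_width))
  fs <- sort(unique(sweep$rep_rate))
  arr <- array(NA_real_, c(length(vs), length(ws), length(fs)))
  iv <- match(sweep$voltage, vs)
  iw <- match(sweep$pulse_width, ws)
  ifr <- match(sweep$rep_rate, fs)
  arr[cbind(iv, iw, ifr)] <- sweep[[observable]] - T_BASELINE
  lin1 <- function(grid_x, x) {
    i <- findInterval(x, grid_x, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1), length(grid_x) - 1)
    w <- (x - grid_x[i]) / (grid_x[i + 1] - grid_x[i])
    list(i = i, w = w)
  }
  function(v, pw, f) {
    a <- lin1(vs^2, v^2); b <- lin1(ws, pw); c_ <- lin1(fs, f)
    out <- 0
    for (da in 0:1) for (db in 0:1) for (dc in 0:1) {
      wt <- (if (da) a$w else 1 - a$w) * (if (db) b$w else 1 - b$w) *
        (if (dc) c_$w else 1 - c_$w)
      out <- out + wt * arr[cbind(a$i + da, b$i + db, c_$i + dc)]
    }
    out + T_BASELINE
  }
}

#' Threshold isosurface in (voltage, pulse width, frequency) space
#'
#' Evaluates the trilinearly interpolated sweep response (linear in pulse
#' width and frequency, quadratic in voltage via V^2) on a refined
#' (voltage, pulse width) grid and solves for the frequency at which it
#' crosses `limit`. The region between the surface and the origin
#' satisfies the limit. Returns the surface as vertices plus a triangle
#' index matrix.
#'
#' @param sweep a [run_sweep()] result covering all three axes.
#' @param observable response column.
#' @param limit temperature limit (degC).
#' @param n_grid refinement of the (voltage, pulse width) evaluation grid.
#' @return list with `vertices` (data.frame `voltage`, `pulse_width`,
#'   `rep_rate`), `triangles` (3-column index matrix) and `limit`; empty
#'   vertices when the response never reaches the limit.
#' @export
threshold_surface <- function(sweep, observable = "t_max_100us", limit = 44,
                              n_grid = 21) {
  if (length(unique(sweep$voltage)) < 2 ||
      length(unique(sweep$pulse_width)) < 2 ||
      length(unique(sweep$rep_rate)) < 2)
    fail("pulseheat_precondition_error",
         "threshold_surface needs a sweep over all three axes")
  resp <- sweep_interpolant(sweep, observable)
  vs <- seq(min(sweep$voltage), max(sweep$voltage), length.out = n_grid)
  ws <- seq(min(sweep$pulse_width), max(sweep$pulse_width),
            length.out = n_grid)
  fgrid <- sort(unique(sweep$rep_rate))
  vert_id <- matrix(NA_integer_, n_grid, n_grid)
  verts <- list()
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    y <- resp(rep(vs[i], length(fgrid)), rep(ws[j], length(fgrid)), fgrid)
    cr <- interp_crossing(fgrid, y, limit)
    if (cr$status == "ok") {
      verts[[length(verts) + 1]] <-
        data.frame(voltage = vs[i], pulse_width = ws[j], rep_rate = cr$x)
      vert_id[i, j] <- length(verts)
    }
  }
  vertices <- if (length(verts)) do.call(rbind, verts) else
    data.frame(voltage = numeric(0), pulse_width = numeric(0),
               rep_rate = numeric(0))
  tris <- list()
  for (i in seq_len(n_grid - 1)) for (j in seq_len(n_grid - 1)) {
    q <- c(vert_id[i, j], vert_id[i + 1, j], vert_id[i + 1, j + 1],
           vert_id[i, j + 1])
    if (!any(is.na(q))) {
      tris[[length(tris) + 1]] <- q[c(1, 2, 3)]
      tris[[length(tris) + 1]] <- q[c(1, 3, 4)]
    }
  }
  list(vertices = vertices,
       triangles = if (length(tris)) do.call(rbind, tris) else
         matrix(integer(0), 0, 3),
       limit = limit)
}
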