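# Shared finite-volume face machinery on the full grid box.  All solvers
# describe their 7-point stencil by three face-conductance arrays (gx, gy,
# gz: the +axis face of each cell, zero on boundary or inactive faces) with
# harmonic averaging of the cell coefficient across the two half-cells.

axis_arrays <- function(grid) {
  d <- grid$dim; nx <- d[1]; ny <- d[2]
  list(
    h = list(array(grid$dx / 2, d),
             array(rep(grid$dy / 2, each = nx), d),
             array(rep(grid$dz / 2, each = nx * ny), d)),
    area = list(array(rep(grid$dy, each = nx), d) *
                  array(rep(grid$dz, each = nx * ny), d),
                array(grid$dx, d) * array(rep(grid$dz, each = nx * ny), d),
                array(grid$dx, d) * array(rep(grid$dy, each = nx), d))
  )
}

shift_op <- function(d, axis) {
  # index lists selecting all-but-last / all-but-first slabs along axis
  sel <- function(drop_last) {
    idx <- list(TRUE, TRUE, TRUE)
    idx[[axis]] <- if (drop_last) seq_len(d[axis] - 1) else
      1 + seq_len(d[axis] - 1)
    idx
  }
  list(l = sel(TRUE), r = sel(FALSE))
}

slab_get <- function(x, idx) do.call(`[`, c(list(x), idx, list(drop = FALSE)))
slab_set <- function(x, idx, value) do.call(`[<-`, c(list(x), idx,
                                                     list(value)))

# face-conductance arrays for coefficient kappa (0 where kappa = 0 / NA)
face_conductances <- function(grid, kappa) {
  d <- grid$dim
  kap <- kappa
  kap[is.na(kap)] <- 0
  aa <- axis_arrays(grid)
  out <- list()
  for (ax in 1:3) {
    res <- aa$h[[ax]] / kap  # half-cell resistance (Inf where kappa = 0)
    s <- shift_op(d, ax)
    g <- array(0, d)
    num <- slab_get(aa$area[[ax]], s$l) /
      (slab_get(res, s$l) + slab_get(res, s$r))
    out[[ax]] <- slab_set(g, s$l, num)
  }
  names(out) <- c("gx", "gy", "gz")
  out
}

# sum of the (up to six) face conductances of every cell
face_rowsum <- function(d, fc) {
  gsum <- array(0, d)
  for (ax in 1:3) {
    s <- shift_op(d, ax)
    gface <- slab_get(fc[[ax]], s$l)
    gsum <- slab_set(gsum, s$l, slab_get(gsum, s$l) + gface)
    gsum <- slab_set(gsum, s$r, slab_get(gsum, s$r) + gface)
  }
  gsum
}
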