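# Shared small fixtures for fast tests.

tiny_slab <- function(voltage = 540, thickness = 0.0054, n_cells = 8, ...) {
  make_slab(thickness = thickness, voltage = voltage, n_cells = n_cells, ...)
}

# coarse needle-geometry grid for structural tests (fast to build and solve)
coarse_needle_grid <- function() {
  build_grid(tissue_geometry(),
             grid_spec(fine_h = 5e-4, tumor_h = 1.6e-3, coarse_h = 6e-3,
                       fine_margin = 6e-4))
}

# scenario tuned for fast whole-pipeline runs on the coarse grid
coarse_scenario <- function(voltage = 4000, pulse_width = 500,
                            rep_rate = 1000) {
  scn <- default_scenario(voltage, pulse_width, rep_rate)
  scn$solver$fine_h <- 5e-4
  scn$solver$tumor_h <- 1.6e-3
  scn$solver$coarse_h <- 6e-3
  scn$solver$fine_margin <- 6e-4
  scn
}
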