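# Shared small fixtures: a coarse slab model + solved field (built once per
# test run; a few seconds) and a compact neuron on it. Grids here are
# deliberately small — accuracy-critical checks build their own grids.

fx_env <- new.env()

fx_grid_small <- function()
  grid_spec(lateral_extent_um = 2000, z_top_um = 800, h_fine_um = 20,
            fine_radius_um = 300, ratio = 1.5, h_elec_um = 20,
            choroid_um = 200)

fx_site <- function(erd = 100, thickness = 200, fibrosis = 0)
  electrode_site("C5", erd_um = erd, thickness_um = thickness,
                 fibrosis_um = fibrosis)

fx_slab <- function() {
  if (is.null(fx_env$slab))
    fx_env$slab <- build_slab_geometry(fx_site(), grid = fx_grid_small())
  fx_env$slab
}

fx_field <- function() {
  if (is.null(fx_env$field)) fx_env$field <- solve_unit_field(fx_slab())
  fx_env$field
}

fx_neuron <- function(soma_xy = c(100, 50)) {
  traj <- axon_trajectory(soma_xy)
  build_morphology(soma_xy, traj, model = fx_slab())
}

fx_unit_potentials <- function(morph)
  fieldcable:::unit_potentials_for(morph, fx_field())

# independent convex-hull + shoelace oracle (Andrew's monotone chain)
oracle_hull_area_mm2 <- function(xy_um) {
  p <- unique(xy_um[order(xy_um[, 1], xy_um[, 2]), , drop = FALSE])
  n <- nrow(p)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(p[h[length(h) - 1], ], p[h[length(h)], ], p[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  hull <- c(build(seq_len(n)), build(rev(seq_len(n))))
  hull <- hull[!duplicated(hull)]
  v <- p[hull, , drop = FALSE] * 1e-3
  m <- nrow(v)
  abs(sum(v[, 1] * v[c(2:m, 1), 2] - v[c(2:m, 1), 1] * v[, 2])) / 2
}
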