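test_that("analytic disc oracle satisfies its closed-form identities", {
  v0 <- disc_electrode_analytic(100, 0.1, 1, 0, 0)
  expect_equal(v0, 1 / (4 * 0.1 * 100e-6))          # 25,000 V
  expect_equal(disc_electrode_analytic(100, 0.1, 1, 0, 100), v0 / 2)
  expect_equal(disc_electrode_analytic(100, 0.1, 1, 200, 0),
               (2 * v0 / pi) * asin(0.5))
  # doubling the injected current doubles the potential everywhere
  expect_equal(disc_electrode_analytic(100, 0.1, 2, 150, 80),
               2 * disc_electrode_analytic(100, 0.1, 1, 150, 80))
})

test_that("half-space solve approximates the analytic disc solution", {
  hs <- build_halfspace_model(a_um = 100, sigma = 0.1, extent_um = 4000,
                              depth_um = 3000, h_fine_um = 20,
                              fine_radius_um = 250, fine_depth_um = 250)
  f <- solve_unit_field(hs)
  v0 <- disc_electrode_analytic(100, 0.1, 1, 0, 0)
  expect_lt(abs(f$terminal_V - v0) / v0, 0.05)
  pts <- cbind(c(0, 150, 0), c(0, 0, 100), -c(100, 100, 200))
  num <- sample_potential(f, pts)
  ana <- disc_electrode_analytic(100, 0.1, 1, sqrt(pts[, 1]^2 + pts[, 2]^2),
                                 -pts[, 3])
  expect_true(all(abs(num - ana) / ana < 0.05))
  # discrete maximum principle: extremum at the source
  expect_lte(max(f$v, na.rm = TRUE), f$terminal_V + 1e-9)
  expect_gte(min(f$v, na.rm = TRUE), -1e-9)
})

test_that("current is conserved and the active electrode is equipotential", {
  f <- fx_field()
  expect_lt(abs(boundary_current(f) - 1), 0.01)
  tm <- fx_slab()
  vmetal <- f$v[tm$electrodes[[tm$active]]]
  expect_equal(max(vmetal) - min(vmetal), 0)
  expect_equal(max(vmetal), f$terminal_V)
  expect_lte(max(f$v, na.rm = TRUE), f$terminal_V + 1e-9)
})

test_that("floating electrodes are equipotential; disabling them changes V", {
  tm <- fx_slab()
  f <- fx_field()
  others <- setdiff(names(tm$electrodes), tm$active)
  others <- others[vapply(others, function(l)
    length(tm$electrodes[[l]]) > 0, logical(1))]
  expect_gt(length(others), 0)
  for (l in others) {
    v <- f$v[tm$electrodes[[l]]]
    expect_equal(max(v) - min(v), 0)
  }
  f2 <- solve_unit_field(tm, config = solver_config(floating = FALSE))
  expect_false(isTRUE(all.equal(f2$terminal_V, f$terminal_V,
                                tolerance = 1e-10)))
  expect_lt(abs(boundary_current(f2) - 1), 0.01)
})

test_that("an effectively transparent membrane converges to no membrane", {
  g <- fx_grid_small()
  site <- fx_site()
  tm_open <- build_slab_geometry(site, grid = g, membrane = FALSE)
  tm_hi <- build_slab_geometry(site, grid = g)
  tm_hi$membrane$sigma <- 1e4   # sheet resistance -> 0
  f_open <- solve_unit_field(tm_open)
  f_hi <- solve_unit_field(tm_hi)
  expect_lt(abs(f_hi$terminal_V - f_open$terminal_V) / f_open$terminal_V,
            0.005)
  # and the standard membrane raises the electrode potential
  f_mem <- fx_field()
  expect_gt(f_mem$terminal_V, f_open$terminal_V)
})

test_that("sampling is trilinear: exact at nodes, linear in between", {
  f <- fx_field()
  i <- c(10L, 20L); j <- c(15L, 9L); k <- c(5L, 12L)
  pts <- cbind(f$xc[i], f$yc[j], f$zc[k])
  expect_equal(sample_potential(f, pts), f$v[cbind(i, j, k)])
  # synthetic exactly linear field is reproduced anywhere
  lin <- f
  lin$v <- array(outer(outer(2 * lin$xc, 3 * lin$yc, "+"), 5 * lin$zc, "+"),
                 dim = dim(f$v))
  p <- cbind(runif(20, -500, 500), runif(20, -500, 500), runif(20, -150, 150))
  expect_equal(sample_potential(lin, p),
               2 * p[, 1] + 3 * p[, 2] + 5 * p[, 3], tolerance = 1e-10)
  expect_error(sample_potential(f, cbind(1e6, 0, 0)), "outside")
})

test_that("sampled potentials are stable under grid refinement", {
  site <- fx_site()
  coarse <- fx_field()
  fine <- solve_unit_field(build_slab_geometry(
    site, grid = grid_spec(lateral_extent_um = 2000, z_top_um = 800,
                           h_fine_um = 12.5, fine_radius_um = 300,
                           ratio = 1.5, h_elec_um = 12.5,
                           choroid_um = 200)))
  pts <- cbind(c(0, 100, 200, -150), c(0, 50, -100, 0),
               c(-15, -15, -55, -100))
  vc <- sample_potential(coarse, pts)
  vf <- sample_potential(fine, pts)
  expect_true(all(abs(vc - vf) / abs(vf) < 0.05))
})

test_that("potential fields round-trip bit-exactly through the container", {
  f <- fx_field()
  path <- tempfile(fileext = ".rds")
  write_potential_field(f, path)
  expect_identical(read_potential_field(path), f)
  saveRDS(1:3, path)
  expect_error(read_potential_field(path), "not a potential_field")
})

test_that("unknown electrodes and non-convergence are reported", {
  tm <- fx_slab()
  expect_error(solve_unit_field(tm, electrode_label = "Z9"), "Z9")
  expect_error(solve_unit_field(tm, config = solver_config(maxit = 3)),
               "converge")
})
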