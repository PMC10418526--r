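test_that("Lloyd placement stays in the disc and is reproducible", {
  pop <- place_somas_lloyd(n = 250, radius_um = 700, seed = 2,
                           iterations = 12)
  expect_equal(nrow(pop$xy), 250)
  expect_true(all(sqrt(rowSums(pop$xy^2)) <= 700 + 1e-9))
  expect_identical(pop$xy,
                   place_somas_lloyd(n = 250, radius_um = 700, seed = 2,
                                     iterations = 12)$xy)
  expect_equal(anyDuplicated(pop$xy), 0)
  # Lloyd energy is non-increasing
  expect_true(all(diff(pop$energy) <= 1e-9))
  expect_error(place_somas_lloyd(n = 0, seed = 1), ">= 1")
  expect_error(place_somas_lloyd(n = 5, seed = 1, iterations = -1),
               "iterations")
})

test_that("a single soma relaxes to the disc centroid", {
  pop <- place_somas_lloyd(n = 1, radius_um = 700, seed = 9,
                           iterations = 2, tol_um = 0)
  expect_lt(sqrt(sum(pop$xy^2)), 5)
})

test_that("relaxation spreads points out and approaches area-uniformity", {
  dmin <- function(xy) min(dist(xy))
  gain <- vapply(1:20, function(s) {
    init <- place_somas_lloyd(n = 40, radius_um = 700, seed = s,
                              iterations = 0)
    rel <- place_somas_lloyd(n = 40, radius_um = 700, seed = s,
                             iterations = 12)
    dmin(rel$xy) - dmin(init$xy)
  }, numeric(1))
  expect_gt(median(gain), 0)

  pop <- place_somas_lloyd(n = 250, radius_um = 700, seed = 4,
                           iterations = 30)
  # any concentric sub-disc holds about its area fraction of somas
  for (r in c(350, 495, 600)) {
    frac <- mean(sqrt(rowSums(pop$xy^2)) <= r)
    expect_lt(abs(frac - (r / 700)^2), 0.1)
  }
})

test_that("fiber trajectories obey the bundle-model geometry", {
  pars <- trajectory_params()
  # straight-line degenerate form
  tr0 <- axon_trajectory(c(200, 100), trajectory_params(b_scale = 0))
  chord <- sqrt(sum((tr0$xy[1, ] - tr0$xy[nrow(tr0$xy), ])^2))
  expect_equal(tr0$arc_length_um, chord, tolerance = 1e-6)
  # arc length >= straight-line distance, steps bounded, ends at the margin
  for (soma in list(c(0, 50), c(-300, -200), c(400, 300))) {
    tr <- axon_trajectory(soma, pars)
    expect_equal(unname(tr$xy[1, ]), soma, tolerance = 1e-6)
    eucl <- sqrt(sum((soma - tr$xy[nrow(tr$xy), ])^2))
    expect_gte(tr$arc_length_um + 1e-9, eucl)
    expect_lte(max(sqrt(rowSums(diff(tr$xy)^2))), pars$step_um + 1e-6)
    r_end <- sqrt(sum((tr$xy[nrow(tr$xy), ] - pars$onh_xy_um)^2))
    expect_equal(r_end, pars$r0_deg * pars$um_per_deg, tolerance = 1)
  }
  # temporal macular fibers are near-straight
  tr <- axon_trajectory(c(0, 50), pars)
  a <- tr$xy[1, ]; b <- tr$xy[nrow(tr$xy), ]
  u <- (b - a) / sqrt(sum((b - a)^2))
  dev <- apply(tr$xy, 1, function(p) {
    w <- p - a
    abs(w[1] * u[2] - w[2] * u[1])
  })
  expect_lt(max(dev), 300)  # < ~4 degrees of bend over a ~4 mm course
  # superior somas keep superior courses (no raphe crossing)
  trs <- axon_trajectory(c(-200, 80), pars)
  rel <- sweep(trs$xy, 2, pars$onh_xy_um)
  expect_error(axon_trajectory(pars$onh_xy_um + c(100, 0), pars),
               "optic nerve head")
})

test_that("morphologies follow the paper's depth paradigm", {
  tm <- fx_slab()
  m <- fx_neuron(c(100, 50))
  comp <- m$compartments
  expect_true(m$buildable)
  expect_equal(comp$z_um[comp$section == "soma"], -55)
  expect_true(all(comp$z_um[comp$section == "distal_axon"] == -15))
  expect_true(all(comp$z_um[comp$section == "dendrite"] == -55))
  expect_true(all(comp$z_um > -200 & comp$z_um < 0))
  # section ordering along the chain
  expect_equal(unique(comp$section),
               c("dendrite", "soma", "axon_hillock", "sodium_band",
                 "narrow_segment", "distal_axon"))
  # compartments contiguous: adjacent centers about half-length apart
  gaps <- sqrt(rowSums(diff(as.matrix(comp[, c("x_um", "y_um", "z_um")]))^2))
  halfsum <- (comp$L_um[-nrow(comp)] + comp$L_um[-1]) / 2
  expect_true(all(gaps <= halfsum * 1.3 + 1e-6))
  # axon length matches the trajectory arc (here capped by the plan)
  plan <- section_plan()
  ax <- sum(comp$L_um[comp$section == "distal_axon"])
  expect_lte(ax, plan$axon_max_L_um + plan$axon_comp_um)
})

test_that("thin retina makes the morphology unbuildable", {
  thinmap <- function(x, y) ifelse(x > 0, 40, 200)
  tm <- build_slab_geometry(fx_site(), grid = fx_grid_small(),
                            thickness_fun = thinmap)
  traj <- axon_trajectory(c(150, 0))
  m <- build_morphology(c(150, 0), traj, model = tm)
  expect_false(m$buildable)
  expect_match(m$reason, "thinner")
  m2 <- build_morphology(c(-150, 0), axon_trajectory(c(-150, 0)), model = tm)
  expect_true(m2$buildable)
})

test_that("morphology exports to CSV and SWC-like text", {
  m <- fx_neuron()
  csv <- tempfile(fileext = ".csv")
  write_morphology(m, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(m$compartments))
  swc <- tempfile(fileext = ".swc")
  write_morphology(m, swc, format = "swc")
  tr <- read.table(swc)
  expect_equal(ncol(tr), 7)
  expect_equal(tr[1, 7], -1)  # root has no parent
})
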