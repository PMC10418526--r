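#' Uniform soma placement by Lloyd's algorithm
#'
#' Distributes `n` retinal ganglion cell somas quasi-uniformly within a disc
#' beneath the electrode. Random initial points are relaxed by Lloyd
#' iterations of a discrete centroidal Voronoi tessellation: a fixed dense
#' quasi-uniform sample of the disc is repeatedly partitioned by nearest
#' center and the centers moved to their partition centroids. The Lloyd
#' energy (mean squared distance of the sample to its nearest center) is
#' non-increasing across iterations.
#'
#' @param center x-y of the disc center, micrometers (default electrode
#'   center at the origin).
#' @param radius_um placement radius (default 700).
#' @param n number of somas (default 250).
#' @param iterations maximum Lloyd iterations (default 30); iteration also
#'   stops once the mean centroid displacement falls below `tol_um`.
#' @param seed integer seed; placement is reproducible per seed.
#' @param tol_um mean-displacement stopping tolerance (default 1 um).
#' @return list of class `soma_population`: `xy` (n x 2 matrix, micrometers),
#'   `center`, `radius_um`, `seed`, and the per-iteration `energy` trace.
#' @examples
#' pop <- place_somas_lloyd(n = 50, seed = 7, iterations = 10)
#' max(sqrt(rowSums(pop$xy^2)))  # <= 700
#' @export
place_somas_lloyd <- function(center = c(0, 0), radius_um = 700, n = 250L,
                              iterations = 30L, seed = 1L, tol_um = 1) {
  if (n < 1) stop("n must be >= 1")
  if (radius_um <= 0) stop("radius must be positive")
  if (iterations < 0) stop("iterations must be >= 0")

  # fixed quasi-uniform sample of the unit disc (deterministic grid)
  ns <- 81L
  gx <- seq(-1 + 1 / ns, 1 - 1 / ns, length.out = ns)
  smp <- as.matrix(expand.grid(x = gx, y = gx))
  smp <- smp[rowSums(smp^2) <= 1, , drop = FALSE]

  pts <- with_seed(seed, {
    r <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  })

  energy <- numeric(0)
  for (it in seq_len(iterations)) {
    # nearest-center assignment: ||s - p||^2 = |s|^2 - 2 s.p + |p|^2
    cross <- smp %*% t(pts)
    d2 <- outer(rowSums(smp^2), rowSums(pts^2), "+") - 2 * cross
    nearest <- max.col(-d2, ties.method = "first")
    energy <- c(energy, mean(d2[cbind(seq_len(nrow(smp)), nearest)]))
    newx <- vapply(seq_len(n), function(k) {
      sel <- nearest == k
      if (any(sel)) mean(smp[sel, 1]) else pts[k, 1]
    }, numeric(1))
    newy <- vapply(seq_len(n), function(k) {
      sel <- nearest == k
      if (any(sel)) mean(smp[sel, 2]) else pts[k, 2]
    }, numeric(1))
    moved <- mean(sqrt((newx - pts[, 1])^2 + (newy - pts[, 2])^2))
    pts <- cbind(newx, newy)
    if (moved * radius_um < tol_um) break
  }
  xy <- sweep(pts * radius_um, 2, center, "+")
  dimnames(xy) <- list(NULL, c("x_um", "y_um"))
  structure(list(xy = xy, center = center, radius_um = radius_um,
                 n = n, seed = seed, energy = energy * radius_um^2),
            class = "soma_population")
}

#' @export
print.soma_population <- function(x, ...) {
  cat(sprintf("<soma_population> %d somas within %g um of (%g, %g)\n",
              x$n, x$radius_um, x$center[1], x$center[2]))
  invisible(x)
}

#' Nerve-fiber trajectory parameters
#'
#' Parametric retinal nerve fiber bundle model in modified polar coordinates
#' about the optic nerve head (ONH): a fiber entering the disc margin at
#' angle `phi0` (degrees; 0 = nasal horizontal, +90 = superior, +/-180 =
#' temporal horizontal/raphe) follows
#' `phi(r) = phi0 + b(phi0) * (r - r0)^c(phi0)` for `r >= r0`, with
#' region-dependent `b`, `c`:
#' superior `b = exp(-1.9 + 3.9 tanh(-(phi0 - 121)/14))`,
#' `c = 1.9 + 1.4 tanh((phi0 - 121)/14)`; inferior
#' `b = -exp(0.7 + 1.5 tanh(-(-phi0 - 90)/25))`,
#' `c = 1.0 + 0.5 tanh((-phi0 - 90)/25)`; `r0 = 4` degrees.
#' Temporal (macular) fibers are therefore nearly straight while nasal
#' fibers arc strongly.
#'
#' @param onh_xy_um ONH center in retinal-plane micrometers relative to the
#'   array center (default 4 mm nasal, 0.6 mm superior).
#' @param r0_deg disc margin radius in degrees.
#' @param um_per_deg retinal distance per degree of visual angle.
#' @param step_um maximum polyline step along the trajectory.
#' @param b_scale multiply the curvature coefficient `b` (0 gives radial
#'   straight-line fibers, useful for validation).
#' @return list of class `trajectory_params`.
#' @export
trajectory_params <- function(onh_xy_um = c(4000, 600), r0_deg = 4,
                              um_per_deg = 288, step_um = 20, b_scale = 1) {
  structure(list(onh_xy_um = onh_xy_um, r0_deg = r0_deg,
                 um_per_deg = um_per_deg, step_um = step_um,
                 b_scale = b_scale), class = "trajectory_params")
}

jansonius_bc <- function(phi0) {
  if (phi0 >= 0) {
    b <- exp(-1.9 + 3.9 * tanh(-(phi0 - 121) / 14))
    cc <- 1.9 + 1.4 * tanh((phi0 - 121) / 14)
  } else {
    b <- -exp(0.7 + 1.5 * tanh(-(-phi0 - 90) / 25))
    cc <- 1.0 + 0.5 * tanh((-phi0 - 90) / 25)
  }
  c(b = b, c = cc)
}

#' Axon trajectory from a soma to the optic nerve head
#'
#' Solves the fiber-bundle equation of [trajectory_params()] for the disc
#' entry angle `phi0` passing through the soma, then samples the arc from
#' the soma to the ONH disc margin as a polyline with steps no larger than
#' `params$step_um`. Somas exactly on the horizontal raphe are assigned to
#' the superior hemifield (deterministic tie-break). The polyline is
#' arc-length monotone toward the ONH and never crosses the raphe.
#'
#' @param soma_xy x-y of the soma, micrometers (array-centered frame).
#' @param params a [trajectory_params()].
#' @return list of class `axon_trajectory`: `xy` polyline (micrometers,
#'   starting at the soma), `phi0_deg`, `arc_length_um`.
#' @export
axon_trajectory <- function(soma_xy, params = trajectory_params()) {
  # ONH-centered frame, degrees; x axis points nasally (away from the array)
  rel <- (soma_xy - params$onh_xy_um) / params$um_per_deg
  # nasal direction = from array center towards ONH
  u <- params$onh_xy_um / sqrt(sum(params$onh_xy_um^2))
  rot <- rbind(c(u[1], u[2]), c(-u[2], u[1]))  # maps u -> +x
  p <- as.numeric(rot %*% rel)
  r_s <- sqrt(sum(p^2))
  phi_s <- atan2(p[2], p[1]) * 180 / pi
  if (r_s <= params$r0_deg)
    stop("soma lies inside the optic nerve head disc")
  superior <- phi_s >= 0  # raphe tie-break: superior branch

  bc_of <- function(phi0) {
    bc <- jansonius_bc(phi0)
    bc["b"] <- bc["b"] * params$b_scale
    bc
  }
  g <- function(phi0) {
    bc <- bc_of(phi0)
    phi0 + bc["b"] * (r_s - params$r0_deg)^bc["c"] - phi_s
  }
  solve_phi0 <- function(lo, hi) {
    glo <- g(lo); ghi <- g(hi)
    if (sign(glo) != sign(ghi))
      return(stats::uniroot(g, c(lo, hi), tol = 1e-9)$root)
    # no sign change (possible at the nasal-horizontal seam of the model):
    # take the best-fitting entry angle on a fine grid
    cand <- seq(lo, hi, length.out = 721)
    cand[which.min(abs(vapply(cand, g, numeric(1))))]
  }
  if (params$b_scale == 0) {
    phi0 <- phi_s
  } else if (superior) {
    phi0 <- solve_phi0(1e-6, min(max(phi_s, 1e-6), 180 - 1e-6))
  } else {
    phi0 <- solve_phi0(max(min(phi_s, -1e-6), -180 + 1e-6), -1e-6)
  }
  bc <- bc_of(phi0)

  # sample r from soma to disc margin; refine until steps <= step_um
  nstep <- max(8L, ceiling((r_s - params$r0_deg) * params$um_per_deg /
                             (0.7 * params$step_um)))
  repeat {
    r <- seq(r_s, params$r0_deg, length.out = nstep + 1)
    phi <- phi0 + bc["b"] * (r - params$r0_deg)^bc["c"]
    xy_onh <- cbind(r * cos(phi * pi / 180), r * sin(phi * pi / 180))
    seglen <- sqrt(rowSums(diff(xy_onh)^2)) * params$um_per_deg
    if (max(seglen) <= params$step_um || nstep > 1e5) break
    nstep <- ceiling(nstep * max(seglen) / params$step_um * 1.05)
  }
  # back to the array frame
  xy <- t(t(rot) %*% t(xy_onh)) * params$um_per_deg +
    matrix(params$onh_xy_um, nrow(xy_onh), 2, byrow = TRUE)
  dimnames(xy) <- list(NULL, c("x_um", "y_um"))
  structure(list(xy = xy, phi0_deg = phi0,
                 arc_length_um = sum(seglen), params = params),
            class = "axon_trajectory")
}

#' Compartment section plan for the RGC morphology
#'
#' Lengths, diameters and compartment counts for each section of the
#' unbranched model cell (an equivalent dendrite, soma, axon hillock,
#' high-sodium initial-segment band, narrow segment, distal axon), in the
#' style of published multicompartment mammalian RGC models. All exposed for
#' sensitivity analyses.
#'
#' @param dendrite_L_um,dendrite_diam_um,dendrite_n equivalent dendrite.
#' @param soma_diam_um soma diameter (single compartment).
#' @param hillock_L_um,hillock_diam_um,hillock_n axon hillock.
#' @param socb_L_um,socb_diam_um,socb_n sodium-channel band.
#' @param narrow_L_um,narrow_diam_um,narrow_n narrow segment.
#' @param axon_diam_um,axon_comp_um,axon_max_L_um distal axon (follows the
#'   fiber trajectory; compartments of `axon_comp_um`, truncated at
#'   `axon_max_L_um` or the ONH, whichever comes first).
#' @param soma_depth_um,axon_depth_um depths below the retinal surface.
#' @return list of class `section_plan`.
#' @export
section_plan <- function(dendrite_L_um = 500, dendrite_diam_um = 3,
                         dendrite_n = 8L,
                         soma_diam_um = 20,
                         hillock_L_um = 40, hillock_diam_um = 2,
                         hillock_n = 4L,
                         socb_L_um = 60, socb_diam_um = 1.5, socb_n = 6L,
                         narrow_L_um = 90, narrow_diam_um = 0.5,
                         narrow_n = 6L,
                         axon_diam_um = 1.0, axon_comp_um = 25,
                         axon_max_L_um = 2000,
                         soma_depth_um = 55, axon_depth_um = 15) {
  structure(as.list(environment()), class = "section_plan")
}

# walk a polyline, returning points at given arc-length stations
polyline_at <- function(xy, s_target) {
  seg <- sqrt(rowSums(diff(xy)^2))
  cs <- c(0, cumsum(seg))
  s_target <- pmin(s_target, cs[length(cs)])
  i <- pmin(findInterval(s_target, cs), length(seg))
  w <- (s_target - cs[i]) / seg[i]
  xy[i, , drop = FALSE] * (1 - w) + xy[i + 1, , drop = FALSE] * w
}

#' Build a 3-D multicompartment RGC morphology
#'
#' Chains an equivalent dendrite, the soma, the axon hillock, the
#' sodium-channel band, the narrow segment and the distal axon into an
#' ordered compartment table. The soma sits `soma_depth_um` (default 55)
#' below the retinal surface, the distal axon runs `axon_depth_um`
#' (default 15) below the surface along the fiber trajectory, and the
#' hillock/band/narrow sections ramp linearly between the two depths. The
#' dendrite extends horizontally at soma depth away from the axon direction.
#'
#' @param soma_xy x-y of the soma, micrometers.
#' @param trajectory an [axon_trajectory()] starting at the soma.
#' @param model optional `tissue_model`; when given, the local retinal
#'   thickness at the soma is checked and the morphology flagged
#'   unbuildable where the retina is thinner than the soma depth.
#' @param plan a [section_plan()].
#' @return A `neuron_morphology`: data frame with `section`, `x_um`, `y_um`,
#'   `z_um`, `L_um`, `diam_um` plus attributes; `$buildable` is `FALSE`
#'   (with an empty table) where the retina cannot host the soma.
#' @export
build_morphology <- function(soma_xy, trajectory, model = NULL,
                             plan = section_plan()) {
  thick_here <- if (!is.null(model))
    local_retinal_thickness(model, soma_xy[1], soma_xy[2]) else Inf
  if (thick_here < plan$soma_depth_um) {
    return(structure(list(compartments = NULL, buildable = FALSE,
                          soma_xy = soma_xy,
                          reason = "retina thinner than soma depth"),
                     class = "neuron_morphology"))
  }
  zs <- -plan$soma_depth_um
  za <- -plan$axon_depth_um
  traj <- trajectory$xy
  dir0 <- traj[2, ] - traj[1, ]
  dir0 <- dir0 / sqrt(sum(dir0^2))

  rows <- list()
  add <- function(section, xyz, L, diam)
    rows[[length(rows) + 1]] <<- data.frame(
      section = section, x_um = xyz[1], y_um = xyz[2], z_um = xyz[3],
      L_um = L, diam_um = diam, stringsAsFactors = FALSE)

  # dendrite: horizontal at soma depth, opposite the axon direction
  dL <- plan$dendrite_L_um / plan$dendrite_n
  for (i in rev(seq_len(plan$dendrite_n))) {
    p <- soma_xy - dir0 * (plan$soma_diam_um / 2 + (i - 0.5) * dL)
    add("dendrite", c(p, zs), dL, plan$dendrite_diam_um)
  }
  add("soma", c(soma_xy, zs), plan$soma_diam_um, plan$soma_diam_um)

  # initial sections ramp from soma depth to axon depth along the trajectory
  ramp_L <- plan$hillock_L_um + plan$socb_L_um + plan$narrow_L_um
  s0 <- plan$soma_diam_um / 2
  ramp_z <- function(s) zs + (za - zs) * pmin(1, pmax(0, (s - s0) / ramp_L))
  sections <- list(
    c("axon_hillock", plan$hillock_L_um, plan$hillock_n, plan$hillock_diam_um),
    c("sodium_band", plan$socb_L_um, plan$socb_n, plan$socb_diam_um),
    c("narrow_segment", plan$narrow_L_um, plan$narrow_n, plan$narrow_diam_um))
  s <- s0
  for (sec in sections) {
    L <- as.numeric(sec[2]); nseg <- as.integer(sec[3])
    diam <- as.numeric(sec[4])
    cl <- L / nseg
    for (i in seq_len(nseg)) {
      mid <- s + (i - 0.5) * cl
      p <- polyline_at(traj, mid)
      add(sec[1], c(p, ramp_z(mid)), cl, diam)
    }
    s <- s + L
  }
  # distal axon along the trajectory at axon depth
  total_s <- min(trajectory$arc_length_um, s + plan$axon_max_L_um)
  n_ax <- max(1L, floor((total_s - s) / plan$axon_comp_um))
  for (i in seq_len(n_ax)) {
    mid <- s + (i - 0.5) * plan$axon_comp_um
    p <- polyline_at(traj, mid)
    add("distal_axon", c(p, za), plan$axon_comp_um, plan$axon_diam_um)
  }
  comp <- do.call(rbind, rows)
  rownames(comp) <- NULL
  structure(list(compartments = comp, buildable = TRUE, soma_xy = soma_xy,
                 plan = plan), class = "neuron_morphology")
}

#' @export
print.neuron_morphology <- function(x, ...) {
  if (!x$buildable) {
    cat("<neuron_morphology> unbuildable:", x$reason, "\n")
  } else {
    cat(sprintf("<neuron_morphology> %d compartments (%s)\n",
                nrow(x$compartments),
                paste(unique(x$compartments$section), collapse = " > ")))
  }
  invisible(x)
}

#' Export a morphology as a compartment CSV or SWC-like tree text
#'
#' @param morph a `neuron_morphology`.
#' @param path output file.
#' @param format `"csv"` (compartment table) or `"swc"` (7-column tree text
#'   for visualization).
#' @export
write_morphology <- function(morph, path, format = c("csv", "swc")) {
  format <- match.arg(format)
  if (!morph$buildable) stop("morphology is unbuildable")
  comp <- morph$compartments
  if (format == "csv") {
    write.csv(comp, path, row.names = FALSE, quote = FALSE)
  } else {
    type_of <- c(dendrite = 3L, soma = 1L, axon_hillock = 2L,
                 sodium_band = 2L, narrow_segment = 2L, distal_axon = 2L)
    n <- nrow(comp)
    swc <- data.frame(id = seq_len(n), type = type_of[comp$section],
                      x = comp$x_um, y = comp$y_um, z = comp$z_um,
                      r = comp$diam_um / 2,
                      parent = c(-1L, seq_len(n - 1)))
    utils::write.table(swc, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
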