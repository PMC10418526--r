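#' Tissue conductivities
#'
#' Bulk conductivity (S/m) assigned to each segmented domain, with the
#' retinal value overridable for sensitivity analyses.
#'
#' @param retina,vitreous,choroid,fibrosis,platinum conductivities in S/m.
#' @return named list of class `conductivity_set`.
#' @export
conductivity_defaults <- function(retina = 0.100, vitreous = 1.5,
                                  choroid = 0.503, fibrosis = 0.15,
                                  platinum = 9.43e6) {
  vals <- list(retina = retina, vitreous = vitreous, choroid = choroid,
               fibrosis = fibrosis, platinum = platinum)
  if (any(unlist(vals) <= 0)) stop("conductivities must be strictly positive")
  structure(vals, class = "conductivity_set")
}

#' Voxel grid parameters for slab tissue models
#'
#' The grid is rectilinear and nonuniform: uniform fine spacing within
#' `fine_radius_um` of the active electrode (and through the retina, the
#' electrode-retina gap and the electrode plane), coarsening geometrically
#' outward. Lateral extent defaults to a desk-scale 4 x 4 mm with 2 mm of
#' vitreous above the array; edge effects are negligible beyond ~10 electrode
#' radii, and the full-scale clinical extents (25 x 17 mm laterally, 18 mm of
#' vitreous) remain available by argument.
#'
#' @param lateral_extent_um total lateral extent (square), micrometers.
#' @param z_top_um height of the vitreous column above the retinal surface.
#' @param h_fine_um fine grid spacing near the electrode (<= 25 um).
#' @param fine_radius_um lateral half-width of the fine region.
#' @param ratio geometric coarsening ratio (> 1).
#' @param h_elec_um thickness of the electrode/substrate voxel layer.
#' @param choroid_um choroid layer thickness beneath the retina.
#' @param fine_margin_um how far the fine axial spacing extends into the
#'   choroid below the pigment-epithelium membrane.
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(lateral_extent_um = 4000, z_top_um = 2000,
                      h_fine_um = 15, fine_radius_um = 500, ratio = 1.4,
                      h_elec_um = 15, choroid_um = 300,
                      fine_margin_um = 60) {
  if (h_fine_um > 25)
    stop("fine grid spacing must be <= 25 um near the electrode plane")
  stopifnot(lateral_extent_um > 2 * fine_radius_um, z_top_um > 0, ratio > 1)
  structure(list(lateral_extent_um = lateral_extent_um, z_top_um = z_top_um,
                 h_fine_um = h_fine_um, fine_radius_um = fine_radius_um,
                 ratio = ratio, h_elec_um = h_elec_um,
                 choroid_um = choroid_um, fine_margin_um = fine_margin_um),
            class = "grid_spec")
}

# uniform subdivision of [a, b] into >= nmin cells of width <= h
axis_uniform <- function(a, b, h, nmin = 1L) {
  n <- max(nmin, ceiling((b - a) / h - 1e-9))
  seq(a, b, length.out = n + 1)
}

# geometrically graded edges from `from` towards `to`, starting width h0
axis_graded <- function(from, to, h0, ratio) {
  span <- abs(to - from)
  if (span < h0 * 1e-9) return(numeric(0))
  w <- h0
  widths <- c()
  total <- 0
  while (total < span) {
    widths <- c(widths, w)
    total <- total + w
    w <- w * ratio
  }
  widths <- widths * (span / total)  # land exactly on `to`
  from + sign(to - from) * cumsum(widths)
}

# symmetric lateral axis: fine around 0, graded to +/- extent/2
axis_lateral <- function(grid) {
  half <- grid$lateral_extent_um / 2
  rf <- grid$fine_radius_um
  fine <- axis_uniform(-rf, rf, grid$h_fine_um)
  right <- axis_graded(rf, half, grid$h_fine_um * grid$ratio, grid$ratio)
  sort(unique(c(-right, fine, right)))
}

labels_code <- c(vitreous = 1L, fibrosis = 2L, retina = 3L, choroid = 4L,
                 electrode_metal = 5L, substrate = 6L)

#' Build a parametric slab tissue model for one electrode site
#'
#' Constructs the voxelized stand-in for the segmented-and-meshed clinical
#' geometry: a layered slab with (bottom to top) choroid, a thin resistive
#' retinal-pigment-epithelium membrane at the retina/choroid interface,
#' retina, the vitreous gap, optional fibrotic tissue directly beneath the
#' electrode, and the electrode array plane (platinum discs in an insulating
#' substrate) at height `erd_um` above the retinal inner surface, with
#' vitreous above. z = 0 is the retinal inner surface and +z points into the
#' vitreous. The outer face of the choroid (bottom boundary) is the
#' electrical ground.
#'
#' @param site an [electrode_site()] (or a list with the same fields).
#' @param array an [electrode_array_spec()].
#' @param grid a [grid_spec()].
#' @param conduct a [conductivity_defaults()] set.
#' @param thickness_fun optional `function(x_um, y_um)` giving a laterally
#'   varying retinal thickness (defaults to the uniform `site$thickness_um`);
#'   the retinal inner surface stays flat at z = 0 and the degeneration is
#'   taken up at the outer boundary.
#' @param membrane `TRUE` to include the 10 um, 0.001 S/m
#'   pigment-epithelium membrane as a contact-impedance interface condition.
#' @param fibrosis_radius_um lateral radius of the fibrotic slab beneath the
#'   electrode (default: the electrode footprint radius).
#' @return A `tissue_model`: grid axes, per-voxel domain labels and
#'   conductivities, electrode metal voxel sets, and membrane parameters.
#' @examples
#' site <- electrode_site("A1", erd_um = 100, thickness_um = 200)
#' tm <- build_slab_geometry(site, grid = grid_spec(lateral_extent_um = 2000,
#'                                                  z_top_um = 1000))
#' local_retinal_thickness(tm, 0, 0)
#' @export
build_slab_geometry <- function(site, array = electrode_array_spec(),
                                grid = grid_spec(),
                                conduct = conductivity_defaults(),
                                thickness_fun = NULL,
                                membrane = TRUE,
                                fibrosis_radius_um = NULL) {
  if (!inherits(site, "electrode_site"))
    site <- do.call(electrode_site, site[c("label", "erd_um", "thickness_um",
                                           "fibrosis_um")])
  erd <- site$erd_um
  fib <- site$fibrosis_um
  thick <- site$thickness_um
  if (erd < fib) stop("erd_um < fibrosis_um")
  if (thick < grid$h_fine_um)
    stop("retinal thickness smaller than one voxel")

  x <- axis_lateral(grid)
  y <- x

  thick_at <- if (is.null(thickness_fun)) {
    function(x, y) rep(thick, length(x))
  } else thickness_fun
  xc0 <- (x[-1] + x[-length(x)]) / 2
  yc0 <- xc0
  thick_mat <- outer(xc0, yc0, function(a, b) thick_at(a, b))
  if (any(thick_mat <= 0)) stop("thickness_fun must be positive everywhere")
  thick_max <- max(thick_mat, thick)

  hz <- grid$h_fine_um
  gap <- erd - fib
  z_bot <- -(thick_max + grid$choroid_um)
  z_fine_lo <- -(thick_max + grid$fine_margin_um)
  segs <- list(rev(axis_graded(z_fine_lo, z_bot, hz * grid$ratio, grid$ratio)),
               axis_uniform(z_fine_lo, 0, hz))
  if (gap > 0) segs <- c(segs, list(axis_uniform(0, gap, hz, nmin = 2L)))
  if (fib > 0) segs <- c(segs, list(axis_uniform(gap, erd, hz, nmin = 2L)))
  segs <- c(segs, list(c(erd, erd + grid$h_elec_um)),
            list(axis_graded(erd + grid$h_elec_um, erd + grid$z_top_um,
                             hz * grid$ratio, grid$ratio)))
  z <- sort(unique(c(z_bot, unlist(segs))))

  nx <- length(x) - 1L; ny <- length(y) - 1L; nz <- length(z) - 1L
  xc <- (x[-1] + x[-length(x)]) / 2
  yc <- (y[-1] + y[-length(y)]) / 2
  zc <- (z[-1] + z[-length(z)]) / 2

  lab <- array(labels_code[["vitreous"]], dim = c(nx, ny, nz))
  # below the surface: retina above the local outer boundary, else choroid
  below <- which(zc < 0)
  for (k in below) {
    ret <- zc[k] > -thick_mat           # nx x ny logical
    lab[, , k] <- ifelse(ret, labels_code[["retina"]],
                         labels_code[["choroid"]])
  }
  # fibrotic slab beneath the electrode footprint
  r_e <- array$electrode_diameter_um / 2
  r_fib <- if (is.null(fibrosis_radius_um)) r_e else fibrosis_radius_um
  r2c <- outer(xc^2, yc^2, "+")
  if (fib > 0) {
    kf <- which(zc > gap & zc < erd)
    infib <- r2c <= r_fib^2
    for (k in kf)
      lab[, , k][infib] <- labels_code[["fibrosis"]]
  }
  # electrode plane: metal discs in an insulating substrate
  off <- array_offsets(array, site$label)
  ke <- which(zc > erd & zc < erd + grid$h_elec_um)
  half <- grid$lateral_extent_um / 2
  keep <- abs(off$x_um) < half & abs(off$y_um) < half
  off <- off[keep, , drop = FALSE]
  sub_pad <- array$pitch_um / 2
  in_sub <- outer(xc >= min(off$x_um) - sub_pad & xc <= max(off$x_um) + sub_pad,
                  yc >= min(off$y_um) - sub_pad & yc <= max(off$y_um) + sub_pad,
                  "&")
  electrodes <- vector("list", nrow(off))
  names(electrodes) <- off$label
  for (k in ke) {
    plane <- ifelse(in_sub, labels_code[["substrate"]],
                    labels_code[["vitreous"]])
    lab[, , k] <- plane
  }
  for (e in seq_len(nrow(off))) {
    d2 <- outer((xc - off$x_um[e])^2, (yc - off$y_um[e])^2, "+")
    inmetal <- which(d2 <= r_e^2, arr.ind = TRUE)
    if (nrow(inmetal) == 0) next
    cells <- integer(0)
    for (k in ke) {
      lin <- inmetal[, 1] + (inmetal[, 2] - 1L) * nx + (k - 1L) * nx * ny
      lab[lin] <- labels_code[["electrode_metal"]]
      cells <- c(cells, lin)
    }
    electrodes[[e]] <- cells
  }
  if (length(electrodes[[site$label]]) == 0)
    stop("active electrode footprint not resolved by the grid")

  sigma_of <- c(conduct$vitreous, conduct$fibrosis, conduct$retina,
                conduct$choroid, conduct$platinum, 0)
  sig <- array(sigma_of[lab], dim = dim(lab))

  structure(list(
    x = x, y = y, z = z, xc = xc, yc = yc, zc = zc,
    dx = diff(x), dy = diff(y), dz = diff(z),
    label = lab, sigma = sig,
    electrodes = electrodes, active = site$label,
    membrane = list(enabled = isTRUE(membrane), thickness_um = 10,
                    sigma = 0.001),
    site = site, array = array, grid = grid, conduct = conduct,
    thick_mat = thick_mat, top_disc = NULL
  ), class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("<tissue_model> %d x %d x %d voxels, active electrode %s\n",
              d[1], d[2], d[3], x$active))
  cat(sprintf("  erd %g um, retina %g um, fibrosis %g um; membrane %s\n",
              x$site$erd_um, x$site$thickness_um, x$site$fibrosis_um,
              if (x$membrane$enabled) "on" else "off"))
  invisible(x)
}

#' Local retinal thickness from the voxel model
#'
#' Returns the z-extent of retina-labeled voxels in the column containing
#' `(x_um, y_um)` — the distance from the inner to the outer retinal
#' boundary as resolved by the grid.
#'
#' @param model a `tissue_model`.
#' @param x_um,y_um lateral position, micrometers.
#' @return thickness in micrometers.
#' @export
local_retinal_thickness <- function(model, x_um, y_um) {
  n <- max(length(x_um), length(y_um))
  x_um <- rep_len(x_um, n); y_um <- rep_len(y_um, n)
  ix <- findInterval(x_um, model$x, rightmost.closed = TRUE)
  iy <- findInterval(y_um, model$y, rightmost.closed = TRUE)
  if (any(ix < 1 | ix > length(model$xc) | iy < 1 | iy > length(model$yc)))
    stop("position outside the lateral extent of the model")
  vapply(seq_len(n), function(i) {
    col <- model$label[ix[i], iy[i], ]
    sum(model$dz[col == labels_code[["retina"]]])
  }, numeric(1))
}

#' Homogeneous half-space validation model
#'
#' A uniform-conductivity medium occupying z < 0 with an equipotential disc
#' electrode of radius `a_um` centered at the origin of the insulating plane
#' z = 0, grounded at the remote bottom boundary. Used to validate the field
#' solver against the closed-form disc-electrode solution
#' ([disc_electrode_analytic()]).
#'
#' @param a_um disc radius, micrometers.
#' @param sigma medium conductivity, S/m.
#' @param extent_um lateral extent (square, centered).
#' @param depth_um domain depth below the plane.
#' @param h_fine_um fine spacing near the disc.
#' @param fine_radius_um lateral half-width of the fine region.
#' @param fine_depth_um depth of the fine axial region.
#' @param ratio geometric coarsening ratio.
#' @param far_field `"analytic"` prescribes the closed-form solution on the
#'   remote (bottom and lateral) boundaries, emulating the semi-infinite
#'   medium so that the comparison isolates discretization error;
#'   `"ground"` uses the slab convention (bottom grounded, laterals
#'   insulating).
#' @return a `tissue_model` whose solved field can be compared to the
#'   analytic oracle.
#' @export
build_halfspace_model <- function(a_um = 100, sigma = 0.1, extent_um = 8000,
                                  depth_um = 6000, h_fine_um = 12.5,
                                  fine_radius_um = 300, fine_depth_um = 300,
                                  ratio = 1.4,
                                  far_field = c("analytic", "ground")) {
  far_field <- match.arg(far_field)
  g <- grid_spec(lateral_extent_um = extent_um, z_top_um = 100,
                 h_fine_um = h_fine_um, fine_radius_um = fine_radius_um,
                 ratio = ratio)
  x <- axis_lateral(g)
  z <- sort(unique(c(
    rev(axis_graded(-fine_depth_um, -depth_um, h_fine_um * ratio, ratio)),
    axis_uniform(-fine_depth_um, 0, h_fine_um))))
  nx <- length(x) - 1L; nz <- length(z) - 1L
  lab <- array(labels_code[["vitreous"]], dim = c(nx, nx, nz))
  structure(list(
    x = x, y = x, z = z,
    xc = (x[-1] + x[-length(x)]) / 2, yc = (x[-1] + x[-length(x)]) / 2,
    zc = (z[-1] + z[-length(z)]) / 2,
    dx = diff(x), dy = diff(x), dz = diff(z),
    label = lab,
    sigma = array(sigma, dim = dim(lab)),
    electrodes = list(), active = "disc",
    membrane = list(enabled = FALSE, thickness_um = 10, sigma = 0.001),
    site = NULL, array = NULL, grid = g,
    conduct = conductivity_defaults(retina = sigma, vitreous = sigma,
                                    choroid = sigma, fibrosis = sigma),
    thick_mat = NULL,
    top_disc = list(a_um = a_um),
    # semi-infinite medium emulation: prescribe the analytic far-field on
    # the remote boundaries so the comparison isolates discretization error
    dirichlet_fun = if (far_field == "analytic")
      function(x, y, z)
        disc_electrode_analytic(a_um, sigma, 1, sqrt(x^2 + y^2), pmax(0, -z))
      else NULL
  ), class = "tissue_model")
}
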