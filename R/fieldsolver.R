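#' Field solver configuration
#'
#' @param tol relative residual tolerance for the conjugate-gradient solve.
#' @param maxit maximum CG iterations.
#' @param floating treat inactive electrode discs as floating conductors
#'   (equipotential, zero net current). If `FALSE` they are meshed as plain
#'   platinum voxels.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(tol = 1e-8, maxit = 50000L, floating = TRUE) {
  stopifnot(tol > 0, maxit >= 1)
  structure(list(tol = tol, maxit = as.integer(maxit),
                 floating = isTRUE(floating)), class = "solver_config")
}

# face conductances for one direction; returns triplet (cell1, cell2, G[S])
face_conductances <- function(model, dir) {
  d <- dim(model$label)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  um <- 1e-6
  if (dir == 1L) {
    i1 <- seq_len(nx - 1)
    sl1 <- model$sigma[i1, , , drop = FALSE]
    sl2 <- model$sigma[i1 + 1, , , drop = FALSE]
    h1 <- array(rep(model$dx[i1], times = ny * nz), dim = c(nx - 1, ny, nz))
    h2 <- array(rep(model$dx[i1 + 1], times = ny * nz),
                dim = c(nx - 1, ny, nz))
    area <- outer(rep(1, nx - 1), outer(model$dy, model$dz)) * um^2
    idx <- which(array(TRUE, dim = c(nx - 1, ny, nz)))
    ai <- arrayInd(idx, c(nx - 1, ny, nz))
    c1 <- ai[, 1] + (ai[, 2] - 1) * nx + (ai[, 3] - 1) * nx * ny
    c2 <- c1 + 1L
    mem <- 0
  } else if (dir == 2L) {
    j1 <- seq_len(ny - 1)
    sl1 <- model$sigma[, j1, , drop = FALSE]
    sl2 <- model$sigma[, j1 + 1, , drop = FALSE]
    h1 <- aperm(array(rep(model$dy[j1], times = nx * nz),
                      dim = c(ny - 1, nx, nz)), c(2, 1, 3))
    h2 <- aperm(array(rep(model$dy[j1 + 1], times = nx * nz),
                      dim = c(ny - 1, nx, nz)), c(2, 1, 3))
    area <- aperm(outer(rep(1, ny - 1), outer(model$dx, model$dz)),
                  c(2, 1, 3)) * um^2
    ai <- arrayInd(seq_len((ny - 1) * nx * nz), c(nx, ny - 1, nz))
    c1 <- ai[, 1] + (ai[, 2] - 1) * nx + (ai[, 3] - 1) * nx * ny
    c2 <- c1 + nx
    mem <- 0
  } else {
    k1 <- seq_len(nz - 1)
    sl1 <- model$sigma[, , k1, drop = FALSE]
    sl2 <- model$sigma[, , k1 + 1, drop = FALSE]
    h1 <- array(rep(model$dz[k1], each = nx * ny), dim = c(nx, ny, nz - 1))
    h2 <- array(rep(model$dz[k1 + 1], each = nx * ny),
                dim = c(nx, ny, nz - 1))
    area <- array(outer(model$dx, model$dy), dim = c(nx, ny, nz - 1)) * um^2
    ai <- arrayInd(seq_len(nx * ny * (nz - 1)), c(nx, ny, nz - 1))
    c1 <- ai[, 1] + (ai[, 2] - 1) * nx + (ai[, 3] - 1) * nx * ny
    c2 <- c1 + nx * ny
    # thin pigment-epithelium membrane at retina/choroid faces:
    # series sheet resistance t_m / sigma_m per unit area
    l1 <- model$label[, , k1, drop = FALSE]
    l2 <- model$label[, , k1 + 1, drop = FALSE]
    mem <- 0
    if (model$membrane$enabled) {
      rc <- labels_code[c("retina", "choroid")]
      at_mem <- (l1 == rc[1] & l2 == rc[2]) | (l1 == rc[2] & l2 == rc[1])
      mem <- as.numeric(at_mem) *
        (model$membrane$thickness_um * um / model$membrane$sigma)
    }
  }
  ok <- sl1 > 0 & sl2 > 0
  res <- (h1 * um) / (2 * sl1) + (h2 * um) / (2 * sl2) + mem  # ohm * m^2
  G <- ifelse(ok, area / res, 0)
  keep <- which(G > 0)
  list(c1 = c1[keep], c2 = c2[keep], G = as.numeric(G)[keep])
}

#' Solve the quasi-static volume-conduction problem for unit current
#'
#' Finite-volume discretization of `div(sigma grad V) = 0` with
#' harmonic-mean face conductivities on the model grid. The active electrode
#' is an equipotential current terminal injecting 1 A (solutions scale
#' linearly with current); inactive electrodes are floating conductors
#' (equipotential, zero net current); the bottom boundary (outer choroid
#' face) is ground (0 V); all other outer boundaries and the array substrate
#' are no-flux; the pigment-epithelium membrane enters as a thin resistive
#' interface. The symmetric positive-definite system is solved by
#' Jacobi-preconditioned conjugate gradients.
#'
#' @param model a `tissue_model`.
#' @param electrode_label the active electrode (defaults to the site label
#'   the model was built for).
#' @param config a [solver_config()].
#' @return A `potential_field`: cell-center axes (micrometers), the 3-D array
#'   of potentials in volts per injected ampere (`NA` in insulating
#'   substrate voxels), and metadata including the terminal potential, the
#'   current collected at the ground boundary, solver residual and iteration
#'   count.
#' @export
solve_unit_field <- function(model, electrode_label = model$active,
                             config = solver_config()) {
  d <- dim(model$label)
  ncell <- prod(d)
  is_active_disc <- !is.null(model$top_disc)
  if (!is_active_disc && is.null(model$electrodes[[electrode_label]]))
    stop("no such electrode in the model: ", electrode_label)

  # unknown numbering: conducting cells, with electrode metal merged
  map <- integer(ncell)
  conducting <- which(model$sigma > 0)
  elec_cells <- unlist(model$electrodes, use.names = FALSE)
  plain <- setdiff(conducting, elec_cells)
  map[plain] <- seq_along(plain)
  nun <- length(plain)
  term <- NA_integer_
  if (is_active_disc) {
    nun <- nun + 1L
    term <- nun
  } else {
    for (lb in names(model$electrodes)) {
      cells <- model$electrodes[[lb]]
      if (length(cells) == 0) next
      if (lb == electrode_label) {
        nun <- nun + 1L
        map[cells] <- nun
        term <- nun
      } else if (config$floating) {
        nun <- nun + 1L
        map[cells] <- nun
      } else {
        map[cells] <- nun + seq_along(cells)
        nun <- nun + length(cells)
      }
    }
  }

  fx <- face_conductances(model, 1L)
  fy <- face_conductances(model, 2L)
  fz <- face_conductances(model, 3L)
  c1 <- c(fx$c1, fy$c1, fz$c1)
  c2 <- c(fx$c2, fy$c2, fz$c2)
  G <- c(fx$G, fy$G, fz$G)
  u1 <- map[c1]; u2 <- map[c2]
  keep <- u1 > 0 & u2 > 0
  u1 <- u1[keep]; u2 <- u2[keep]; G <- G[keep]

  # Dirichlet ground on the bottom boundary (half-cell conductance); with a
  # far-field boundary function, prescribed values on bottom and laterals
  nx <- d[1]; ny <- d[2]; nzc <- d[3]
  fn <- model$dirichlet_fun
  bot <- seq_len(nx * ny)
  sigb <- as.vector(model$sigma[, , 1])
  areab <- as.vector(outer(model$dx, model$dy)) * 1e-12
  dir_cells <- bot
  dir_G <- ifelse(sigb > 0, areab * sigb / (model$dz[1] * 1e-6 / 2), 0)
  dir_V <- if (is.null(fn)) numeric(nx * ny) else
    as.vector(outer(model$xc, model$yc,
                    function(a, b) fn(a, b, model$z[1])))
  if (!is.null(fn)) {
    # lateral faces carry the prescribed far-field values too
    kz <- seq_len(nzc)
    for (side in list(list(ix = 1L, edge = model$x[1], ax = "x"),
                      list(ix = nx, edge = model$x[nx + 1], ax = "x"),
                      list(ix = 1L, edge = model$y[1], ax = "y"),
                      list(ix = ny, edge = model$y[ny + 1], ax = "y"))) {
      if (side$ax == "x") {
        cells <- side$ix + (rep(seq_len(ny), times = nzc) - 1L) * nx +
          (rep(kz, each = ny) - 1L) * nx * ny
        sig <- as.vector(model$sigma[side$ix, , ])
        area <- as.vector(outer(model$dy, model$dz)) * 1e-12
        h <- model$dx[side$ix]
        vv <- as.vector(outer(model$yc, model$zc,
                              function(a, b) fn(side$edge, a, b)))
      } else {
        cells <- rep(seq_len(nx), times = nzc) + (side$ix - 1L) * nx +
          (rep(kz, each = nx) - 1L) * nx * ny
        sig <- as.vector(model$sigma[, side$ix, ])
        area <- as.vector(outer(model$dx, model$dz)) * 1e-12
        h <- model$dy[side$ix]
        vv <- as.vector(outer(model$xc, model$zc,
                              function(a, b) fn(side$edge, a, b)))
      }
      dir_cells <- c(dir_cells, cells)
      dir_G <- c(dir_G, ifelse(sig > 0, area * sig / (h * 1e-6 / 2), 0))
      dir_V <- c(dir_V, vv)
    }
  }
  ud <- map[dir_cells]
  dkeep <- ud > 0 & dir_G > 0
  ub <- map[bot]
  Gb <- dir_G[seq_len(nx * ny)]
  bkeep <- ub > 0 & Gb > 0

  ti <- c(u1, u2, u1, u2, ud[dkeep])
  tj <- c(u2, u1, u1, u2, ud[dkeep])
  tx <- c(-G, -G, G, G, dir_G[dkeep])

  # top-boundary disc terminal (half-space validation model)
  if (is_active_disc) {
    nz <- d[3]
    topk <- nz
    r2 <- outer(model$xc^2, model$yc^2, "+")
    in_disc <- which(r2 <= model$top_disc$a_um^2)
    tcells <- in_disc + (topk - 1L) * nx * ny
    Gt <- (outer(model$dx, model$dy)[in_disc] * 1e-12) *
      as.vector(model$sigma[, , topk])[in_disc] /
      (model$dz[topk] * 1e-6 / 2)
    ut <- map[tcells]
    stopifnot(all(ut > 0))
    ti <- c(ti, ut, rep(term, length(ut)), ut, rep(term, length(ut)))
    tj <- c(tj, rep(term, length(ut)), ut, ut, rep(term, length(ut)))
    tx <- c(tx, -Gt, -Gt, Gt, Gt)
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nun, nun))
  b <- numeric(nun)
  b[term] <- 1.0
  if (any(dkeep & dir_V != 0)) {
    sel <- which(dkeep & dir_V != 0)
    for (s in sel) b[ud[s]] <- b[ud[s]] + dir_G[s] * dir_V[s]
  }

  sol <- pcg_solve(A@p, A@i, A@x, b, config$tol, config$maxit)
  if (sol$relres >= config$tol)
    stop(sprintf(
      "field solve did not converge: relative residual %.3g after %d iterations",
      sol$relres, sol$iter))

  v <- rep(NA_real_, ncell)
  v[map > 0] <- sol$x[map[map > 0]]
  varr <- array(v, dim = d)
  # net current leaving through all Dirichlet (ground / far-field) faces
  ground_current <- sum(dir_G[dkeep] * (sol$x[ud[dkeep]] - dir_V[dkeep]))

  structure(list(
    xc = model$xc, yc = model$yc, zc = model$zc,
    v = varr, active = electrode_label, injected_A = 1,
    terminal_V = sol$x[term],
    meta = list(relres = sol$relres, iter = sol$iter,
                ground_current_A = ground_current,
                conduct = model$conduct, dims = d,
                membrane = model$membrane)
  ), class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf(
    "<potential_field> electrode %s: terminal %.4g V/A, ground current %.4f A\n",
    x$active, x$terminal_V, x$meta$ground_current_A))
  cat(sprintf("  grid %s, CG residual %.2g in %d iterations\n",
              paste(x$meta$dims, collapse = " x "), x$meta$relres,
              x$meta$iter))
  invisible(x)
}

#' Net current collected at the ground boundary
#'
#' For a conservative finite-volume solution this equals the injected
#' current to solver precision; the discrete conservation check used
#' throughout the test-suite.
#'
#' @param field a `potential_field`.
#' @return current in amperes.
#' @export
boundary_current <- function(field) field$meta$ground_current_A

#' Analytic disc-electrode potential in a homogeneous half-space
#'
#' Closed-form potential of an equipotential disc of radius `a` on the
#' insulating boundary plane of a semi-infinite homogeneous medium carrying
#' total current `I` (Newman's access-resistance geometry):
#' `V(r, z) = (2 V0 / pi) * asin(2a / (sqrt((r-a)^2 + z^2) +
#' sqrt((r+a)^2 + z^2)))` with `V0 = I / (4 sigma a)`. On the axis this
#' reduces to `(2 V0 / pi) * atan(a / z)` and `V(0, 0) = V0`.
#'
#' @param a_um disc radius, micrometers.
#' @param sigma conductivity, S/m.
#' @param I_A total injected current, amperes.
#' @param r_um,z_um cylindrical coordinates of the evaluation points
#'   (micrometers; `z_um >= 0` is depth into the medium).
#' @return potential in volts (vectorized over `r_um`, `z_um`).
#' @export
disc_electrode_analytic <- function(a_um, sigma, I_A, r_um, z_um) {
  stopifnot(a_um > 0, sigma > 0, all(z_um >= 0))
  a <- a_um * 1e-6; r <- r_um * 1e-6; z <- z_um * 1e-6
  v0 <- I_A / (4 * sigma * a)
  arg <- 2 * a / (sqrt((r - a)^2 + z^2) + sqrt((r + a)^2 + z^2))
  (2 * v0 / pi) * asin(pmin(1, arg))
}

#' Sample a potential field at arbitrary points
#'
#' Trilinear interpolation on the cell-center lattice; exact at cell
#' centers. Points outside the lattice, or touching insulating substrate
#' voxels, raise an error naming the offending point.
#'
#' @param field a `potential_field`.
#' @param points numeric matrix (n x 3) of x, y, z positions in micrometers.
#' @return potentials in volts per injected ampere.
#' @export
sample_potential <- function(field, points) {
  points <- matrix(points, ncol = 3)
  gx <- field$xc; gy <- field$yc; gz <- field$zc
  for (j in 1:3) {
    g <- list(gx, gy, gz)[[j]]
    bad <- points[, j] < g[1] | points[, j] > g[length(g)]
    if (any(bad))
      stop(sprintf("point (%g, %g, %g) um is outside the sampled grid",
                   points[which(bad)[1], 1], points[which(bad)[1], 2],
                   points[which(bad)[1], 3]))
  }
  ix <- pmin(pmax(findInterval(points[, 1], gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(points[, 2], gy), 1L), length(gy) - 1L)
  iz <- pmin(pmax(findInterval(points[, 3], gz), 1L), length(gz) - 1L)
  wx <- (points[, 1] - gx[ix]) / (gx[ix + 1] - gx[ix])
  wy <- (points[, 2] - gy[iy]) / (gy[iy + 1] - gy[iy])
  wz <- (points[, 3] - gz[iz]) / (gz[iz + 1] - gz[iz])
  d <- dim(field$v)
  lin <- function(i, j, k) field$v[cbind(i, j, k)]
  out <-
    lin(ix, iy, iz) * (1 - wx) * (1 - wy) * (1 - wz) +
    lin(ix + 1, iy, iz) * wx * (1 - wy) * (1 - wz) +
    lin(ix, iy + 1, iz) * (1 - wx) * wy * (1 - wz) +
    lin(ix + 1, iy + 1, iz) * wx * wy * (1 - wz) +
    lin(ix, iy, iz + 1) * (1 - wx) * (1 - wy) * wz +
    lin(ix + 1, iy, iz + 1) * wx * (1 - wy) * wz +
    lin(ix, iy + 1, iz + 1) * (1 - wx) * wy * wz +
    lin(ix + 1, iy + 1, iz + 1) * wx * wy * wz
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop(sprintf("point (%g, %g, %g) um touches an insulating region",
                 points[i, 1], points[i, 2], points[i, 3]))
  }
  out
}

#' Persist / restore a potential field
#'
#' Round-trips the axes, value array and metadata bit-exactly through a
#' single-file container.
#'
#' @param field a `potential_field`.
#' @param path file path.
#' @export
write_potential_field <- function(field, path) {
  saveRDS(field, path, compress = FALSE)
  invisible(path)
}

#' @rdname write_potential_field
#' @export
read_potential_field <- function(path) {
  f <- readRDS(path)
  if (!inherits(f, "potential_field")) stop("not a potential_field file")
  f
}
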