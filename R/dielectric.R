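#' Gaussian density of a single atom
#'
#' Each atom is represented by an atom-centred Gaussian density
#' `exp(-d^2 / (sigma^2 R^2))` rather than a hard sphere, where `d` is the
#' distance to the atom centre, `R` its van der Waals radius and `sigma` the
#' relative variance. The density is 1 at the centre and decays smoothly;
#' there is no sharp molecular boundary.
#'
#' @param p A 3-vector or n x 3 matrix of evaluation points (Angstrom).
#' @param atom A one-row data frame (a row of `s$atoms`) with `x`, `y`, `z`,
#'   `radius`.
#' @param sigma Relative variance of the Gaussian (default 0.93).
#' @return Density value(s) in `[0, 1]`.
#' @export
atom_density <- function(p, atom, sigma = 0.93) {
  stopifnot(sigma > 0, atom$radius > 0)
  if (!is.matrix(p)) p <- matrix(p, ncol = 3)
  d2 <- (p[, 1] - atom$x)^2 + (p[, 2] - atom$y)^2 + (p[, 3] - atom$z)^2
  exp(-d2 / (sigma^2 * atom$radius^2))
}

#' Cumulative Gaussian solute density
#'
#' Combines the individual atom densities into the solute density
#' `g(r) = 1 - prod_i (1 - g_i(r))`, which is 1 wherever any atom density is
#' 1 and tends to 0 in bulk solvent. Adding atoms can only increase it.
#'
#' @param p A 3-vector or n x 3 matrix of evaluation points.
#' @param s A `"pqr"` structure.
#' @param sigma Relative variance (default 0.93).
#' @return Cumulative density value(s) in `[0, 1]`.
#' @export
cumulative_density <- function(p, s, sigma = 0.93) {
  stopifnot(inherits(s, "pqr"))
  if (!is.matrix(p)) p <- matrix(p, ncol = 3)
  acc <- rep(1, nrow(p))
  for (i in seq_len(nrow(s$atoms)))
    acc <- acc * (1 - atom_density(p, s$atoms[i, ], sigma))
  1 - acc
}

# cumulative density on the tensor grid xs x ys x zs, exploiting that each
# atom Gaussian factorises into per-axis 1-D Gaussians
density_on_axes <- function(xs, ys, zs, atoms, sigma) {
  acc <- array(1, dim = c(length(xs), length(ys), length(zs)))
  for (i in seq_len(nrow(atoms))) {
    w2 <- (sigma * atoms$radius[i])^2
    gx <- exp(-(xs - atoms$x[i])^2 / w2)
    gy <- exp(-(ys - atoms$y[i])^2 / w2)
    gz <- exp(-(zs - atoms$z[i])^2 / w2)
    acc <- acc * (1 - outer(outer(gx, gy), gz))
  }
  1 - acc
}

#' Smooth Gaussian dielectric field on the grid
#'
#' Maps the cumulative solute density to a permittivity by the convex blend
#' `eps(r) = g(r) * eps_in + (1 - g(r)) * eps_w`, evaluated at the midpoints
#' of grid edges (where the flux-conservative finite-difference stencil needs
#' permittivity values) and, for reuse, at the nodes themselves.
#'
#' @param g A `"grid_spec"`.
#' @param s A `"pqr"` structure.
#' @param eps_in Internal reference dielectric constant (default 2).
#' @param eps_w Water reference dielectric constant (default 80).
#' @param sigma Gaussian relative variance (default 0.93).
#' @return An object of class `"dielectric_field"`: list with `grid`,
#'   `eps_x`, `eps_y`, `eps_z` (edge-midpoint permittivities; `eps_x` has dim
#'   `c(n-1, n, n)` etc.), `g_node` (node-centred density, dim `n^3`),
#'   `eps_in`, `eps_w`, `sigma`.
#' @export
dielectric_field <- function(g, s, eps_in = 2, eps_w = 80, sigma = 0.93) {
  stopifnot(inherits(g, "grid_spec"), inherits(s, "pqr"),
            sigma > 0, eps_in >= 1, eps_w >= eps_in)
  atoms <- s$atoms
  nodes <- lapply(1:3, function(a) axis_coords(g, a))
  mids  <- lapply(nodes, function(v) (v[-1] + v[-length(v)]) / 2)
  blend <- function(dens) dens * eps_in + (1 - dens) * eps_w
  structure(list(
    grid  = g,
    eps_x = blend(density_on_axes(mids[[1]], nodes[[2]], nodes[[3]], atoms, sigma)),
    eps_y = blend(density_on_axes(nodes[[1]], mids[[2]], nodes[[3]], atoms, sigma)),
    eps_z = blend(density_on_axes(nodes[[1]], nodes[[2]], mids[[3]], atoms, sigma)),
    g_node = density_on_axes(nodes[[1]], nodes[[2]], nodes[[3]], atoms, sigma),
    eps_in = eps_in, eps_w = eps_w, sigma = sigma
  ), class = "dielectric_field")
}

#' @export
print.dielectric_field <- function(x, ...) {
  cat(sprintf("Gaussian dielectric field on %d^3 grid (sigma = %g)\n",
              x$grid$n, x$sigma))
  rng <- range(c(range(x$eps_x), range(x$eps_y), range(x$eps_z)))
  cat(sprintf("  eps_in %g, eps_w %g; midpoint eps range [%.4f, %.4f]\n",
              x$eps_in, x$eps_w, rng[1], rng[2]))
  invisible(x)
}

#' Node-averaged local dielectric
#'
#' The local permittivity at a grid node is the arithmetic mean of the six
#' edge-midpoint values adjacent to it (the two midpoints along each axis).
#'
#' @param eps A `"dielectric_field"`.
#' @param node Integer 3-vector of 0-based node indices, or an m x 3 matrix.
#' @return Averaged permittivity value(s).
#' @export
averaged_local_dielectric <- function(eps, node) {
  if (!is.matrix(node)) node <- matrix(node, ncol = 3)
  n <- eps$grid$n
  if (any(node < 1) || any(node > n - 2))
    stop("averaged_local_dielectric requires interior nodes", call. = FALSE)
  i <- node[, 1] + 1L; j <- node[, 2] + 1L; k <- node[, 3] + 1L
  dx <- dim(eps$eps_x); dy <- dim(eps$eps_y); dz <- dim(eps$eps_z)
  at <- function(a, d, ii, jj, kk) a[cbind(ii, jj, kk)]
  (at(eps$eps_x, dx, i - 1L, j, k) + at(eps$eps_x, dx, i, j, k) +
   at(eps$eps_y, dy, i, j - 1L, k) + at(eps$eps_y, dy, i, j, k) +
   at(eps$eps_z, dz, i, j, k - 1L) + at(eps$eps_z, dz, i, j, k)) / 6
}
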