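#' Solver configuration
#'
#' Collects the physical and numerical parameters of the finite-difference
#' Poisson-Boltzmann solve.
#'
#' @param salt Bulk salt concentration, mol/L (default 0.5).
#' @param temperature Temperature in K (default 298.15).
#' @param valences Signed valences of the mobile species, all at
#'   concentration `salt`; must sum to zero (electroneutral bulk). Default
#'   `c(1, -1)`.
#' @param ion_radius Effective radius (Angstrom) used in the mobile-ion
#'   desolvation weight (default 2.0).
#' @param tolerance Convergence threshold: maximum absolute potential update
#'   per sweep, kT/e (default 1e-4).
#' @param max_iterations Sweep budget (default 2000).
#' @param mode `"linear"` (linearised mobile-ion term, default) or
#'   `"nonlinear"` (full Boltzmann term, local Newton updates).
#' @param omega Over-relaxation factor in `[1, 2)`. Default 1.85 for the
#'   linear mode and 1.0 (plain Gauss-Seidel) for the nonlinear mode.
#' @return An object of class `"solver_config"`.
#' @export
solver_config <- function(salt = 0.5, temperature = 298.15,
                          valences = c(1L, -1L), ion_radius = 2.0,
                          tolerance = 1e-4, max_iterations = 2000L,
                          mode = c("linear", "nonlinear"), omega = NULL) {
  mode <- match.arg(mode)
  stopifnot(salt >= 0, temperature > 0, tolerance > 0, max_iterations >= 1,
            ion_radius > 0, length(valences) >= 1)
  if (sum(valences) != 0)
    stop("mobile-ion valences must sum to zero (electroneutral bulk at equal concentrations)",
         call. = FALSE)
  if (is.null(omega)) omega <- if (mode == "linear") 1.85 else 1.0
  stopifnot(omega >= 1, omega < 2)
  structure(list(salt = salt, temperature = temperature,
                 valences = as.integer(valences), ion_radius = ion_radius,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 mode = mode, omega = omega),
            class = "solver_config")
}

# e -> kT/e potential prefactor: phi(kT/e) = f * q/(eps*r)
charge_prefactor <- function(temperature) {
  ion_constants()$coulomb_kcal / kT_kcal(temperature)
}

# mol/L -> ions per A^3
conc_per_A3 <- function(salt) salt * 6.02214076e-4

# inverse Debye length (1/A) for the configured bulk
debye_kappa <- function(cfg, eps_w) {
  if (cfg$salt == 0) return(0)
  f <- charge_prefactor(cfg$temperature)
  sqrt(4 * pi * f * conc_per_A3(cfg$salt) * sum(cfg$valences^2) / eps_w)
}

#' Spread atomic charges onto grid nodes
#'
#' Trilinear (cloud-in-cell) assignment: each atom's charge is distributed
#' over the 8 nodes of its enclosing cell with weights that sum to one, so
#' the total grid charge equals the structure's net charge.
#'
#' @param s A `"pqr"` structure.
#' @param g A `"grid_spec"`.
#' @return A 3-D array (`n^3`) of node charges in units of e.
#' @export
spread_charges <- function(s, g) {
  n <- g$n
  q <- array(0, dim = c(n, n, n))
  fi <- world_to_grid(g, coords(s))
  if (any(fi < 0) || any(fi > n - 1))
    stop("atom outside the grid box", call. = FALSE)
  i0 <- pmin(floor(fi), n - 2)          # cell lower corner, 0-based
  t <- fi - i0
  for (a in seq_len(nrow(fi))) {
    qa <- s$atoms$charge[a]
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) t[a, 1] else 1 - t[a, 1]) *
           (if (dy) t[a, 2] else 1 - t[a, 2]) *
           (if (dz) t[a, 3] else 1 - t[a, 3])
      ii <- i0[a, 1] + dx + 1; jj <- i0[a, 2] + dy + 1; kk <- i0[a, 3] + dz + 1
      q[ii, jj, kk] <- q[ii, jj, kk] + qa * w
    }
  }
  q
}

#' Debye-Hueckel boundary potential
#'
#' Fills the six faces of the grid with the screened-Coulomb superposition
#' `sum_a f q_a exp(-kappa d_a) / (eps_w d_a)` in kT/e, the standard
#' boundary condition for finite-difference Poisson-Boltzmann solves.
#' `kappa` is the inverse Debye length of the configured bulk (0 at zero
#' salt).
#'
#' @param s A `"pqr"` structure.
#' @param g A `"grid_spec"`.
#' @param cfg A `"solver_config"`.
#' @param eps_w Bulk water dielectric (default 80).
#' @return A 3-D array (`n^3`), boundary nodes set, interior zero.
#' @export
boundary_potential <- function(s, g, cfg = solver_config(), eps_w = 80) {
  n <- g$n
  phi <- array(0, dim = c(n, n, n))
  idx <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
  onb <- idx[, 1] %in% c(1L, n) | idx[, 2] %in% c(1L, n) | idx[, 3] %in% c(1L, n)
  b <- idx[onb, , drop = FALSE]
  pts <- grid_to_world(g, b - 1)
  kap <- debye_kappa(cfg, eps_w)
  f <- charge_prefactor(cfg$temperature)
  val <- numeric(nrow(pts))
  for (a in seq_len(nrow(s$atoms))) {
    d <- sqrt((pts[, 1] - s$atoms$x[a])^2 + (pts[, 2] - s$atoms$y[a])^2 +
              (pts[, 3] - s$atoms$z[a])^2)
    d <- pmax(d, g$h / 2)
    val <- val + f * s$atoms$charge[a] * exp(-kap * d) / (eps_w * d)
  }
  phi[b] <- val
  phi
}

#' Ion accessibility weight from a desolvation penalty
#'
#' Converts a per-node ion desolvation penalty into the Boltzmann weight
#' `exp(-dG_solv / RT)` that scales the local mobile-ion density: 1 in bulk,
#' vanishing inside the solute body. This is how mobile ions are kept out of
#' the solute interior in the absence of a sharp boundary.
#'
#' @param dsolv Penalty array or vector, kcal/mol, >= 0.
#' @param temperature Temperature in K (default 298.15).
#' @return Weights in `[0, 1]`, same shape as `dsolv`.
#' @export
ion_accessibility <- function(dsolv, temperature = 298.15) {
  if (any(dsolv < -1e-9))
    stop("desolvation penalty must be non-negative", call. = FALSE)
  exp(-pmax(dsolv, 0) / kT_kcal(temperature))
}

# averaged six-midpoint dielectric for every node; boundary nodes get eps_w
eps_avg_grid <- function(eps) {
  n <- eps$grid$n
  out <- array(eps$eps_w, dim = c(n, n, n))
  ii <- 2:(n - 1)
  out[ii, ii, ii] <-
    (eps$eps_x[ii - 1, ii, ii] + eps$eps_x[ii, ii, ii] +
     eps$eps_y[ii, ii - 1, ii] + eps$eps_y[ii, ii, ii] +
     eps$eps_z[ii, ii, ii - 1] + eps$eps_z[ii, ii, ii]) / 6
  out
}

#' Solve the desolvation-modified Poisson-Boltzmann equation
#'
#' Iterative Gauss-Seidel (optionally over-relaxed) solution of the
#' flux-conservative 7-point discretisation of
#' `div(eps grad phi) = -4 pi (rho_solute + rho_mobile)` on the grid, with
#' Debye-Hueckel boundary values. The mobile-ion charge density is
#' Boltzmann-weighted by both the local potential and the ion desolvation
#' penalty, `exp(-(z phi + dG_solv)/RT)`, which keeps ions out of the
#' low-dielectric solute body. In `"linear"` mode the Boltzmann factor is
#' linearised in `phi`; in `"nonlinear"` mode the full exponential is kept
#' and each node update takes a local Newton step.
#'
#' @param s A `"pqr"` structure (all atoms strictly inside the grid).
#' @param g A `"grid_spec"` built from `s`.
#' @param eps A `"dielectric_field"` on the same grid.
#' @param cfg A `"solver_config"`.
#' @return An object of class `"potential_map"`: list with `grid`, `phi`
#'   (3-D array, kT/e), `iterations`, `converged`, `history` (max update per
#'   sweep), `cfg`.
#' @export
solve_pbe <- function(s, g, eps, cfg = solver_config()) {
  stopifnot(inherits(g, "grid_spec"), inherits(eps, "dielectric_field"))
  n <- g$n
  f <- charge_prefactor(cfg$temperature)
  src <- spread_charges(s, g) * f * 4 * pi / g$h
  phi <- boundary_potential(s, g, cfg, eps$eps_w)

  nsp <- length(cfg$valences)
  lam <- matrix(1, nrow = n^3, ncol = nsp)
  A <- 0
  if (cfg$salt > 0) {
    # per-species accessibility from the z^2-scaled Born penalty at each node
    eavg <- eps_avg_grid(eps)
    pen1 <- ion_constants()$coulomb_kcal / (2 * cfg$ion_radius) *
      (1 / eavg - 1 / eps$eps_w)
    pen1 <- pmax(pen1, 0)
    for (sp in seq_len(nsp))
      lam[, sp] <- as.vector(ion_accessibility(cfg$valences[sp]^2 * pen1,
                                               cfg$temperature))
    A <- 4 * pi * g$h^2 * f * conc_per_A3(cfg$salt)
  }

  res <- pbe_relax(phi, eps$eps_x, eps$eps_y, eps$eps_z, src, lam,
                   cfg$valences, A, n, cfg$tolerance, cfg$max_iterations,
                   cfg$omega, cfg$mode == "nonlinear")
  if (!res$converged)
    warning(sprintf("PB solver did not converge in %d sweeps (last max update %.3g kT/e)",
                    res$iterations, utils::tail(res$history, 1)),
            call. = FALSE)
  structure(list(grid = g, phi = phi, iterations = res$iterations,
                 converged = res$converged, history = res$history,
                 cfg = cfg),
            class = "potential_map")
}

#' @export
print.potential_map <- function(x, ...) {
  cat(sprintf("potential map: %d^3 nodes, phi in kT/e, range [%.3f, %.3f]\n",
              x$grid$n, min(x$phi), max(x$phi)))
  cat(sprintf("  %s after %d sweeps (mode %s, salt %g M)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$cfg$mode, x$cfg$salt))
  invisible(x)
}
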