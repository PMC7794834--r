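#' Uniform-dielectric Coulomb potential map
#'
#' Computes, at every grid node, the unscreened Coulomb potential of the
#' solute charges in a homogeneous medium, `sum_a q_a / (eps d_a)` converted
#' to kT/e. Distances are capped below at half a grid spacing so nodes
#' coincident with an atom centre stay finite. This is the potential used by
#' molecular-dynamics-setup ion placers, and serves as the reference against
#' which the Poisson-Boltzmann + desolvation treatment is compared.
#'
#' @param s A `"pqr"` structure.
#' @param g A `"grid_spec"`.
#' @param eps_uniform Homogeneous dielectric constant (default 80).
#' @param temperature Temperature in K (default 298.15).
#' @return A 3-D array (`n^3`) of potentials in kT/e.
#' @export
coulomb_map <- function(s, g, eps_uniform = 80, temperature = 298.15) {
  stopifnot(eps_uniform >= 1)
  n <- g$n
  ax <- lapply(1:3, function(a) axis_coords(g, a))
  phi <- array(0, dim = c(n, n, n))
  f <- charge_prefactor(temperature)
  for (a in seq_len(nrow(s$atoms))) {
    at <- s$atoms[a, ]
    if (at$charge == 0) next
    d2 <- outer(outer((ax[[1]] - at$x)^2, (ax[[2]] - at$y)^2, "+"),
                (ax[[3]] - at$z)^2, "+")
    d <- pmax(sqrt(d2), g$h / 2)
    phi <- phi + f * at$charge / (eps_uniform * d)
  }
  phi
}

#' Greedy Coulomb-potential ion placement
#'
#' Emulates the standard molecular-dynamics-setup placer: among grid nodes
#' farther than `min_dist_surface` from the solute van der Waals surface
#' (distance to the nearest atom centre minus that atom's radius), place
#' each ion at the node minimising `q_ion * phi` under the uniform-dielectric
#' Coulomb potential; after each placement the placed ion's own Coulomb
#' contribution is added to the map so subsequent ions respond to it. Placed
#' ions additionally keep a mutual separation greater than
#' `min_dist_surface`. Ties are broken by lexicographic grid index.
#'
#' @param s A `"pqr"` structure.
#' @param n_ions Number of ions to place.
#' @param ion An `"ion_spec"` or species string.
#' @param min_dist_surface Standoff from the vdW surface in Angstrom
#'   (default 6).
#' @param g Optional `"grid_spec"`; when missing, a box with 30% solute fill
#'   is built so that eligible nodes exist beyond the standoff.
#' @param eps_uniform Homogeneous dielectric (default 80).
#' @param temperature Temperature in K (default 298.15).
#' @return A list with `positions` (n_ions x 3 matrix, world coordinates),
#'   `energies` (q_ion * phi at placement time, kT units) and `grid`.
#' @export
place_ions <- function(s, n_ions, ion, min_dist_surface = 6, g = NULL,
                       eps_uniform = 80, temperature = 298.15) {
  stopifnot(n_ions >= 1)
  if (is.character(ion)) ion <- ion_spec(ion)
  if (is.null(g)) g <- build_grid(s, perfil = 30)
  n <- g$n
  phi <- coulomb_map(s, g, eps_uniform, temperature)

  # distance from each node to the vdW surface
  ax <- lapply(1:3, function(a) axis_coords(g, a))
  surf <- array(Inf, dim = c(n, n, n))
  for (a in seq_len(nrow(s$atoms))) {
    at <- s$atoms[a, ]
    d2 <- outer(outer((ax[[1]] - at$x)^2, (ax[[2]] - at$y)^2, "+"),
                (ax[[3]] - at$z)^2, "+")
    surf <- pmin(surf, sqrt(d2) - at$radius)
  }
  eligible <- surf > min_dist_surface
  eligible[c(1, n), , ] <- FALSE
  eligible[, c(1, n), ] <- FALSE
  eligible[, , c(1, n)] <- FALSE
  if (!any(eligible))
    stop("no eligible nodes beyond the surface standoff; placed 0 ions",
         call. = FALSE)

  idx_all <- which(eligible, arr.ind = TRUE)          # 1-based
  # lexicographic (ix, iy, iz) tie-break order
  lex <- order(idx_all[, 1], idx_all[, 2], idx_all[, 3])
  idx_all <- idx_all[lex, , drop = FALSE]
  pos_all <- grid_to_world(g, idx_all - 1)
  lin_all <- idx_all[, 1] + n * (idx_all[, 2] - 1) + n^2 * (idx_all[, 3] - 1)
  f <- charge_prefactor(temperature)

  placed <- matrix(numeric(0), ncol = 3)
  energies <- numeric(0)
  avail <- rep(TRUE, nrow(idx_all))
  for (m in seq_len(n_ions)) {
    if (!any(avail)) {
      warning(sprintf("only %d of %d ions could be placed", m - 1L, n_ions),
              call. = FALSE)
      break
    }
    sc <- ion$valence * phi[lin_all]
    sc[!avail] <- Inf
    best <- which.min(sc)                              # first minimum = lex order
    p <- pos_all[best, ]
    placed <- rbind(placed, p)
    energies <- c(energies, sc[best])
    # placed ion contributes to the map for subsequent placements
    d <- sqrt((pos_all[, 1] - p[1])^2 + (pos_all[, 2] - p[2])^2 +
              (pos_all[, 3] - p[3])^2)
    dm <- pmax(d, g$h / 2)
    phi[lin_all] <- phi[lin_all] + f * ion$valence / (eps_uniform * dm)
    avail <- avail & d > min_dist_surface
  }
  rownames(placed) <- NULL
  list(positions = placed, energies = energies, grid = g)
}
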