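#' Site energy of a candidate grid point
#'
#' The score of a grid site is the electrostatic interaction of the ion with
#' the solute field plus the Born desolvation penalty at that site:
#' `G(s) = q_ion * phi(s) + dG_solv(eps_r(s))`, in kcal/mol. The potential is
#' supplied in kT/e and converted; the local dielectric is the six-midpoint
#' node average. Low (negative) `G(s)` marks a favourable ion position.
#'
#' @param phi_s Potential at the site, kT/e.
#' @param eps_avg Averaged local dielectric at the site.
#' @param ion An `"ion_spec"`.
#' @param temperature Temperature in K (default 298.15).
#' @param eps_w Bulk water dielectric (default 80).
#' @return Energy in kcal/mol (vectorised).
#' @export
site_energy <- function(phi_s, eps_avg, ion, temperature = 298.15,
                        eps_w = 80) {
  ion$valence * phi_s * kT_kcal(temperature) +
    desolvation_penalty(ion, eps_avg, eps_w)
}

#' Enumerate candidate grid nodes outside the van der Waals surface
#'
#' Candidate ion positions are all interior grid nodes whose distance to
#' every atom centre strictly exceeds that atom's van der Waals radius
#' (nodes inside or on any atom sphere are excluded).
#'
#' @param g A `"grid_spec"`.
#' @param s A `"pqr"` structure.
#' @return An m x 3 matrix of 0-based node indices.
#' @export
enumerate_candidates <- function(g, s) {
  n <- g$n
  keep <- array(FALSE, dim = c(n, n, n))
  ii <- 2:(n - 1)
  keep[ii, ii, ii] <- TRUE
  ax <- lapply(1:3, function(a) axis_coords(g, a))
  for (a in seq_len(nrow(s$atoms))) {
    at <- s$atoms[a, ]
    rx <- which(abs(ax[[1]] - at$x) <= at$radius)
    ry <- which(abs(ax[[2]] - at$y) <= at$radius)
    rz <- which(abs(ax[[3]] - at$z) <= at$radius)
    if (!length(rx) || !length(ry) || !length(rz)) next
    d2 <- outer(outer((ax[[1]][rx] - at$x)^2, (ax[[2]][ry] - at$y)^2, "+"),
                (ax[[3]][rz] - at$z)^2, "+")
    keep[rx, ry, rz][d2 <= at$radius^2] <- FALSE
  }
  idx <- which(keep, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L)
    stop("no candidate nodes outside the vdW surface (grid too small)",
         call. = FALSE)
  colnames(idx) <- c("ix", "iy", "iz")
  idx
}

#' Rank candidate sites by energy with a min-heap priority queue
#'
#' Sites with negative energy are pushed onto a binary min-heap and popped in
#' non-decreasing energy order; non-negative sites are discarded. Ties are
#' broken by lexicographic grid index (x, then y, then z) so that runs are
#' deterministic.
#'
#' @param energies Numeric vector of site energies, kcal/mol.
#' @param nodes m x 3 matrix of 0-based grid indices, one row per energy.
#' @return Integer vector of row positions into `energies`/`nodes`, in pop
#'   order (lowest energy first); only negative-energy rows appear.
#' @export
rank_sites <- function(energies, nodes) {
  stopifnot(length(energies) == nrow(nodes))
  heap_rank(as.numeric(energies), as.integer(nodes[, 1]),
            as.integer(nodes[, 2]), as.integer(nodes[, 3]))
}

#' Steric clash filter
#'
#' A site passes when its distance to every atom is at least
#' `R_ion + R_atom`; a site strictly closer to any atom clashes.
#'
#' @param site 3-vector, world coordinates (Angstrom).
#' @param s A `"pqr"` structure.
#' @param ion An `"ion_spec"` (uses `clash_radius`).
#' @return `TRUE` if the site is clash-free.
#' @export
passes_clash <- function(site, s, ion) {
  a <- s$atoms
  d <- sqrt((a$x - site[1])^2 + (a$y - site[2])^2 + (a$z - site[3])^2)
  all(d >= ion$clash_radius + a$radius)
}

#' Mutual proximity filter
#'
#' A new site passes when its distance to every already-accepted site is
#' strictly greater than `min_sep`.
#'
#' @param site 3-vector, world coordinates.
#' @param accepted m x 3 matrix of accepted site coordinates (may have zero
#'   rows).
#' @param min_sep Minimum separation in Angstrom (default 6).
#' @return `TRUE` if the site is far enough from all accepted sites.
#' @export
passes_proximity <- function(site, accepted, min_sep = 6) {
  if (is.null(accepted) || NROW(accepted) == 0L) return(TRUE)
  accepted <- matrix(accepted, ncol = 3)
  d <- sqrt((accepted[, 1] - site[1])^2 + (accepted[, 2] - site[2])^2 +
            (accepted[, 3] - site[3])^2)
  all(d > min_sep)
}

#' Predict non-specifically surface-bound ion positions
#'
#' Full prediction pipeline: build the grid, compute the Gaussian smooth
#' dielectric field, solve the desolvation-modified Poisson-Boltzmann
#' equation, score every grid node outside the van der Waals surface with
#' the site energy `G(s)`, rank negative-energy sites with a min-heap, and
#' pop sites in energy order through the steric-clash and 6 A mutual
#' proximity filters until `n_max` sites are accepted or the queue is
#' exhausted. Accepted sites receive ranks 1, 2, ...
#'
#' @param s A `"pqr"` structure. HETATM records (pre-existing ions, waters)
#'   are stripped first when ATOM records are present.
#' @param ion An `"ion_spec"` or a species string (`"CA2"`, `"MG2"`,
#'   `"ZN2"`, `"CL1"`).
#' @param n_max Maximum number of sites to report (default 10).
#' @param scale Grid resolution, grids per Angstrom (default 2).
#' @param perfil Percent solute fill of the box (default 70).
#' @param eps_in,eps_w Reference dielectric constants (defaults 2 and 80).
#' @param sigma Gaussian relative variance (default 0.93).
#' @param salt Salt concentration, mol/L (default 0.5).
#' @param mode Solver mode, `"linear"` or `"nonlinear"`.
#' @param temperature Temperature in K (default 298.15).
#' @param cfg Optional `"solver_config"` overriding `salt`, `mode` and
#'   `temperature`.
#' @param min_sep Mutual proximity threshold in Angstrom (default 6).
#' @param desolv_weight Multiplier on the desolvation term of the site
#'   energy (default 1; 0 scores sites by the interaction term alone).
#' @param neighbor_pad Sites report atoms within
#'   `clash_radius + R_atom + neighbor_pad` (default 2 A).
#' @param strip Drop HETATM records before predicting (default TRUE).
#' @return An object of class `"ion_sites"`: list with `sites` (data frame
#'   with columns `rank`, `x`, `y`, `z`, `energy`, `local_eps`, `desolv`),
#'   `neighbors` (list of per-site data frames of nearby atoms),
#'   `ion`, `grid`, `potential`, `params`, `structure`. An empty `sites`
#'   table is a valid result.
#' @examples
#' \donttest{
#' s <- make_born_ion(3, 2)
#' pred <- predict_ion_sites(s, "CL1", n_max = 3)
#' pred
#' }
#' @export
predict_ion_sites <- function(s, ion, n_max = 10, scale = 2, perfil = 70,
                              eps_in = 2, eps_w = 80, sigma = 0.93,
                              salt = 0.5, mode = "linear",
                              temperature = 298.15, cfg = NULL,
                              min_sep = 6, desolv_weight = 1,
                              neighbor_pad = 2, strip = TRUE) {
  stopifnot(inherits(s, "pqr"), n_max >= 1)
  if (is.character(ion)) ion <- ion_spec(ion)
  if (strip && any(s$atoms$record == "ATOM") &&
      any(s$atoms$record == "HETATM"))
    s <- strip_hetero(s)
  if (is.null(cfg))
    cfg <- solver_config(salt = salt, temperature = temperature,
                         ion_radius = ion$effective_radius, mode = mode)

  g <- build_grid(s, scale = scale, perfil = perfil)
  eps <- dielectric_field(g, s, eps_in = eps_in, eps_w = eps_w, sigma = sigma)
  map <- suppressWarnings(solve_pbe(s, g, eps, cfg))

  cand <- enumerate_candidates(g, s)
  eavg <- averaged_local_dielectric(eps, cand)
  dsolv <- desolvation_penalty(ion, eavg, eps_w)
  phi_s <- map$phi[cand + 1L]
  energy <- ion$valence * phi_s * kT_kcal(cfg$temperature) +
    desolv_weight * dsolv

  order_idx <- rank_sites(energy, cand)

  acc_pos <- matrix(numeric(0), ncol = 3)
  acc_row <- integer(0)
  for (idx in order_idx) {
    pos <- grid_to_world(g, cand[idx, ])
    if (!passes_clash(pos, s, ion)) next
    if (!passes_proximity(pos, acc_pos, min_sep)) next
    acc_pos <- rbind(acc_pos, pos)
    acc_row <- c(acc_row, idx)
    if (length(acc_row) >= n_max) break
  }

  k <- length(acc_row)
  sites <- data.frame(
    rank = seq_len(k),
    x = if (k) acc_pos[, 1] else numeric(0),
    y = if (k) acc_pos[, 2] else numeric(0),
    z = if (k) acc_pos[, 3] else numeric(0),
    energy = energy[acc_row],
    local_eps = eavg[acc_row],
    desolv = dsolv[acc_row]
  )
  neighbors <- lapply(seq_len(k), function(i) {
    a <- s$atoms
    d <- sqrt((a$x - sites$x[i])^2 + (a$y - sites$y[i])^2 +
              (a$z - sites$z[i])^2)
    cutoff <- ion$clash_radius + a$radius + neighbor_pad
    nb <- a[d <= cutoff, c("serial", "name", "resname", "chain", "resno"),
            drop = FALSE]
    nb$distance <- d[d <= cutoff]
    nb[order(nb$distance), , drop = FALSE]
  })

  structure(list(sites = sites, neighbors = neighbors, ion = ion, grid = g,
                 potential = map, structure = s,
                 params = list(scale = scale, perfil = perfil,
                               eps_in = eps_in, eps_w = eps_w, sigma = sigma,
                               salt = cfg$salt, mode = cfg$mode,
                               temperature = cfg$temperature,
                               n_max = n_max, min_sep = min_sep,
                               desolv_weight = desolv_weight),
                 converged = map$converged),
            class = "ion_sites")
}
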