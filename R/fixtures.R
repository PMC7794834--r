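#' Single Born ion fixture
#'
#' One atom at the origin with the given charge and radius: the minimal
#' structure whose potential has the Coulomb / screened-Coulomb closed form,
#' used to exercise the solver and dielectric limits.
#'
#' @param q Charge in e.
#' @param radius van der Waals radius in Angstrom.
#' @param label Structure label.
#' @return A `"pqr"` structure with one ATOM record.
#' @export
make_born_ion <- function(q, radius = 2, label = "born_ion") {
  new_structure(data.frame(
    record = "ATOM", serial = 1L, name = "C", resname = "FIX",
    chain = "A", resno = 1L, x = 0, y = 0, z = 0,
    charge = q, radius = radius, stringsAsFactors = FALSE), label)
}

#' Dipole fixture
#'
#' Two opposite charges `+q`/`-q` separated along the x axis, centred on the
#' origin. The net charge is zero; the far field decays as a dipole.
#'
#' @param q Charge magnitude in e.
#' @param separation Centre-to-centre distance in Angstrom.
#' @param radius Atom radius in Angstrom.
#' @return A `"pqr"` structure with two ATOM records.
#' @export
make_dipole <- function(q = 1, separation = 4, radius = 2) {
  new_structure(data.frame(
    record = "ATOM", serial = 1:2, name = c("CP", "CN"), resname = "FIX",
    chain = "A", resno = 1:2,
    x = c(-separation / 2, separation / 2), y = 0, z = 0,
    charge = c(q, -q), radius = radius, stringsAsFactors = FALSE), "dipole")
}

#' Charged-patch fixture
#'
#' A compact slab of uncharged atoms (two `n_side` x `n_side` layers) whose
#' top face carries a localised charge on its central atom. The outward
#' normal of the charged face, `(0, 0, 1)`, is returned as ground truth for
#' directional tests: a counter-ion should be attracted to the patch side.
#' Atom positions get a small seeded jitter so distinct seeds give distinct
#' (but reproducible) structures.
#'
#' @param n_side Atoms per edge of each layer (default 3; at least 2, so the
#'   cluster has at least 8 atoms).
#' @param patch_charge Charge on the top-face central atom, in e.
#' @param radius Atom radius (default 1.8 A).
#' @param spacing Lattice spacing (default 2.8 A).
#' @param jitter Uniform positional jitter half-width (default 0.1 A).
#' @param seed Seed for the jitter.
#' @return A list with `structure` (a `"pqr"`), `normal` (outward normal of
#'   the charged face), `face_center` (position of the charged atom).
#' @export
make_charged_patch <- function(n_side = 3, patch_charge = 3, radius = 1.8,
                               spacing = 2.8, jitter = 0.1, seed = 1) {
  stopifnot(n_side >= 2)
  ax <- (seq_len(n_side) - (n_side + 1) / 2) * spacing
  gridxy <- expand.grid(x = ax, y = ax)
  pos <- rbind(cbind(gridxy, z = 0), cbind(gridxy, z = spacing))
  set.seed(seed)
  pos <- pos + matrix(stats::runif(3 * nrow(pos), -jitter, jitter),
                      ncol = 3)
  # central atom of the top (z = spacing) layer carries the patch charge,
  # pinned on the axis so the face normal is exact
  top_center <- nrow(gridxy) + ceiling(nrow(gridxy) / 2)
  pos[top_center, 1:2] <- 0
  charge <- numeric(nrow(pos))
  charge[top_center] <- patch_charge
  s <- new_structure(data.frame(
    record = "ATOM", serial = seq_len(nrow(pos)), name = "C",
    resname = "FIX", chain = "A", resno = seq_len(nrow(pos)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = charge, radius = radius, stringsAsFactors = FALSE),
    "charged_patch")
  list(structure = s, normal = c(0, 0, 1),
       face_center = unlist(pos[top_center, ], use.names = FALSE))
}

#' Random-cluster fixture
#'
#' A seeded random cluster of atoms inside a ball, with small random partial
#' charges. Used for property tests (symmetries, round trips) where no
#' particular geometry is assumed.
#'
#' @param n_atoms Number of atoms (default 12).
#' @param seed Random seed.
#' @param ball_radius Radius of the containing ball (default 6 A).
#' @param charge_scale Half-width of the uniform charge distribution
#'   (default 0.5 e).
#' @return A `"pqr"` structure.
#' @export
make_random_cluster <- function(n_atoms = 12, seed = 1, ball_radius = 6,
                                charge_scale = 0.5) {
  set.seed(seed)
  # rejection-free: direction * radius^(1/3) sampling
  u <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- ball_radius * stats::runif(n_atoms)^(1 / 3)
  pos <- u * r
  new_structure(data.frame(
    record = "ATOM", serial = seq_len(n_atoms), name = "C", resname = "FIX",
    chain = "A", resno = seq_len(n_atoms),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = round(stats::runif(n_atoms, -charge_scale, charge_scale), 3),
    radius = round(stats::runif(n_atoms, 1.2, 2.2), 2),
    stringsAsFactors = FALSE), sprintf("random_cluster_seed%d", seed))
}

#' Buried-pocket fixture
#'
#' A cup of large uncharged beads opening towards +z with a charged bead at
#' the bottom. Clash-allowed positions inside the cup sit in a region of
#' substantially lowered dielectric (the pocket), while positions above the
#' mouth are nearly bulk-like: the fixture separates the interaction term
#' and the desolvation penalty of the site energy, which pull in opposite
#' directions for a counter-ion. Deterministic (no randomness).
#'
#' @param pocket_charge Charge of the bottom bead in e (default -1).
#' @param bead_radius Bead van der Waals radius (default 4 A).
#' @return A list with `structure`, `charge_pos` (position of the charged
#'   bead), `axis` (pocket opening direction, `(0,0,1)`) and `mouth_z`
#'   (z of the upper wall ring).
#' @export
make_buried_pocket <- function(pocket_charge = -1, bead_radius = 4) {
  ring <- function(r, z, m, phase = 0) {
    th <- phase + 2 * pi * (seq_len(m) - 1) / m
    cbind(x = r * cos(th), y = r * sin(th), z = z)
  }
  pos <- rbind(c(0, 0, 0),
               ring(6.5, 3.5, 8),
               ring(6.5, 7.0, 8, phase = pi / 8),
               ring(4.5, -5.0, 6))   # base: blocks approach from below
  charge <- c(pocket_charge, numeric(nrow(pos) - 1))
  s <- new_structure(data.frame(
    record = "ATOM", serial = seq_len(nrow(pos)), name = "C",
    resname = "FIX", chain = "A", resno = seq_len(nrow(pos)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = charge, radius = bead_radius, stringsAsFactors = FALSE),
    "buried_pocket")
  list(structure = s, charge_pos = c(0, 0, 0), axis = c(0, 0, 1),
       mouth_z = 7.0)
}

#' Write a reference-position table
#'
#' Plain 3-column (x y z) whitespace-separated table with a comment header,
#' the format read back by [read_reference_positions()].
#'
#' @param positions r x 3 matrix of positions.
#' @param path Output file.
#' @param comment Optional header comment.
#' @return `path`, invisibly.
#' @export
write_reference_positions <- function(positions, path, comment = NULL) {
  positions <- ref_matrix(positions)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(sprintf("%.4f %.4f %.4f",
                     positions[, 1], positions[, 2], positions[, 3]), con)
  invisible(path)
}
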