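#' Build the cubic finite-difference grid around a structure
#'
#' The computation box is a cube centred on the geometric centre of the
#' structure. Its side is the largest extent of the solute (atom centres plus
#' van der Waals radii, so the fill fraction measures the solute body) divided
#' by `perfil/100`, then rounded up so that the number of nodes per axis is
#' the smallest odd integer with `(n - 1) * h >= side` (`h = 1/scale`). An
#' odd `n` guarantees a central node. Nodes are vertex-centred: node index
#' `i` (0-based) sits at `origin + i * h`.
#'
#' @param s A `"pqr"` structure.
#' @param scale Grid resolution in grids per Angstrom (default 2).
#' @param perfil Percent of the box filled by the solute (default 70).
#' @return An object of class `"grid_spec"`: list with `scale`, `h`, `n`,
#'   `origin` (world position of node (0,0,0)), `center`, `side`.
#' @examples
#' s <- make_born_ion(1, 2)
#' g <- build_grid(s)       # 13 nodes per axis at the defaults
#' @export
build_grid <- function(s, scale = 2, perfil = 70) {
  stopifnot(inherits(s, "pqr"), scale > 0)
  if (perfil >= 100 || perfil <= 0)
    stop("perfil must lie strictly between 0 and 100 (solute must not touch the box boundary)",
         call. = FALSE)
  a <- s$atoms
  lo <- c(min(a$x - a$radius), min(a$y - a$radius), min(a$z - a$radius))
  hi <- c(max(a$x + a$radius), max(a$y + a$radius), max(a$z + a$radius))
  extent <- max(hi - lo)
  center <- (lo + hi) / 2
  side <- extent / (perfil / 100)
  h <- 1 / scale
  n <- ceiling(side / h) + 1L
  if (n %% 2L == 0L) n <- n + 1L
  n <- max(n, 5L)
  origin <- center - (n - 1L) / 2 * h
  structure(list(scale = scale, h = h, n = as.integer(n),
                 origin = origin, center = center, side = (n - 1L) * h),
            class = "grid_spec")
}

#' World to grid coordinate transform
#'
#' @param g A `"grid_spec"`.
#' @param p A 3-vector or n x 3 matrix of world coordinates (Angstrom).
#' @return Fractional 0-based grid indices, same shape as `p`.
#' @export
world_to_grid <- function(g, p) {
  if (is.matrix(p)) sweep(p, 2, g$origin) * g$scale
  else (p - g$origin) * g$scale
}

#' Grid to world coordinate transform
#'
#' @param g A `"grid_spec"`.
#' @param idx Fractional 0-based grid indices (3-vector or n x 3 matrix).
#' @return World coordinates in Angstrom.
#' @export
grid_to_world <- function(g, idx) {
  if (is.matrix(idx)) sweep(idx * g$h, 2, g$origin, "+")
  else g$origin + idx * g$h
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d^3 nodes, h = %g A (%g grids/A), side %.2f A\n",
              x$n, x$h, x$scale, x$side))
  cat(sprintf("  origin (%.3f, %.3f, %.3f), center (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# world coordinates of the node axis i (0 .. n-1), one axis
axis_coords <- function(g, axis) g$origin[axis] + (seq_len(g$n) - 1) * g$h
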