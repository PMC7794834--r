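#' Export a 3-D grid map as plain text
#'
#' Writes a node-centred 3-D array (a potential map in kT/e, or a density /
#' dielectric array) with a self-describing header: grid spec, value label,
#' and any extra parameters. Values are written in node order (x fastest).
#'
#' @param values 3-D array of node values, or a `"potential_map"`.
#' @param g A `"grid_spec"` (taken from the map when `values` is one).
#' @param path Output file.
#' @param label Value label recorded in the header.
#' @param extra Named list of extra header fields.
#' @return `path`, invisibly.
#' @export
write_grid_map <- function(values, g = NULL, path, label = "phi_kT_per_e",
                           extra = list()) {
  if (inherits(values, "potential_map")) {
    g <- values$grid
    values <- values$phi
  }
  stopifnot(inherits(g, "grid_spec"), length(values) == g$n^3)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# gridmap n=%d scale=%.8g", g$n, g$scale),
           sprintf("# origin %.8g %.8g %.8g",
                   g$origin[1], g$origin[2], g$origin[3]),
           sprintf("# label %s", label),
           vapply(names(extra), function(k)
             sprintf("# %s %s", k, format(extra[[k]])), character(1)))
  writeLines(hdr, con)
  writeLines(format(as.vector(values), digits = 9, trim = TRUE,
                    scientific = TRUE), con)
  invisible(path)
}

#' Read a plain-text grid map written by [write_grid_map()]
#'
#' @param path Input file.
#' @return A list with `values` (3-D array), `grid` (a `"grid_spec"`),
#'   `label`, `header` (all header lines).
#' @export
read_grid_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  dat <- as.numeric(lines[!grepl("^#", lines)])
  m <- regmatches(hdr[1], regexec("n=(\\d+) scale=([0-9.eE+-]+)", hdr[1]))[[1]]
  n <- as.integer(m[2]); scale <- as.numeric(m[3])
  ol <- strsplit(trimws(sub("# origin", "", hdr[grepl("^# origin", hdr)][1])),
                 "[[:space:]]+")[[1]]
  origin <- as.numeric(ol)
  if (length(dat) != n^3) stop("grid map length mismatch", call. = FALSE)
  g <- structure(list(scale = scale, h = 1 / scale, n = n, origin = origin,
                      center = origin + (n - 1) / 2 / scale,
                      side = (n - 1) / scale),
                 class = "grid_spec")
  lab <- sub("# label ", "", hdr[grepl("^# label", hdr)][1])
  list(values = array(dat, dim = c(n, n, n)), grid = g, label = lab,
       header = hdr)
}
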