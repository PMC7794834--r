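#' @export
print.ion_sites <- function(x, ...) {
  cat(sprintf("ion site prediction for '%s' (%s, z = %+d)\n",
              x$structure$label, x$ion$species, x$ion$valence))
  if (!x$converged)
    cat("  warning: PB solver did not converge; energies may be inaccurate\n")
  if (nrow(x$sites) == 0L) {
    cat("  no favourable (negative-energy) sites found\n")
  } else {
    df <- x$sites
    df$energy <- round(df$energy, 3)
    df$local_eps <- round(df$local_eps, 2)
    df$desolv <- round(df$desolv, 3)
    df$x <- round(df$x, 3); df$y <- round(df$y, 3); df$z <- round(df$z, 3)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.ion_sites <- function(object, ...) {
  x <- object
  cat(sprintf("Prediction of surface-bound %s positions on '%s'\n",
              x$ion$species, x$structure$label))
  cat(sprintf("  grid %d^3 (h = %g A), eps_in %g / eps_w %g, sigma %g\n",
              x$grid$n, x$grid$h, x$params$eps_in, x$params$eps_w,
              x$params$sigma))
  cat(sprintf("  salt %g M, %s PB, T = %g K; solver %s after %d sweeps\n",
              x$params$salt, x$params$mode, x$params$temperature,
              if (x$converged) "converged" else "NOT converged",
              x$potential$iterations))
  cat(sprintf("  %d site(s) accepted (n_max %d, min separation %g A)\n",
              nrow(x$sites), x$params$n_max, x$params$min_sep))
  if (nrow(x$sites) > 0L) {
    cat(sprintf("  energies %.3f .. %.3f kcal/mol; local eps %.1f .. %.1f\n",
                min(x$sites$energy), max(x$sites$energy),
                min(x$sites$local_eps), max(x$sites$local_eps)))
    nb <- x$neighbors[[1]]
    if (nrow(nb) > 0L)
      cat(sprintf("  rank-1 nearest atom: %s/%s %d at %.2f A\n",
                  nb$resname[1], nb$name[1], nb$resno[1], nb$distance[1]))
  }
  invisible(x)
}

#' @export
as.data.frame.ion_sites <- function(x, ...) x$sites

#' Plot predicted sites against the structure
#'
#' A simple 2-D projection (default xy) of atom positions (open circles,
#' scaled to vdW radius) and predicted sites (filled, labelled by rank).
#'
#' @param x An `"ion_sites"` object.
#' @param axes Which two coordinates to plot, e.g. `c("x", "y")`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ion_sites <- function(x, axes = c("x", "y"), ...) {
  a <- x$structure$atoms
  s <- x$sites
  u <- axes[1]; v <- axes[2]
  rng <- function(w) range(c(a[[w]], s[[w]]), na.rm = TRUE) + c(-3, 3)
  graphics::plot(a[[u]], a[[v]], asp = 1, xlim = rng(u), ylim = rng(v),
                 xlab = paste(u, "(A)"), ylab = paste(v, "(A)"),
                 pch = 1, cex = pmax(a$radius, 0.5),
                 col = ifelse(a$charge > 0, "firebrick",
                              ifelse(a$charge < 0, "steelblue", "grey40")),
                 main = sprintf("%s sites on %s", x$ion$species,
                                x$structure$label), ...)
  if (nrow(s) > 0L) {
    graphics::points(s[[u]], s[[v]], pch = 19, col = "darkorange", cex = 1.2)
    graphics::text(s[[u]], s[[v]], labels = s$rank, pos = 3, cex = 0.8)
  }
  invisible(x)
}

#' Write predicted sites as a tab-separated table
#'
#' Columns: rank, x, y, z, energy (kcal/mol), local_eps, desolv (kcal/mol),
#' neighbors (semicolon-separated `name:resno:distance` entries). Header
#' lines (prefixed `#`) carry the run manifest for reproducibility.
#'
#' @param x An `"ion_sites"` object.
#' @param path Output file path.
#' @param manifest Optional character vector of manifest lines to embed.
#' @return `path`, invisibly.
#' @export
write_sites <- function(x, path, manifest = NULL) {
  s <- x$sites
  nbcol <- vapply(seq_len(nrow(s)), function(i) {
    nb <- x$neighbors[[i]]
    if (nrow(nb) == 0L) return("")
    paste(sprintf("%s:%d:%.2f", nb$name, nb$resno, nb$distance),
          collapse = ";")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) writeLines(paste0("# ", manifest), con)
  writeLines(paste(c("rank", "x", "y", "z", "energy_kcal", "local_eps",
                     "desolv_kcal", "neighbors"), collapse = "\t"), con)
  if (nrow(s) > 0L)
    writeLines(sprintf("%d\t%.3f\t%.3f\t%.3f\t%.4f\t%.3f\t%.4f\t%s",
                       s$rank, s$x, s$y, s$z, s$energy, s$local_eps,
                       s$desolv, nbcol), con)
  invisible(path)
}

#' Write predicted sites as viewer-loadable HETATM records
#'
#' Emits one PDB-style HETATM record per site (residue name = ion species,
#' B-factor column = site energy) so predictions can be inspected in a
#' molecular viewer alongside the structure.
#'
#' @param x An `"ion_sites"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sites_pdb <- function(x, path) {
  s <- x$sites
  el <- substr(gsub("[0-9]", "", x$ion$species), 1, 2)
  lines <- sprintf("HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   s$rank, el, substr(x$ion$species, 1, 3), s$rank,
                   s$x, s$y, s$z, 1.0, pmax(pmin(s$energy, 99.99), -99.99),
                   el)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
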