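# Independent exhaustive-scan oracles. These deliberately avoid the package's
# candidate enumeration, heap ranking and filter loop: everything below is a
# plain scan over all nodes, a full sort, and a linear filter pass.

# all interior nodes strictly outside every atom sphere, by brute force
oracle_candidates <- function(g, s) {
  ax <- lapply(1:3, function(a) g$origin[a] + (0:(g$n - 1)) * g$h)
  nodes <- as.matrix(expand.grid(ix = 0:(g$n - 1), iy = 0:(g$n - 1),
                                 iz = 0:(g$n - 1)))
  interior <- nodes[, 1] >= 1 & nodes[, 1] <= g$n - 2 &
              nodes[, 2] >= 1 & nodes[, 2] <= g$n - 2 &
              nodes[, 3] >= 1 & nodes[, 3] <= g$n - 2
  keep <- interior
  pts <- cbind(ax[[1]][nodes[, 1] + 1], ax[[2]][nodes[, 2] + 1],
               ax[[3]][nodes[, 3] + 1])
  for (a in seq_len(nrow(s$atoms))) {
    d2 <- (pts[, 1] - s$atoms$x[a])^2 + (pts[, 2] - s$atoms$y[a])^2 +
          (pts[, 3] - s$atoms$z[a])^2
    keep <- keep & d2 > s$atoms$radius[a]^2
  }
  nodes[keep, , drop = FALSE]
}

# full pipeline oracle: score every exterior node, sort fully (energy, then
# lexicographic grid index), then scan applying clash and proximity filters
oracle_predict <- function(s, ion, n_max, scale = 2, perfil = 70,
                           eps_in = 2, eps_w = 80, sigma = 0.93, salt = 0.5,
                           temperature = 298.15, min_sep = 6,
                           desolv_weight = 1) {
  if (is.character(ion)) ion <- ion_spec(ion)
  g <- build_grid(s, scale = scale, perfil = perfil)
  eps <- dielectric_field(g, s, eps_in = eps_in, eps_w = eps_w, sigma = sigma)
  cfg <- solver_config(salt = salt, temperature = temperature,
                       ion_radius = ion$effective_radius)
  map <- suppressWarnings(solve_pbe(s, g, eps, cfg))

  nodes <- oracle_candidates(g, s)
  kT <- ionsite::ion_constants()$boltzmann_kcal * temperature
  m <- nrow(nodes)
  en <- numeric(m)
  for (r in seq_len(m)) {
    i <- nodes[r, 1] + 1L; j <- nodes[r, 2] + 1L; k <- nodes[r, 3] + 1L
    ea <- (eps$eps_x[i - 1L, j, k] + eps$eps_x[i, j, k] +
           eps$eps_y[i, j - 1L, k] + eps$eps_y[i, j, k] +
           eps$eps_z[i, j, k - 1L] + eps$eps_z[i, j, k]) / 6
    pen <- ionsite::ion_constants()$coulomb_kcal /
      (2 * ion$effective_radius) * ion$valence^2 * (1 / ea - 1 / eps_w)
    en[r] <- ion$valence * map$phi[i, j, k] * kT + desolv_weight * pen
  }
  neg <- which(en < 0)
  ord <- neg[order(en[neg], nodes[neg, 1], nodes[neg, 2], nodes[neg, 3])]

  accepted <- matrix(numeric(0), ncol = 3)
  ranks <- integer(0)
  for (r in ord) {
    p <- g$origin + nodes[r, ] * g$h
    d <- sqrt((s$atoms$x - p[1])^2 + (s$atoms$y - p[2])^2 +
              (s$atoms$z - p[3])^2)
    if (any(d < ion$clash_radius + s$atoms$radius)) next
    if (nrow(accepted) > 0) {
      dd <- sqrt(rowSums(sweep(accepted, 2, p)^2))
      if (any(dd <= min_sep)) next
    }
    accepted <- rbind(accepted, p)
    ranks <- c(ranks, r)
    if (length(ranks) >= n_max) break
  }
  list(positions = accepted, energies = en[ranks], grid = g)
}

expect_same_sites <- function(pred, oracle, tol = 1e-9) {
  expect_equal(nrow(pred$sites), nrow(oracle$positions))
  if (nrow(pred$sites) > 0) {
    expect_equal(unname(as.matrix(pred$sites[, c("x", "y", "z")])),
                 unname(oracle$positions), tolerance = tol)
  }
}
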