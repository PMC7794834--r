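test_that("atom density has the Gaussian closed form", {
  s <- make_born_ion(1, 2)
  a <- s$atoms[1, ]
  expect_equal(atom_density(c(0, 0, 0), a, sigma = 0.93), 1)
  # at d = sigma * R the density is exactly e^-1
  expect_equal(atom_density(c(0.93 * 2, 0, 0), a, sigma = 0.93), exp(-1))
  expect_lt(atom_density(c(15, 0, 0), a, sigma = 0.93), 1e-12)
  # monotone decay along a ray
  d <- seq(0, 8, by = 0.25)
  vals <- atom_density(cbind(d, 0, 0), a, sigma = 0.93)
  expect_true(all(diff(vals) < 0))
})

test_that("cumulative density combines atoms by the complement product", {
  one <- make_born_ion(1, 2)
  p <- c(1.3, 0.4, -0.2)
  expect_equal(cumulative_density(p, one), atom_density(p, one$atoms[1, ]))

  # two coincident atoms with individual density 0.5 -> 1 - 0.25
  r <- 2; sig <- 0.93
  d_half <- sig * r * sqrt(log(2))        # g_i = 0.5 at this distance
  two <- read_pqr(c("ATOM 1 C FIX 1 0 0 0 0 2.0",
                    "ATOM 2 C FIX 1 0 0 0 0 2.0"))
  expect_equal(cumulative_density(c(d_half, 0, 0), two, sig), 0.75)

  # an atom whose density is 1 at p makes the cumulative density exactly 1
  mix <- read_pqr(c("ATOM 1 C FIX 1 0 0 0 0 2.0",
                    "ATOM 2 C FIX 1 5 0 0 0 2.0"))
  expect_identical(cumulative_density(c(5, 0, 0), mix, sig), 1)
})

test_that("adding atoms never decreases the cumulative density", {
  s_small <- make_random_cluster(n_atoms = 5, seed = 2)
  s_big <- make_random_cluster(n_atoms = 5, seed = 2)
  extra <- make_random_cluster(n_atoms = 3, seed = 9)$atoms
  s_big$atoms <- rbind(s_big$atoms, extra)
  set.seed(4)
  pts <- matrix(runif(60, -8, 8), ncol = 3)
  expect_true(all(cumulative_density(pts, s_big) >=
                  cumulative_density(pts, s_small) - 1e-15))
})

test_that("dielectric field is a convex blend bounded by its references", {
  s <- make_random_cluster(n_atoms = 8, seed = 6)
  g <- build_grid(s)
  eps <- dielectric_field(g, s, eps_in = 2, eps_w = 80)
  for (arr in list(eps$eps_x, eps$eps_y, eps$eps_z)) {
    expect_gte(min(arr), 2)
    expect_lte(max(arr), 80)
  }
})

test_that("dielectric equals eps_in at an atom centre and eps_w far away", {
  s <- make_born_ion(1, 2)
  g <- build_grid(s, perfil = 25)        # room for a far-field region
  eps <- dielectric_field(g, s, eps_in = 2, eps_w = 80)
  # atom sits on the central node
  ctr <- (g$n + 1) / 2
  expect_equal(eps$g_node[ctr, ctr, ctr], 1)
  node_eps <- eps$g_node * 2 + (1 - eps$g_node) * 80
  expect_equal(node_eps[ctr, ctr, ctr], 2, tolerance = 1e-6)
  # beyond 6 sigma R the field is bulk to 1e-6 * (eps_w - eps_in)
  far <- 6 * 0.93 * 2
  ax <- g$origin[1] + (0:(g$n - 1)) * g$h
  mx <- (ax[-1] + ax[-g$n]) / 2                 # x midpoints in row y=z=min
  dmid <- sqrt(mx^2 + ax[1]^2 + ax[1]^2)
  sel <- which(dmid > far)
  expect_gt(length(sel), 0)
  expect_lt(max(abs(eps$eps_x[sel, 1, 1] - 80)), 1e-6 * 78)
})

test_that("the dielectric transition is smooth, with no boundary jump", {
  s <- make_born_ion(1, 2)
  # fine sampling along a ray through the atom: adjacent differences shrink
  # with the step, as for a continuous function
  for (step in c(0.1, 0.05)) {
    d <- seq(0, 6, by = step)
    dens <- cumulative_density(cbind(d, 0, 0), s)
    epsv <- dens * 2 + (1 - dens) * 80
    expect_lt(max(abs(diff(epsv))), 80 * step)  # bounded increments
  }
})

test_that("averaged local dielectric is the mean of the six edge midpoints", {
  s <- make_born_ion(1, 2)
  g <- build_grid(s)
  eps <- dielectric_field(g, s, eps_in = 2, eps_w = 80)
  node <- c(2L, 3L, 4L)                    # 0-based interior node
  i <- node[1] + 1L; j <- node[2] + 1L; k <- node[3] + 1L
  manual <- mean(c(eps$eps_x[i - 1, j, k], eps$eps_x[i, j, k],
                   eps$eps_y[i, j - 1, k], eps$eps_y[i, j, k],
                   eps$eps_z[i, j, k - 1], eps$eps_z[i, j, k]))
  expect_equal(averaged_local_dielectric(eps, node), manual)
  # uniform field: the average is the field value
  u <- dielectric_field(g, s, eps_in = 80, eps_w = 80)
  expect_equal(averaged_local_dielectric(u, node), 80)
  # synthetic six-midpoint average: {2,2,2,80,80,80} -> 41
  expect_equal(mean(c(2, 2, 2, 80, 80, 80)), 41)
  expect_error(averaged_local_dielectric(eps, c(0L, 3L, 4L)), "interior")
})
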