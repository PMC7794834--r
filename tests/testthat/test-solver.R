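kT298 <- ion_constants()$boltzmann_kcal * 298.15

test_that("trilinear charge spreading conserves charge", {
  s <- make_born_ion(1, 2)
  g <- build_grid(s)
  q <- spread_charges(s, g)
  ctr <- (g$n + 1) / 2
  # atom exactly on the central node
  expect_equal(q[ctr, ctr, ctr], 1)
  expect_equal(sum(q), 1, tolerance = 1e-12)

  # atom at a cell centre: eight nodes get 1/8 each
  s2 <- s
  s2$atoms$x <- s2$atoms$x + g$h / 2
  s2$atoms$y <- s2$atoms$y + g$h / 2
  s2$atoms$z <- s2$atoms$z + g$h / 2
  q2 <- spread_charges(s2, g)
  expect_equal(sort(unique(round(as.vector(q2), 12))), c(0, 0.125))
  expect_equal(sum(q2 != 0), 8)

  # arbitrary positions: partition of unity
  s3 <- make_random_cluster(n_atoms = 9, seed = 8)
  g3 <- build_grid(s3)
  expect_equal(sum(spread_charges(s3, g3)), net_charge(s3),
               tolerance = 1e-12)
})

test_that("boundary potential has the screened-Coulomb closed form", {
  # zero charge -> all zero
  s0 <- make_born_ion(0, 2)
  g0 <- build_grid(s0)
  expect_true(all(boundary_potential(s0, g0) == 0))

  # +1 e, no salt: face-centre boundary node at 10 A reads
  # 332.0636/(80*10) kcal/mol -> /kT = 0.7006 kT/e
  s <- make_born_ion(1, 2)
  g <- build_grid(s, scale = 2, perfil = 20)     # side 20 A, half-width 10
  expect_equal(g$side, 20)
  cfg0 <- solver_config(salt = 0)
  phi <- boundary_potential(s, g, cfg0)
  ctr <- (g$n + 1) / 2
  expect_equal(phi[1, ctr, ctr], 332.0636 / (80 * 10) / kT298,
               tolerance = 1e-4)

  # 0.5 M salt: Debye length ~4.34 A from first principles
  cfg5 <- solver_config(salt = 0.5)
  kap <- ionsite:::debye_kappa(cfg5, 80)
  expect_equal(1 / kap, 4.343, tolerance = 0.01)
  phi5 <- boundary_potential(s, g, cfg5)
  expect_equal(phi5[1, ctr, ctr], phi[1, ctr, ctr] * exp(-kap * 10),
               tolerance = 1e-9)
})

test_that("ion accessibility is the Boltzmann weight of the penalty", {
  expect_equal(ion_accessibility(0), 1)
  expect_equal(ion_accessibility(kT298 * log(2)), 0.5)
  expect_lt(ion_accessibility(40, temperature = 298), 1e-29)
  expect_error(ion_accessibility(-1), "non-negative")
})

test_that("zero-charge structure yields an identically zero potential", {
  s <- make_born_ion(0, 2)
  g <- build_grid(s)
  eps <- dielectric_field(g, s)
  m <- solve_pbe(s, g, eps, solver_config(salt = 0.5))
  expect_true(all(m$phi == 0))
  expect_true(m$converged)
})

test_that("solver reproduces the Coulomb and Debye-Hueckel limits", {
  s <- make_born_ion(1, 2)
  g <- build_grid(s, scale = 2, perfil = 25)     # 33^3
  eps <- dielectric_field(g, s, eps_in = 80, eps_w = 80)
  ax <- g$origin[1] + (0:(g$n - 1)) * g$h
  idx <- as.matrix(expand.grid(1:g$n, 1:g$n, 1:g$n))
  r <- sqrt(ax[idx[, 1]]^2 + ax[idx[, 2]]^2 + ax[idx[, 3]]^2)
  shell <- r >= 5 & r <= 0.8 * (g$n - 1) / 2 * g$h

  m0 <- solve_pbe(s, g, eps, solver_config(salt = 0))
  coulomb <- 332.063713 / (80 * r[shell]) / kT298
  expect_lt(max(abs(m0$phi[idx[shell, ]] - coulomb) / coulomb), 0.05)

  cfg5 <- solver_config(salt = 0.5)
  m5 <- solve_pbe(s, g, eps, cfg5)
  kap <- ionsite:::debye_kappa(cfg5, 80)
  dh <- coulomb * exp(-kap * r[shell])
  expect_lt(max(abs(m5$phi[idx[shell, ]] - dh) / dh), 0.10)
})

test_that("linear solutions superpose and are charge-antisymmetric", {
  mk2 <- function(q1, q2) read_pqr(c(
    sprintf("ATOM 1 C FIX 1 -2 0 0 %g 2.0", q1),
    sprintf("ATOM 2 C FIX 2 2 0.5 -1 %g 1.6", q2)))
  s12 <- mk2(1, -0.5)
  g <- build_grid(s12)
  eps <- dielectric_field(g, s12)
  cfg <- solver_config(salt = 0.5, tolerance = 1e-6)
  m12 <- solve_pbe(s12, g, eps, cfg)
  # superposition: same grid and dielectric, charges split
  solve_on <- function(q1, q2) {
    sq <- mk2(q1, q2)
    solve_pbe(sq, g, eps, cfg)$phi
  }
  expect_lt(max(abs(m12$phi - (solve_on(1, 0) + solve_on(0, -0.5)))), 1e-3)
  # sign antisymmetry
  expect_lt(max(abs(solve_on(-1, 0.5) + m12$phi)), 1e-12)
})

test_that("sweep updates decay and refinement improves the Coulomb limit", {
  s <- make_born_ion(1, 2)
  errs <- sapply(c(1, 2), function(sc) {
    g <- build_grid(s, scale = sc, perfil = 25)
    eps <- dielectric_field(g, s, eps_in = 80, eps_w = 80)
    m <- solve_pbe(s, g, eps, solver_config(salt = 0))
    ax <- g$origin[1] + (0:(g$n - 1)) * g$h
    idx <- as.matrix(expand.grid(1:g$n, 1:g$n, 1:g$n))
    r <- sqrt(ax[idx[, 1]]^2 + ax[idx[, 2]]^2 + ax[idx[, 3]]^2)
    shell <- r >= 5 & r <= 0.8 * (g$n - 1) / 2 * g$h
    coulomb <- 332.063713 / (80 * r[shell]) / kT298
    # convergence history decays overall
    h <- m$history
    expect_lt(h[length(h)], h[1])
    max(abs(m$phi[idx[shell, ]] - coulomb) / coulomb)
  })
  expect_lt(errs[2], errs[1])
})

test_that("nonlinear mode agrees with linear mode for weak potentials", {
  s <- make_born_ion(0.05, 2)
  g <- build_grid(s, perfil = 25)
  eps <- dielectric_field(g, s, eps_in = 80, eps_w = 80)
  ml <- solve_pbe(s, g, eps, solver_config(salt = 0.5, mode = "linear",
                                           tolerance = 1e-6))
  mn <- solve_pbe(s, g, eps, solver_config(salt = 0.5, mode = "nonlinear",
                                           tolerance = 1e-6))
  expect_true(mn$converged)
  sel <- abs(ml$phi) < 0.3
  expect_lt(max(abs(ml$phi[sel] - mn$phi[sel])), 0.01)
})

test_that("non-convergence is reported, never silent", {
  s <- make_born_ion(2, 2)
  g <- build_grid(s)
  eps <- dielectric_field(g, s)
  expect_warning(
    m <- solve_pbe(s, g, eps, solver_config(max_iterations = 3)),
    "did not converge")
  expect_false(m$converged)
  expect_equal(m$iterations, 3L)
})

test_that("electroneutral bulk is enforced", {
  expect_error(solver_config(valences = c(2, -1)), "electroneutral")
  expect_silent(solver_config(valences = c(2, -1, -1)))
})
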