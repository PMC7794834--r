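kT298 <- ion_constants()$boltzmann_kcal * 298.15

test_that("site energy combines interaction and desolvation terms", {
  cl <- ion_spec("CL1")
  ca <- ion_spec("CA2")
  expect_equal(site_energy(0, 80, cl), 0)
  # phi = -5 kT/e, z = +2, bulk dielectric: 2*(-5)*kT kcal/mol
  expect_equal(site_energy(-5, 80, ca), -10 * kT298, tolerance = 1e-9)
  expect_equal(site_energy(-5, 80, ca), -5.9249, tolerance = 1e-4)
  # phi = 0, eps 2: pure penalty, 4x the monovalent value
  expect_equal(site_energy(0, 2, ca), 161.881, tolerance = 1e-3)
})

test_that("candidate enumeration excludes the vdW interior (brute force)", {
  s <- make_born_ion(1, 2)
  g <- build_grid(s)                       # 13^3, h = 0.5
  cand <- enumerate_candidates(g, s)
  oracle <- oracle_candidates(g, s)
  expect_equal(cand[order(cand[, 1], cand[, 2], cand[, 3]), ],
               oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ])
  # hand count: interior nodes minus nodes with |r| <= 2 A
  pts <- grid_to_world(g, cand)
  expect_true(all(sqrt(rowSums(pts^2)) > 2))
  n_int <- (g$n - 2)^3
  ax <- g$origin[1] + (0:(g$n - 1)) * g$h
  inside <- sum(outer(outer(ax[2:12]^2, ax[2:12]^2, "+"), ax[2:12]^2, "+") <= 4)
  expect_equal(nrow(cand), n_int - inside)

  mult <- make_random_cluster(n_atoms = 7, seed = 4)
  gm <- build_grid(mult)
  cm <- enumerate_candidates(gm, mult)
  om <- oracle_candidates(gm, mult)
  expect_equal(nrow(cm), nrow(om))
})

test_that("heap ranking pops negative energies in full-sort order", {
  e <- c(-3, -1, -2, 5)
  nodes <- cbind(1:4, 1:4, 1:4)
  expect_equal(rank_sites(e, nodes), c(1L, 3L, 2L))
  expect_equal(rank_sites(c(1, 2, 3), nodes[1:3, ]), integer(0))

  set.seed(42)
  n <- 10000
  e <- c(rnorm(n), rnorm(50))              # includes positives and negatives
  nd <- cbind(sample.int(40, length(e), TRUE), sample.int(40, length(e), TRUE),
              sample.int(40, length(e), TRUE))
  got <- rank_sites(e, nd)
  neg <- which(e < 0)
  want <- neg[order(e[neg], nd[neg, 1], nd[neg, 2], nd[neg, 3])]
  expect_identical(got, want)
})

test_that("clash and proximity filters follow the printed inequalities", {
  s <- read_pqr("ATOM 1 C FIX 1 0 0 0 0.0 1.5")
  ion <- ion_spec("CA2")                   # clash radius 2.0
  expect_false(passes_clash(c(3.0, 0, 0), s, ion))   # 3.0 < 3.5
  expect_true(passes_clash(c(3.5, 0, 0), s, ion))    # boundary passes
  expect_true(passes_clash(c(50, 0, 0), s, ion))

  expect_true(passes_proximity(c(0, 0, 0), matrix(numeric(0), ncol = 3)))
  expect_false(passes_proximity(c(0, 0, 0), rbind(c(5.9, 0, 0))))
  expect_true(passes_proximity(c(0, 0, 0), rbind(c(6.01, 0, 0),
                                                 c(0, 20, 0))))
})

test_that("uncharged solute yields an empty prediction", {
  s <- make_born_ion(0, 2)
  p <- predict_ion_sites(s, "CL1")
  expect_equal(nrow(p$sites), 0L)
  p0 <- make_charged_patch(patch_charge = 0)$structure
  expect_equal(nrow(predict_ion_sites(p0, "CL1")$sites), 0L)
})

test_that("prediction matches the exhaustive-scan oracle", {
  fixtures <- list(
    list(s = make_born_ion(3, 2), ion = "CL1"),
    list(s = make_charged_patch(patch_charge = 3, seed = 2)$structure,
         ion = "CL1"),
    list(s = make_random_cluster(n_atoms = 10, seed = 3, ball_radius = 3),
         ion = "CA2")
  )
  for (fx in fixtures) {
    pred <- predict_ion_sites(fx$s, fx$ion, n_max = 8)
    orc <- oracle_predict(fx$s, fx$ion, n_max = 8)
    expect_same_sites(pred, orc)
    expect_lte(pred$grid$n, 33)
  }
})

test_that("counter-ion rank-1 sits in the first allowed shell", {
  s <- make_born_ion(3, 2)
  p <- predict_ion_sites(s, "CL1", n_max = 5)
  expect_gt(nrow(p$sites), 0)
  d1 <- sqrt(sum(unlist(p$sites[1, c("x", "y", "z")])^2))
  standoff <- 2 + 2                         # R_ion + R_atom
  expect_gte(d1, standoff)
  expect_lte(d1, standoff + sqrt(3) * p$grid$h)
})

test_that("like-charged ion finds no site near an isolated charge", {
  s <- make_born_ion(3, 2)
  p <- predict_ion_sites(s, "CA2", n_max = 5)
  if (nrow(p$sites) > 0) {
    d <- sqrt(p$sites$x^2 + p$sites$y^2 + p$sites$z^2)
    expect_true(all(d > 10))
  } else {
    expect_equal(nrow(p$sites), 0L)
  }
})

test_that("outputs respect ordering, clash and separation invariants", {
  for (fx in list(list(s = make_born_ion(3, 2), ion = "CL1"),
                  list(s = make_charged_patch(patch_charge = 3)$structure,
                       ion = "CL1"),
                  list(s = make_random_cluster(n_atoms = 10, seed = 12),
                       ion = "MG2"))) {
    p <- predict_ion_sites(fx$s, fx$ion, n_max = 10)
    st <- p$sites
    if (nrow(st) == 0) next
    expect_true(all(st$energy < 0))
    expect_true(all(diff(st$energy) >= 0))
    expect_equal(st$rank, seq_len(nrow(st)))
    pos <- as.matrix(st[, c("x", "y", "z")])
    if (nrow(pos) > 1) {
      pd <- as.matrix(stats::dist(pos))
      expect_true(all(pd[upper.tri(pd)] > 6))
    }
    a <- p$structure$atoms
    for (i in seq_len(nrow(pos))) {
      d <- sqrt((a$x - pos[i, 1])^2 + (a$y - pos[i, 2])^2 +
                (a$z - pos[i, 3])^2)
      expect_true(all(d >= p$ion$clash_radius + a$radius))
    }
  }
})

test_that("site list is invariant under global charge conjugation", {
  s <- make_random_cluster(n_atoms = 10, seed = 21)
  s_neg <- s
  s_neg$atoms$charge <- -s$atoms$charge
  a <- predict_ion_sites(s, ion_spec("I1", valence = 1), n_max = 6)
  b <- predict_ion_sites(s_neg, ion_spec("I1", valence = -1), n_max = 6)
  expect_equal(a$sites$rank, b$sites$rank)
  expect_equal(as.matrix(a$sites[, c("x", "y", "z")]),
               as.matrix(b$sites[, c("x", "y", "z")]), tolerance = 1e-12)
  expect_equal(a$sites$energy, b$sites$energy, tolerance = 1e-9)
})

test_that("identical inputs give identical outputs", {
  s <- make_charged_patch(patch_charge = 2, seed = 5)$structure
  p1 <- predict_ion_sites(s, "CL1", n_max = 5)
  p2 <- predict_ion_sites(s, "CL1", n_max = 5)
  expect_identical(p1$sites, p2$sites)
})

test_that("n_max caps the number of reported sites", {
  s <- make_born_ion(4, 2)
  p <- predict_ion_sites(s, "CL1", n_max = 2)
  expect_lte(nrow(p$sites), 2)
  # neighbors are reported with distances
  if (nrow(p$sites) > 0) {
    nb <- p$neighbors[[1]]
    expect_true(all(c("serial", "distance") %in% names(nb)))
    expect_true(all(nb$distance <= p$ion$clash_radius + 2 + 2))
  }
})
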