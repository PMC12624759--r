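# MM terms, generalized Born polar solvation, MM/GBSA-style rescoring.

bead_topology <- function(n, charge = 0, gb_radius = 2, lj_sigma = 3,
                          lj_epsilon = 0.1) {
  topology_params(data.frame(
    serial = seq_len(n), charge = charge, gb_radius = gb_radius,
    lj_sigma = lj_sigma, lj_epsilon = lj_epsilon))
}

test_that("Coulomb and LJ terms reproduce their closed forms", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0))
  top <- bead_topology(2, charge = 1, lj_epsilon = 0)
  e <- coulomb_lj_energy(coords, top)
  expect_equal(e$E_coulomb, 332.0637, tolerance = 1e-9)
  expect_equal(e$E_lj, 0)

  # LJ minimum at 2^(1/6) sigma is exactly -epsilon
  sig <- 3.2; eps <- 0.25
  top2 <- topology_params(data.frame(serial = 1:2, charge = 0, gb_radius = 2,
                                     lj_sigma = sig, lj_epsilon = eps))
  e2 <- coulomb_lj_energy(rbind(c(0, 0, 0), c(2^(1 / 6) * sig, 0, 0)), top2)
  expect_equal(e2$E_lj, -eps, tolerance = 1e-12)

  expect_error(coulomb_lj_energy(rbind(c(0, 0, 0), c(0, 0, 0)), top),
               "singularity")
})

test_that("pair energies match an independent double-loop oracle", {
  set.seed(19)
  n <- 10
  coords <- matrix(rnorm(n * 3, sd = 4), n)
  top <- topology_params(data.frame(
    serial = 1:n, charge = runif(n, -1, 1), gb_radius = runif(n, 1.2, 2),
    lj_sigma = runif(n, 2.5, 3.5), lj_epsilon = runif(n, 0.05, 0.3)))
  e <- coulomb_lj_energy(coords, top)
  a <- top$atoms
  ec <- 0; elj <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    ec <- ec + 332.0637 * a$charge[i] * a$charge[j] / r
    sij <- (a$lj_sigma[i] + a$lj_sigma[j]) / 2
    eij <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    elj <- elj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  expect_equal(e$E_coulomb, ec, tolerance = 1e-9)
  expect_equal(e$E_lj, elj, tolerance = 1e-9)
})

test_that("GB reduces to the Born closed form and the distant-ion asymptote", {
  top <- bead_topology(1, charge = 1, gb_radius = 2)
  g <- gb_polar(matrix(0, 1, 3), top)
  expect_equal(g$G_gb, -166.0319 * (1 - 1 / 78.5) / 2, tolerance = 1e-6)
  expect_equal(g$effective_radii, 2, tolerance = 1e-9)

  # q = 0 everywhere gives exactly zero
  g0 <- gb_polar(matrix(rnorm(9), 3), bead_topology(3, charge = 0))
  expect_equal(g0$G_gb, 0)

  # two ions 1000 A apart: Born self terms plus screened cross term
  top2 <- bead_topology(2, charge = 1, gb_radius = 2)
  g2 <- gb_polar(rbind(c(0, 0, 0), c(1000, 0, 0)), top2)
  pref <- -166.0319 * (1 - 1 / 78.5)
  closed <- pref * (1 / 2 + 1 / 2 + 2 / 1000)
  expect_equal(g2$G_gb, closed, tolerance = 1e-4)
})

test_that("every energy term is invariant under rigid motion", {
  es <- gen_energy_system(seed = 2, jitter = 0.1)
  coords <- get_coords(es$strong)
  e0 <- gbsa_frame(coords, es$topology, es$receptor_idx, es$ligand_idx, es$strong)
  th <- 0.9
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- sweep(coords %*% rot, 2, c(7, -3, 11), `+`)
  e1 <- gbsa_frame(moved, es$topology, es$receptor_idx, es$ligand_idx,
                   set_coords(es$strong, moved))
  for (term in c("E_coulomb", "E_lj", "G_gb", "G_np", "G_total")) {
    expect_equal(e1[[term]], e0[[term]], tolerance = 1e-6)
  }
  # decomposition closes
  expect_equal(e0$G_total, e0$E_coulomb + e0$E_lj + e0$G_gb + e0$G_np,
               tolerance = 1e-9)
})

test_that("the non-interacting limit gives dG near zero", {
  es <- gen_energy_system(seed = 3)
  coords <- get_coords(es$strong)
  coords[es$ligand_idx, ] <- sweep(coords[es$ligand_idx, , drop = FALSE], 2,
                                   c(500, 0, 0), `+`)
  e <- gbsa_frame(coords, es$topology, es$receptor_idx, es$ligand_idx)
  expect_lt(abs(e$G_total), 0.1)
})

test_that("partition errors are caught", {
  es <- gen_energy_system(seed = 1)
  coords <- get_coords(es$strong)
  expect_error(gbsa_frame(coords, es$topology, es$receptor_idx,
                          c(es$receptor_idx[1], es$ligand_idx)), "overlap")
  expect_error(gbsa_frame(coords, es$topology, es$receptor_idx,
                          es$ligand_idx[-1]), "cover")
})

test_that("the planted strong binder outranks the decoy and inverts with charge sign", {
  es <- gen_energy_system(seed = 4, jitter = 0.1)
  gs <- gbsa_frame(get_coords(es$strong), es$topology, es$receptor_idx,
                   es$ligand_idx, es$strong)
  gd <- gbsa_frame(get_coords(es$decoy), es$topology, es$receptor_idx,
                   es$ligand_idx, es$decoy)
  expect_lt(gs$G_total, gd$G_total)

  flipped <- gen_energy_system(seed = 4, jitter = 0.1, guest_charge = -0.5)
  fs <- gbsa_frame(get_coords(flipped$strong), flipped$topology,
                   flipped$receptor_idx, flipped$ligand_idx, flipped$strong)
  fd <- gbsa_frame(get_coords(flipped$decoy), flipped$topology,
                   flipped$receptor_idx, flipped$ligand_idx, flipped$decoy)
  expect_gt(fs$G_total, fd$G_total)

  # identical poses give ddG = 0 exactly
  gs2 <- gbsa_frame(get_coords(es$strong), es$topology, es$receptor_idx,
                    es$ligand_idx, es$strong)
  expect_equal(gs2$G_total - gs$G_total, 0)
})

test_that("trajectory averaging reports frame means with SEM over frames", {
  es <- gen_energy_system(seed = 5)
  coords <- get_coords(es$strong)
  # constant-energy synthetic frames: SEM = 0
  tr <- mol_trajectory(es$strong, rep(list(coords), 3))
  out <- gbsa_trajectory(tr, es$topology, es$receptor_idx, es$ligand_idx)
  expect_equal(out$sem, 0)

  # planted per-frame energies via ligand displacement produce the plain
  # mean/SEM arithmetic: check against the per-frame table directly
  shift <- function(d) {
    f <- coords
    f[es$ligand_idx, ] <- sweep(f[es$ligand_idx, , drop = FALSE], 2, c(d, 0, 0), `+`)
    f
  }
  tr2 <- mol_trajectory(es$strong, list(shift(0), shift(0.3), shift(0.6)))
  out2 <- gbsa_trajectory(tr2, es$topology, es$receptor_idx, es$ligand_idx)
  expect_equal(out2$mean$G_total, mean(out2$per_frame$G_total), tolerance = 1e-12)
  expect_equal(out2$sem, sd(out2$per_frame$G_total) / sqrt(3), tolerance = 1e-12)
})
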