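# Trajectory statistics: ligand RMSD, interface RMSD, RMSF, bound fraction,
# contacts, occupancy, average structures.

static_traj <- function(n_frames = 5, n_res = 20) {
  topo <- make_long_chain(n_res)
  mol_trajectory(topo, rep(list(get_coords(topo)), n_frames))
}

test_that("ligand RMSD series: static, analytic shift, and two-step oracle", {
  g <- gen_binding_trajectory(n_frames = 30, bound_mask = rep(TRUE, 30),
                              noise_sigma = 0.05, seed = 5)
  traj <- g$trajectory
  rec_ca <- select_atoms(traj, "chain A and name CA")
  lig <- select_atoms(traj, "chain B and heavy")

  stat <- static_traj()
  fit <- select_atoms(stat, "name CA")
  expect_equal(ligand_rmsd_series(stat, fit, select_atoms(stat, "resid 18-20")),
               rep(0, 5))

  # rigid 5 A ligand shift with a frozen receptor
  base <- frame_coords(traj, 1)
  shifted <- base
  shifted[lig$indices, ] <- sweep(shifted[lig$indices, , drop = FALSE], 2,
                                  c(0, 3, 4), `+`)
  two <- mol_trajectory(traj$topology, list(base, shifted))
  series <- ligand_rmsd_series(two, rec_ca, lig)
  expect_equal(series, c(0, 5), tolerance = 1e-9)

  # independent two-step oracle (unweighted fit, then no-fit RMSD)
  series_full <- ligand_rmsd_series(traj, rec_ca, lig, mass_weighted_fit = FALSE)
  oracle <- vapply(seq_len(n_frames(traj)), function(k) {
    f <- superpose(frame_coords(traj, k), base, rec_ca$indices)
    sqrt(mean(rowSums((f$coords[lig$indices, ] - base[lig$indices, ])^2)))
  }, numeric(1))
  expect_equal(series_full, oracle, tolerance = 1e-6)
  expect_equal(series_full[1], 0, tolerance = 1e-9)
})

test_that("ligand RMSD is invariant to a global rigid motion of all frames", {
  g <- gen_binding_trajectory(n_frames = 12, bound_mask = rep(c(TRUE, FALSE), 6),
                              seed = 3)
  traj <- g$trajectory
  rec_ca <- select_atoms(traj, "chain A and name CA")
  lig <- select_atoms(traj, "chain B and heavy")
  s0 <- ligand_rmsd_series(traj, rec_ca, lig)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- mol_trajectory(traj$topology, lapply(traj$frames, function(f) {
    sweep(f %*% rot, 2, c(10, -5, 2), `+`)
  }))
  expect_equal(ligand_rmsd_series(moved, rec_ca, lig), s0, tolerance = 1e-6)
})

test_that("interface RMSD: identity, displacement, perturbation statistics", {
  g <- gen_binding_trajectory(n_frames = 2, bound_mask = c(TRUE, TRUE), seed = 2)
  ref <- g$reference
  na <- n_atoms(ref)
  pep <- g$peptide_selection
  rec <- setdiff(seq_len(na), pep)

  expect_equal(interface_rmsd(ref, ref, rec, pep)$irmsd, 0, tolerance = 1e-9)

  far <- get_coords(ref)
  far[pep, ] <- sweep(far[pep, , drop = FALSE], 2, c(50, 0, 0), `+`)
  disp <- interface_rmsd(far, ref, rec, pep)
  expect_gt(disp$irmsd, 10)
  expect_true(disp$unbound_like)

  # empty interface reported as undefined, not zero
  apart <- set_coords(ref, far)
  empty <- interface_rmsd(get_coords(apart), apart, rec, pep, interface_radius = 10)
  expect_false(empty$defined)
  expect_true(is.na(empty$irmsd))

  # sigma-perturbation: mean I-RMSD ~ sqrt(3) sigma over replicates
  set.seed(77)
  sigma <- 0.3
  vals <- vapply(1:100, function(i) {
    pert <- get_coords(ref) + matrix(rnorm(3 * na, 0, sigma), na)
    interface_rmsd(pert, ref, rec, pep)$irmsd
  }, numeric(1))
  # fitting absorbs some variance; agreement within 20%
  expect_lt(abs(mean(vals) - sqrt(3) * sigma) / (sqrt(3) * sigma), 0.2)
})

test_that("RMSF: zeros for static input, analytic two-point case, stiff vs floppy", {
  expect_true(all(rmsf(static_traj())$rmsf == 0))

  topo <- make_long_chain(5)
  base <- get_coords(topo)
  up <- base; up[1, 1] <- up[1, 1] + 1
  dn <- base; dn[1, 1] <- dn[1, 1] - 1
  tr <- mol_trajectory(topo, list(up, dn))
  per_atom <- attr(rmsf(tr, align_selection = 5:20), "per_atom")
  expect_equal(per_atom$rmsf[per_atom$index == 1], 1.0, tolerance = 1e-9)

  # planted floppy loop fluctuates more than a stiff one
  set.seed(4)
  floppy_res <- 1:5; stiff_res <- 11:15
  topo2 <- make_long_chain(20)
  floppy_idx <- select_atoms(topo2, "resid 1-5")$indices
  frames <- lapply(1:30, function(i) {
    f <- get_coords(topo2)
    f[floppy_idx, ] <- f[floppy_idx, ] + matrix(rnorm(length(floppy_idx) * 3, 0, 1.0),
                                                length(floppy_idx))
    f + matrix(rnorm(length(f), 0, 0.05), nrow(f))
  })
  tr2 <- mol_trajectory(topo2, frames)
  r <- rmsf(tr2, align_selection = select_atoms(topo2, "resid 6-20 and name CA"))
  res_id <- as.integer(sub("^A:", "", r$residue))
  expect_gt(mean(r$rmsf[res_id %in% floppy_res]), mean(r$rmsf[res_id %in% stiff_res]))

  expect_error(rmsf(mol_trajectory(topo, list(base))), "single frame")
})

test_that("bound fraction recovers the planted mask exactly and respects the boundary", {
  mask <- rep(c(TRUE, FALSE), c(60, 40))
  g <- gen_binding_trajectory(n_frames = 100, bound_mask = mask, seed = 9)
  site <- binding_site_from_residues(g$reference, g$manifest$planted_truth$site_residues)
  bf <- bound_fraction(g$trajectory, site, g$peptide_selection)
  expect_equal(bf$fraction, 0.6)
  expect_identical(bf$bound, mask)

  # boundary: distances of exactly 5.9 / 6.1 A
  topo <- g$reference
  pep <- g$peptide_selection
  a <- topo$atoms
  pw <- atomic_mass(a$element[pep])
  base <- get_coords(topo)
  scom <- colMeans(base[site$com_indices, , drop = FALSE])
  pcom <- colSums(base[pep, , drop = FALSE] * pw) / sum(pw)
  dirv <- (pcom - scom) / sqrt(sum((pcom - scom)^2))
  place <- function(dist) {
    f <- base
    f[pep, ] <- sweep(f[pep, , drop = FALSE], 2, scom + dirv * dist - pcom, `+`)
    f
  }
  tr59 <- mol_trajectory(topo, list(place(5.9), place(5.9)))
  tr61 <- mol_trajectory(topo, list(place(6.1), place(6.1)))
  expect_equal(bound_fraction(tr59, site, pep)$fraction, 1.0)
  expect_equal(bound_fraction(tr61, site, pep)$fraction, 0.0)

  # distance series equals the explicit COM arithmetic
  manual <- vapply(seq_len(n_frames(g$trajectory)), function(k) {
    f <- frame_coords(g$trajectory, k)
    p <- colSums(f[pep, , drop = FALSE] * pw) / sum(pw)
    s <- colMeans(f[site$com_indices, , drop = FALSE])
    sqrt(sum((p - s)^2))
  }, numeric(1))
  expect_equal(bf$distance, manual, tolerance = 1e-12)
})

test_that("bound fraction is recovered across planted fractions and seeds", {
  for (frac in c(0.1, 0.5, 0.9)) {
    for (seed in c(1, 7)) {
      n <- 50
      mask <- seq_len(n) <= round(frac * n)
      g <- gen_binding_trajectory(n_frames = n, bound_mask = mask, seed = seed)
      site <- binding_site_from_residues(g$reference,
                                         g$manifest$planted_truth$site_residues)
      expect_equal(bound_fraction(g$trajectory, site, g$peptide_selection)$fraction,
                   mean(mask))
    }
  }
})

test_that("contact frequencies recover planted contacts and apply the 25% rule", {
  mask <- rep(c(TRUE, FALSE), c(30, 20))
  g <- gen_binding_trajectory(n_frames = 50, bound_mask = mask, seed = 13)
  rec <- setdiff(seq_len(n_atoms(g$trajectory)), g$peptide_selection)
  cf <- contact_frequencies(g$trajectory, rec, g$peptide_selection)
  planted <- g$manifest$planted_truth$contacts
  for (k in seq_len(nrow(planted))) {
    row <- cf$full[cf$full$res_a == planted$res_a[k] &
                     cf$full$res_b == planted$res_b[k] &
                     cf$full$kind == planted$kind[k], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$frequency, planted$frequency[k])
  }
  # 60% contacts retained; a 20%-frequency construction is dropped
  mask20 <- rep(c(TRUE, FALSE), c(10, 40))
  g20 <- gen_binding_trajectory(n_frames = 50, bound_mask = mask20, seed = 13)
  cf20 <- contact_frequencies(g20$trajectory,
                              setdiff(seq_len(n_atoms(g20$trajectory)),
                                      g20$peptide_selection),
                              g20$peptide_selection)
  sb20 <- cf20$full[cf20$full$kind == "salt_bridge", ]
  expect_equal(sb20$frequency, 0.2)
  expect_false(any(cf20$filtered$kind == "salt_bridge"))
  # filtered is a subset of full with frequencies above the cutoff
  expect_true(all(cf$filtered$frequency > 0.25))
  expect_lte(nrow(cf$filtered), nrow(cf$full))
})

test_that("a static Arg-Glu pair at 3.2 A is a persistent salt bridge", {
  atoms <- data.frame(
    serial = 1:4,
    name = c("CA", "NH1", "CA", "OE1"),
    element = c("C", "N", "C", "O"),
    resname = c("ARG", "ARG", "GLU", "GLU"),
    resid = c(1, 1, 2, 2), chain = c("A", "A", "B", "B"),
    x = c(0, 1.0, 5.0, 4.2), y = 0, z = 0, stringsAsFactors = FALSE)
  st <- mol_structure(atoms)
  tr <- mol_trajectory(st, rep(list(get_coords(st)), 4))
  cf <- contact_frequencies(tr, 1:2, 3:4)
  sb <- cf$full[cf$full$kind == "salt_bridge", ]
  expect_equal(nrow(sb), 1)
  expect_equal(sb$frequency, 1.0)
})

test_that("occupancy grids conserve counts", {
  topo <- make_long_chain(3)
  base <- get_coords(topo)
  # static atom: one voxel holds everything
  tr <- mol_trajectory(topo, rep(list(base), 7))
  g <- occupancy_grid(tr, selection = 1, spacing = 0.5)
  expect_equal(max(g$counts), 7)
  expect_equal(sum(g$counts), 7)
  # two-frame atom at two sites
  b2 <- base; b2[1, ] <- b2[1, ] + c(3, 0, 0)
  tr2 <- mol_trajectory(topo, list(base, b2))
  g2 <- occupancy_grid(tr2, selection = 1, spacing = 0.5)
  expect_equal(sort(g2$counts[g2$counts > 0]), c(1, 1))
  # conservation on random input
  set.seed(6)
  frames <- lapply(1:9, function(i) base + matrix(rnorm(length(base), 0, 2), nrow(base)))
  g3 <- occupancy_grid(mol_trajectory(topo, frames), spacing = 0.5)
  expect_equal(sum(g3$counts), 9 * nrow(base))
})

test_that("average structures follow the per-coordinate mean after fitting", {
  stat <- static_traj(4)
  expect_equal(get_coords(average_structure(stat)), frame_coords(stat, 1))

  topo <- make_long_chain(4)
  base <- get_coords(topo)
  up <- base; up[2, 1] <- up[2, 1] + 1
  dn <- base; dn[2, 1] <- dn[2, 1] - 1
  avg <- average_structure(mol_trajectory(topo, list(up, dn)),
                           fit_selection = 5:16)
  expect_equal(get_coords(avg)[2, 1], base[2, 1], tolerance = 1e-9)

  # random trajectory: equals the mean of fitted frames computed directly
  set.seed(12)
  frames <- lapply(1:5, function(i) base + matrix(rnorm(length(base), 0, 0.3), nrow(base)))
  tr <- mol_trajectory(topo, frames)
  fitsel <- seq_len(nrow(base))
  w <- atomic_mass(topo$atoms$element)
  fitted <- lapply(frames, function(f) superpose(f, frames[[1]], fitsel, weights = w)$coords)
  expect_equal(get_coords(average_structure(tr, fitsel)),
               Reduce(`+`, fitted) / 5, tolerance = 1e-9)
})
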