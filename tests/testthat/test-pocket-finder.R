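# Grid construction, buriedness scan, morphology, pocket labeling/ranking.

single_atom_structure <- function() {
  mol_structure(data.frame(serial = 1, name = "C", element = "C",
                           resname = "DUM", resid = 1, chain = "A",
                           x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
}

test_that("grid occupancy matches a brute-force distance scan", {
  st <- single_atom_structure()
  g <- build_grid(st, spacing = 1.0, probe_radius = 1.2)
  # brute force: voxel centers within 2.9 A of the atom
  centers <- as.matrix(expand.grid(
    x = g$origin[1] + (seq_len(g$dims[1]) - 1) * g$spacing,
    y = g$origin[2] + (seq_len(g$dims[2]) - 1) * g$spacing,
    z = g$origin[3] + (seq_len(g$dims[3]) - 1) * g$spacing))
  brute <- sum(rowSums(centers^2) <= 2.9^2)
  expect_equal(sum(g$state == 1L), brute)
  # distant space stays candidate
  expect_equal(g$state[1, 1, 1], 0L)
  expect_error(build_grid(st, spacing = 0), "spacing")

  # halving the spacing scales the protein voxel count by ~8
  g2 <- build_grid(st, spacing = 0.5, probe_radius = 1.2)
  expect_equal(sum(g2$state == 1L) / sum(g$state == 1L), 8, tolerance = 0.15)
})

test_that("buriedness is maximal inside the planted cavity and zero far outside", {
  cav <- gen_cavity_protein(sphere_radius = 4, seed = 1)
  g <- buriedness_scan(build_grid(cav$structure), n_rays = 14)
  ctr <- round((c(0, 0, 0) - g$origin) / g$spacing) + 1
  expect_equal(g$buriedness[ctr[1], ctr[2], ctr[3]], 14)
  expect_equal(g$buriedness[1, 1, 1], 0)
})

test_that("buriedness equals brute-force ray casting on a hemispherical dimple", {
  # slab with a dimple: lattice of atoms minus a half-ball at the top face
  gpts <- as.matrix(expand.grid(x = seq(-8, 8, 1.5), y = seq(-8, 8, 1.5),
                                z = seq(-6, 0, 1.5)))
  dimple_center <- c(0, 0, 0)
  keep <- sqrt(rowSums(sweep(gpts, 2, dimple_center)^2)) > 3.5
  slab <- mol_structure(data.frame(
    serial = seq_len(sum(keep)), name = "C", element = "C", resname = "DUM",
    resid = seq_len(sum(keep)), chain = "A",
    x = gpts[keep, 1], y = gpts[keep, 2], z = gpts[keep, 3]))
  g <- buriedness_scan(build_grid(slab), n_rays = 14, max_range = 10, threshold = 0)
  protein <- g$state == 1L
  dirs <- rbind(diag(3), -diag(3), as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))))
  # brute-force count at a probe voxel just inside the dimple
  probe <- round((c(0, 0, -1) - g$origin) / g$spacing) + 1
  brute <- 0
  for (k in seq_len(nrow(dirs))) {
    step_len <- sqrt(sum(dirs[k, ]^2))
    hit <- FALSE
    for (s in seq_len(floor(10 / step_len))) {
      v <- probe + s * dirs[k, ]
      if (any(v < 1) || any(v > g$dims)) break
      if (protein[v[1], v[2], v[3]]) { hit <- TRUE; break }
    }
    brute <- brute + hit
  }
  expect_equal(g$buriedness[probe[1], probe[2], probe[3]], brute)
})

test_that("morphological cleanup matches the brute-force oracle and is identity at 0 steps", {
  cav <- gen_cavity_protein(sphere_radius = 3, seed = 3)
  g <- buriedness_scan(build_grid(cav$structure))
  mask0 <- g$state == 0L
  g_id <- morph_clean(g, erode_steps = 0, dilate_steps = 0)
  expect_identical(g_id$state, g$state)

  g1 <- morph_clean(g, 1, 1)
  oracle <- oracle_dilate(oracle_erode(mask0)) & g$state != 1L
  expect_identical(g1$state == 0L, oracle)

  # an isolated voxel is destroyed by one erosion
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  expect_false(any(oracle_erode(m)))

  # a solid 5^3 block mostly survives an opening, which never grows it
  blk <- array(FALSE, c(9, 9, 9)); blk[3:7, 3:7, 3:7] <- TRUE
  opened <- oracle_dilate(oracle_erode(blk))
  expect_true(all(blk[opened]))
  # the cross-shaped element shaves edges and corners only: 81 of 125 voxels
  expect_gt(sum(opened), 0.6 * sum(blk))
})

test_that("planted cavities are recovered with voxel volumes near truth", {
  cav <- gen_cavity_protein(sphere_radius = 4, seed = 1)
  pockets <- find_pockets(cav$structure)
  expect_equal(length(pockets), 1)
  ideal <- cav$manifest$planted_truth$cavity_volume
  expect_lt(abs(pockets[[1]]$volume - ideal) / ideal, 0.10)
  expect_lt(sqrt(sum((pockets[[1]]$centroid - cav$manifest$planted_truth$cavity_center)^2)), 1.5)

  # flood-fill oracle on the emitted shell agrees with the reported volume
  g <- build_grid(cav$structure)
  ctr <- round((c(0, 0, 0) - g$origin) / g$spacing) + 1
  oracle_vol <- oracle_flood_count(g$state != 1L, ctr)
  expect_lt(abs(oracle_vol - ideal) / ideal, 0.10)

  # convex control: no pockets
  expect_equal(length(find_pockets(gen_solid_protein(radius = 8))), 0)
})

test_that("volume conservation and translation invariance hold", {
  cav <- gen_cavity_protein(sphere_radius = 4, seed = 2)
  g <- morph_clean(buriedness_scan(build_grid(cav$structure)))
  pockets <- label_pockets(g, cav$structure)
  expect_lte(sum(vapply(pockets, function(p) p$volume, 0)),
             sum(g$state == 0L) * g$spacing^3)

  shifted <- set_coords(cav$structure, sweep(get_coords(cav$structure), 2,
                                             c(13.7, -4.2, 8.9), `+`))
  p0 <- find_pockets(cav$structure)
  p1 <- find_pockets(shifted)
  expect_equal(length(p1), length(p0))
  expect_equal(p1[[1]]$volume, p0[[1]]$volume, tolerance = 0.1)
})

test_that("planted-sphere volume error shrinks as the grid is refined", {
  cav <- gen_cavity_protein(sphere_radius = 4, seed = 1)
  ideal <- cav$manifest$planted_truth$cavity_volume
  errs <- vapply(c(2.0, 1.0, 0.5), function(sp) {
    p <- find_pockets(cav$structure, spacing = sp, min_volume = 20)
    if (length(p) == 0) return(Inf)
    abs(p[[1]]$volume - ideal) / ideal
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("hydrophobic ranking scores lining residue classes", {
  cav <- gen_cavity_protein(sphere_radius = 4, seed = 1)
  g <- morph_clean(buriedness_scan(build_grid(cav$structure)))
  pockets <- label_pockets(g, cav$structure)
  # relabel lining residues to a known composition: 3 of 10 hydrophobic
  pockets[[1]]$lining_residues <- c(paste0("A:", 1:3, ":LEU"),
                                    paste0("A:", 4:10, ":ASP"))
  ranked <- rank_pockets(pockets)
  expect_equal(ranked[[1]]$hydrophobic_score, 0.3)
  pockets[[1]]$lining_residues <- paste0("A:", 1:5, ":LEU")
  expect_equal(rank_pockets(pockets)[[1]]$hydrophobic_score, 1.0)
  pockets[[1]]$lining_residues <- paste0("A:", 1:5, ":ASP")
  expect_equal(rank_pockets(pockets)[[1]]$hydrophobic_score, 0.0)
})
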