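# Structure/trajectory parsing, atom selection and rigid-body geometry.

test_that("PDB parsing reads coordinates and errors on malformed input", {
  line <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  s <- parse_structure(line)
  expect_equal(n_atoms(s), 1)
  expect_equal(as.vector(get_coords(s)), c(1, 2, 3))
  expect_equal(s$atoms$resname, "ALA")

  bad <- sub("   3.000", "   x.000", line)
  expect_error(parse_structure(c(line, bad)), "line 2")
  expect_error(parse_structure("HEADER only"), "empty input")
})

test_that("write/parse round-trips coordinates and identifiers", {
  fixtures <- list(
    parse_structure(make_tripeptide_pdb()),
    make_long_chain(20),
    random_structure(15, seed = 4)
  )
  for (s in fixtures) {
    s2 <- parse_structure(write_structure(s))
    expect_equal(get_coords(s2), get_coords(s), tolerance = 1e-3)
    expect_equal(s2$atoms$name, s$atoms$name)
    expect_equal(s2$atoms$resid, s$atoms$resid)
    expect_equal(s2$atoms$chain, s$atoms$chain)
  }
})

test_that("multi-MODEL trajectories parse with frame order and checks", {
  block <- make_tripeptide_pdb()
  txt <- c("MODEL     1", block, "ENDMDL", "MODEL     2", block, "ENDMDL")
  tr <- parse_trajectory(txt)
  expect_equal(n_frames(tr), 2)
  expect_equal(frame_coords(tr, 1), frame_coords(tr, 2))

  single <- parse_trajectory(block)
  expect_equal(n_frames(single), 1)

  ragged <- c("MODEL     1", block, "ENDMDL", "MODEL     2", block[-1], "ENDMDL")
  expect_error(parse_trajectory(ragged), "structural mismatch")
})

test_that("trajectory round-trips through multi-MODEL text", {
  topo <- parse_structure(make_tripeptide_pdb())
  set.seed(9)
  frames <- lapply(1:3, function(i) get_coords(topo) + matrix(rnorm(36, sd = 0.5), 12))
  tr <- mol_trajectory(topo, frames)
  tr2 <- parse_trajectory(write_structure(tr))
  expect_equal(n_frames(tr2), 3)
  for (i in 1:3) expect_equal(frame_coords(tr2, i), frame_coords(tr, i), tolerance = 1e-3)
})

test_that("selection grammar resolves chain/resid/name-class conjunctions", {
  pep <- parse_structure(make_tripeptide_pdb())
  expect_equal(length(select_atoms(pep, "name CA")$indices), 3)
  expect_equal(length(select_atoms(pep, "resid 999")$indices), 0)

  chain <- make_long_chain(160)
  sel <- select_atoms(chain, "resid 103-117 and backbone and heavy")
  expect_equal(length(sel$indices), 15 * 4)
  expect_false(is.unsorted(sel$indices))
  expect_equal(anyDuplicated(sel$indices), 0)
  expect_equal(length(select_atoms(chain, "chain A and calpha")$indices), 160)
  expect_equal(length(select_atoms(chain, "chain B")$indices), 0)
  expect_error(select_atoms(chain, "resid 1-5 and wobble"), "clause 2")
})

test_that("superposition recovers exact rigid copies and matches the quaternion oracle", {
  set.seed(2)
  x <- matrix(rnorm(30, sd = 2), 10)
  idf <- superpose(x, x)
  expect_equal(idf$rotation, diag(3), tolerance = 1e-8)
  expect_lt(sqrt(sum(idf$translation^2)), 1e-8)

  th <- pi / 2
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  y <- x %*% rot + matrix(rep(c(5, 0, 0), each = 10), 10)
  f <- superpose(x, y)
  expect_lt(f$rmsd, 1e-9)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)

  # noisy copy: minimal RMSD must match Horn's quaternion method
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(rnorm(30), 10)
    b <- a %*% rot + matrix(rnorm(30, sd = 0.1), 10)
    f <- superpose(b, a)
    expect_equal(f$rmsd, oracle_quaternion_rmsd(b, a), tolerance = 1e-6)
    # mass-weighted variant against the weighted oracle
    w <- runif(10, 1, 16)
    fw <- superpose(b, a, weights = w)
    expect_equal(fw$rmsd, oracle_quaternion_rmsd(b, a, w), tolerance = 1e-6)
  }

  expect_error(superpose(x[1:2, ], x[1:2, ]), "degenerate")
  coll <- cbind(1:5, 0, 0)
  expect_error(superpose(coll, coll), "collinear")
})

test_that("superposition is optimal: no random rotation improves the fit", {
  set.seed(11)
  a <- matrix(rnorm(24), 8)
  b <- a + matrix(rnorm(24, sd = 0.3), 8)
  f <- superpose(b, a)
  base <- rmsd_coords(f$coords, a)
  ctr <- colMeans(f$coords)
  worse <- vapply(1:200, function(i) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- rbind(
      c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]), 2 * (q[2] * q[4] + q[3] * q[1])),
      c(2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[2] * q[1])),
      c(2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]), 1 - 2 * (q[2]^2 + q[3]^2)))
    rotated <- sweep(sweep(f$coords, 2, ctr) %*% R, 2, ctr, `+`)
    rmsd_coords(rotated, a)
  }, numeric(1))
  expect_true(all(worse >= base - 1e-9))
})

test_that("rmsd matches the analytic shift case and is a pseudometric", {
  set.seed(3)
  a <- matrix(rnorm(15), 5)
  expect_equal(rmsd_coords(a, a), 0)
  b <- sweep(a, 2, c(3, 4, 0), `+`)
  expect_equal(rmsd_coords(a, b), 5)
  # symmetry and triangle inequality on random triples
  for (i in 1:10) {
    x <- matrix(rnorm(15), 5); y <- matrix(rnorm(15), 5); z <- matrix(rnorm(15), 5)
    expect_equal(rmsd_coords(x, y), rmsd_coords(y, x))
    expect_lte(rmsd_coords(x, z), rmsd_coords(x, y) + rmsd_coords(y, z) + 1e-12)
  }
  expect_error(rmsd_coords(a, b[1:3, ]), "structural mismatch")
})

test_that("center of mass handles weights and selections", {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(center_of_mass(pts), c(1, 0, 0))
  expect_equal(center_of_mass(pts, weights = c(1, 3)), c(1.5, 0, 0))
  st <- random_structure(6, seed = 8)
  m <- atomic_mass(st$atoms$element)
  expect_equal(center_of_mass(st),
               colSums(get_coords(st) * m) / sum(m))
  expect_error(center_of_mass(pts, indices = integer(0)), "empty selection")
})
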