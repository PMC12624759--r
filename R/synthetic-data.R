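# Synthetic-input generators with planted ground truth. These stand in for
# the structure model, the docking engine and the MD engine: every quantity
# the pipeline is supposed to recover (cavity volume, bound-frame mask,
# contact list, SASA-filter survivors, binding-energy ordering) is planted by
# construction and recorded in a manifest that is re-derivable from the
# emitted structures.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.manifest <- function(seed, planted_truth, parameters) {
  structure(list(seed = seed, planted_truth = planted_truth,
                 parameters = parameters),
            class = "generator_manifest")
}

#' @export
print.generator_manifest <- function(x, ...) {
  cat("<generator_manifest> seed", x$seed, "- planted:",
      paste(names(x$planted_truth), collapse = ", "), "\n")
  invisible(x)
}

# quasi-uniform points on a sphere of radius r (Fibonacci lattice)
.fib_sphere <- function(n, r = 1) .sphere_points(n) * r

.atoms_df <- function(xyz, name, element = "C", resname = "DUM",
                      resid = NULL, chain = "A") {
  n <- nrow(xyz)
  data.frame(
    serial = seq_len(n), name = name, element = element, resname = resname,
    resid = if (is.null(resid)) seq_len(n) else resid, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE
  )
}

#' Synthetic pseudo-protein enclosing a spherical cavity
#'
#' Dummy carbon atoms form a thick multi-layer shell whose probe-inflated
#' occupancy leaves an empty sphere of the requested radius, with one mouth
#' channel narrower than twice the probe (so the grid sees a closed cavity).
#' The manifest records the ideal cavity volume 4/3 pi r^3 and the mouth
#' direction. The generator verifies enclosure on its own output (flood fill
#' from the cavity center) and refuses parameters that leave the shell open.
#'
#' @param sphere_radius cavity radius in Angstrom (>= 2).
#' @param layer_spacing target in-layer atom spacing (A, default 1.2;
#'   smaller = denser shell).
#' @param jitter Gaussian positional noise applied to shell atoms (A).
#' @param mouth_radius aperture radius of the mouth channel at the inner
#'   shell (A, default 1.5; must be < 2 x probe).
#' @param probe_radius probe radius the shell is built against (default 1.2).
#' @param seed RNG seed.
#' @return list with `structure` (a `mol_structure`) and `manifest`.
#' @export
gen_cavity_protein <- function(sphere_radius = 4, layer_spacing = 1.2,
                               jitter = 0, mouth_radius = 1.5,
                               probe_radius = 1.2, seed = 1) {
  if (sphere_radius < 2) stop("sphere_radius must be >= 2 A")
  if (mouth_radius >= 2 * probe_radius + 0.5) {
    stop("mouth_radius too wide: the mouth must be narrower than the probe seals")
  }
  vdw_c <- .VDW_RADII[["C"]]
  inner <- sphere_radius + vdw_c + probe_radius
  radii <- inner + c(0, 1.5, 3.0)
  .with_seed(seed, {
    layers <- lapply(radii, function(r) {
      n <- ceiling(4 * pi * r^2 / layer_spacing^2)
      .fib_sphere(n, r)
    })
    xyz <- do.call(rbind, layers)
    # carve the mouth: remove atoms within the cone around +z
    theta <- asin(min(1, mouth_radius / inner))
    polar <- acos(pmin(1, pmax(-1, xyz[, 3] / sqrt(rowSums(xyz^2)))))
    xyz <- xyz[polar > theta, , drop = FALSE]
    if (jitter > 0) xyz <- xyz + matrix(rnorm(length(xyz), 0, jitter), ncol = 3)
    st <- mol_structure(.atoms_df(xyz, name = "C", resname = "DUM"))
    # enclosure check: the empty component containing the center must not
    # reach the grid boundary
    g <- build_grid(st, spacing = 1.0, probe_radius = probe_radius)
    open_space <- g$state != .STATE_PROTEIN
    ctr_idx <- round((c(0, 0, 0) - g$origin) / g$spacing) + 1
    comp <- .label_components6(open_space)
    cavity_label <- comp[ctr_idx[1], ctr_idx[2], ctr_idx[3]]
    if (cavity_label == 0) stop("generator failure: cavity center is occupied")
    d <- dim(comp)
    boundary_labels <- unique(c(comp[1, , ], comp[d[1], , ], comp[, 1, ],
                                comp[, d[2], ], comp[, , 1], comp[, , d[3]]))
    if (cavity_label %in% boundary_labels) {
      stop("generator refuses: shell is open (cavity connects to the exterior); ",
           "decrease mouth_radius or layer_spacing")
    }
    manifest <- .manifest(seed, planted_truth = list(
      cavity_volume = 4 / 3 * pi * sphere_radius^3,
      cavity_center = c(0, 0, 0),
      mouth_direction = c(0, 0, 1)
    ), parameters = list(sphere_radius = sphere_radius,
                         layer_spacing = layer_spacing, jitter = jitter,
                         mouth_radius = mouth_radius,
                         probe_radius = probe_radius, seed = seed))
    list(structure = st, manifest = manifest)
  })
}

#' Convex solid pseudo-protein (no cavity control)
#'
#' A filled ball of dummy carbon atoms on a cubic lattice: a convex body in
#' which no pocket should be detected.
#'
#' @param radius ball radius (A).
#' @param spacing lattice spacing (A, default 1.5).
#' @return a `mol_structure`.
#' @export
gen_solid_protein <- function(radius = 8, spacing = 1.5) {
  g <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  mol_structure(.atoms_df(pts, name = "C", resname = "DUM"))
}

# --- binding trajectory -----------------------------------------------------

# local-coordinate atom tables for the toy receptor and tripeptide; contact
# atoms are placed relative to the peptide's bound pose by the generator
.toy_peptide_atoms <- function() {
  # chain B tripeptide Arg-Tyr-Arg (minimal heavy-atom representation);
  # Tyr ring in the yz-plane so its normal is +x (the unbinding direction)
  ring <- cbind(0, 1.39 * cos(seq(0, 5) * pi / 3), 1.39 * sin(seq(0, 5) * pi / 3))
  ring <- sweep(ring, 2, c(0, 0, -3.2), `+`)  # ring center below CA line
  rows <- rbind(
    # ARG 1
    c(-3.8, 0.0, 0.0), c(-2.4, 0.0, 0.0), c(-1.9, 1.4, 0.0), c(-2.6, 2.4, 0.0),
    c(-2.0, -1.2, 1.1), c(-2.0, -1.2, 2.6),
    # TYR 2
    c(-0.6, 1.5, 0.0), c(0.4, 0.5, 0.0), c(1.8, 1.1, 0.0), c(2.0, 2.3, 0.0),
    c(0.3, -0.4, -1.2), ring,
    c(0.0, 0.0, -6.0),
    # ARG 3
    c(2.8, 0.3, 0.0), c(4.2, 0.8, 0.0), c(5.2, -0.3, 0.0), c(5.0, -1.5, 0.0),
    c(4.5, 1.6, 1.2), c(4.5, 1.6, 2.7)
  )
  data.frame(
    serial = seq_len(nrow(rows)),
    name = c("N", "CA", "C", "O", "CB", "NH1",
             "N", "CA", "C", "O", "CB",
             "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH",
             "N", "CA", "C", "O", "CB", "NH1"),
    element = c("N", "C", "C", "O", "C", "N",
                "N", "C", "C", "O", "C",
                "C", "C", "C", "C", "C", "C", "O",
                "N", "C", "C", "O", "C", "N"),
    resname = rep(c("ARG", "TYR", "ARG"), c(6, 12, 6)),
    resid = rep(1:3, c(6, 12, 6)),
    chain = "B",
    x = rows[, 1], y = rows[, 2], z = rows[, 3],
    stringsAsFactors = FALSE
  )
}

#' Synthetic protein-peptide binding trajectory with planted truth
#'
#' A frozen toy receptor plus a rigid tripeptide whose center-of-mass distance
#' to the binding site follows `bound_mask` (bound/unbound nominal distances
#' plus isotropic Gaussian jitter). Three contacts - an Arg-Glu salt bridge,
#' a hydrogen-bond geometry and a Lys/Tyr cation-pi stack - are planted so
#' they hold in exactly the bound frames.
#'
#' @param n_frames number of frames.
#' @param bound_mask logical vector per frame (default: first 60 percent
#'   bound); its mean is the planted bound fraction.
#' @param bound_com_distance,unbound_com_distance nominal peptide-to-site COM
#'   distances (A, defaults 4 and 9).
#' @param noise_sigma isotropic Gaussian jitter on the peptide placement (A,
#'   default 0.2). Separability `bound + 3 sigma < 6 < unbound - 3 sigma` is
#'   enforced.
#' @param seed RNG seed.
#' @return list with `trajectory` (a `mol_trajectory`), `reference` (the
#'   noiseless bound complex as a `mol_structure`), `topology`
#'   (a `topology_params`), `peptide_selection` (atom indices) and `manifest`
#'   (planted bound mask, fraction, contact list, site residues).
#' @export
gen_binding_trajectory <- function(n_frames = 1000, bound_mask = NULL,
                                   bound_com_distance = 4,
                                   unbound_com_distance = 9,
                                   noise_sigma = 0.2, seed = 1) {
  if (is.null(bound_mask)) {
    bound_mask <- seq_len(n_frames) <= round(0.6 * n_frames)
  }
  if (length(bound_mask) != n_frames) stop("bound_mask length must equal n_frames")
  if (!(bound_com_distance + 3 * noise_sigma < 6 &&
        6 < unbound_com_distance - 3 * noise_sigma)) {
    stop("separability violated: need bound + 3 sigma < 6 < unbound - 3 sigma")
  }
  pep <- .toy_peptide_atoms()
  pep_xyz <- as.matrix(pep[, c("x", "y", "z")])
  pep_mass <- atomic_mass(pep$element)
  pep_com_local <- colSums(pep_xyz * pep_mass) / sum(pep_mass)

  # receptor scaffold: six residues whose CA atoms ring the origin in the
  # y-z plane; site COM (CA only) is the origin by symmetry
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ca <- cbind(0, 3 * cos(ang), 3 * sin(ang))
  resnames <- c("GLU", "SER", "LYS", "GLY", "GLY", "GLY")
  rec_rows <- list()
  for (i in 1:6) {
    base <- ca[i, ]
    rec_rows[[i]] <- data.frame(
      name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      resname = resnames[i], resid = i, chain = "A",
      x = base[1] + c(-1.4, 0, 1.0, 1.0),
      y = base[2] + c(0, 0, 1.0, 2.2), z = base[3],
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, rec_rows)

  # nominal bound pose of the peptide: COM at bound_com_distance along +x
  shift <- c(bound_com_distance, 0, 0) - pep_com_local
  pep_bound <- sweep(pep_xyz, 2, shift, `+`)
  nh1 <- pep_bound[pep$name == "NH1" & pep$resid == 1, ]
  bb_o <- pep_bound[pep$name == "O" & pep$resid == 2, ]
  ring_idx <- pep$resid == 2 & pep$name %in% .RING_ATOMS$TYR
  ring_ctr <- colMeans(pep_bound[ring_idx, , drop = FALSE])
  # functional atoms placed against the bound pose, all on the -x side of
  # their peptide partners so the +x unbinding displacement breaks them:
  # GLU OE1/OE2 2.6 A from Arg1 NH1; SER OG 2.7 A from Tyr backbone O;
  # LYS NZ 3.5 A along the Tyr ring normal (-x)
  extra <- data.frame(
    name = c("OE1", "OE2", "OG", "NZ"),
    element = c("O", "O", "O", "N"),
    resname = c("GLU", "GLU", "SER", "LYS"),
    resid = c(1, 1, 2, 3), chain = "A",
    x = c(nh1[1] - 2.6, nh1[1] - 2.6, bb_o[1], ring_ctr[1] - 3.5),
    y = c(nh1[2], nh1[2] + 1.2, bb_o[2] + 2.7, ring_ctr[2]),
    z = c(nh1[3], nh1[3], bb_o[3], ring_ctr[3]),
    stringsAsFactors = FALSE
  )
  rec <- rbind(rec, extra)
  rec <- rec[order(rec$resid, rec$name), ]
  # topology carries the peptide at its bound pose (the reference complex)
  pep_at_bound <- pep
  pep_at_bound$x <- pep_bound[, 1]
  pep_at_bound$y <- pep_bound[, 2]
  pep_at_bound$z <- pep_bound[, 3]
  atoms <- rbind(rec, pep_at_bound[, names(rec)])
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  topo_struct <- mol_structure(atoms)
  n_rec <- nrow(rec)
  pep_idx <- n_rec + seq_len(nrow(pep))

  .with_seed(seed, {
    frames <- vector("list", n_frames)
    base <- get_coords(topo_struct)
    for (k in seq_len(n_frames)) {
      d <- if (bound_mask[k]) bound_com_distance else unbound_com_distance
      jit <- rnorm(3, 0, noise_sigma / sqrt(3))
      f <- base
      delta <- c(d - bound_com_distance, 0, 0) + jit
      f[pep_idx, ] <- sweep(f[pep_idx, , drop = FALSE], 2, delta, `+`)
      frames[[k]] <- f
    }
    traj <- mol_trajectory(topo_struct, frames)

    top_atoms <- data.frame(
      serial = atoms$serial,
      charge = ifelse(atoms$name %in% c("NH1", "NZ"), 0.5,
               ifelse(atoms$name %in% c("OE1", "OE2"), -0.5, 0)),
      gb_radius = vdw_radius(atoms$element),
      screen = 0.8, lj_sigma = 3.2, lj_epsilon = 0.1,
      lcpo_p1 = 1, lcpo_p2 = -1, lcpo_p3 = 0, lcpo_p4 = 0,
      lcpo_radius = vdw_radius(atoms$element)
    )
    manifest <- .manifest(seed, planted_truth = list(
      bound_mask = bound_mask,
      bound_fraction = mean(bound_mask),
      site_residues = paste0("A:", 1:6),
      contacts = data.frame(
        res_a = c("A:1", "A:2", "A:3"), res_b = c("B:1", "B:2", "B:2"),
        kind = c("salt_bridge", "hydrogen_bond", "cation_pi"),
        frequency = mean(bound_mask), stringsAsFactors = FALSE
      )
    ), parameters = list(n_frames = n_frames,
                         bound_com_distance = bound_com_distance,
                         unbound_com_distance = unbound_com_distance,
                         noise_sigma = noise_sigma, seed = seed))
    list(trajectory = traj,
         reference = topo_struct,
         topology = topology_params(top_atoms),
         peptide_selection = pep_idx,
         manifest = manifest)
  })
}

# --- pose set ---------------------------------------------------------------

# receptor clamp for gen_pose_set: two dense rectangular slabs at z = +/- gap
# around the Tyr ring center (y extended to cover CB and the linker bead);
# in-plane spacing 1.3 A seals against a 1.4 A probe, so the side chain's
# exposure is a monotone function of the gap
.clamp_slabs <- function(gap, spacing = 1.3) {
  gx <- seq(-7, 7, by = spacing)
  gy <- seq(-7, 12, by = spacing)
  plate <- as.matrix(expand.grid(x = gx, y = gy))
  up <- cbind(plate, gap)
  dn <- cbind(plate, -gap)
  .atoms_df(rbind(up, dn), name = "C", resname = "DUM", chain = "A")
}

.pose_peptide <- function() {
  # Gly-Tyr-Gly, Tyr ring in the xy-plane centered at the origin so slabs at
  # z = +/- gap clamp it; backbone runs outside the slab extent at y = 10
  ring <- cbind(1.39 * cos(seq(0, 5) * pi / 3), 1.39 * sin(seq(0, 5) * pi / 3), 0)
  rows <- rbind(
    c(-3.8, 10, 0), c(-2.4, 10, 0), c(-1.6, 11.2, 0), c(-2.1, 12.3, 0),
    c(-0.3, 11.0, 0), c(0.6, 10.0, 0), c(2.0, 10.5, 0), c(2.3, 11.7, 0),
    c(0.4, 8.6, 0), c(0.2, 4.3, 0),
    ring,
    c(0, -2.78, 0),  # OH, para to the CB side of the ring
    c(3.2, 9.6, 0), c(4.6, 10.1, 0), c(5.5, 9.1, 0), c(5.3, 7.9, 0)
  )
  data.frame(
    serial = seq_len(nrow(rows)),
    name = c("N", "CA", "C", "O",
             "N", "CA", "C", "O", "CB", "CG1",
             "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH",
             "N", "CA", "C", "O"),
    element = c("N", "C", "C", "O",
                "N", "C", "C", "O", "C", "C",
                "C", "C", "C", "C", "C", "C", "O",
                "N", "C", "C", "O"),
    resname = rep(c("GLY", "TYR", "GLY"), c(4, 13, 4)),
    resid = rep(1:3, c(4, 13, 4)),
    chain = "B",
    x = rows[, 1], y = rows[, 2], z = rows[, 3],
    stringsAsFactors = FALSE
  )
}

.pose_complex <- function(gap) {
  pep <- .pose_peptide()
  slabs <- .clamp_slabs(gap)
  cols <- setdiff(names(pep), "serial")
  atoms <- rbind(slabs[, cols], pep[, cols])
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  mol_structure(atoms)
}

#' Synthetic docked-pose ensemble with controlled aromatic burial
#'
#' Each pose is a Gly-Tyr-Gly tripeptide whose tyrosine ring is clamped
#' between two dense receptor slabs; the slab gap is bisected per pose until
#' the measured Shrake-Rupley side-chain SASA is within `tolerance` of the
#' requested value. Score triples are attached as annotations. The manifest
#' records which poses survive the 20 A^2 filter.
#'
#' @param aromatic_burial_sasa numeric vector of requested side-chain SASA
#'   values (A^2), one per pose.
#' @param score_triples optional data.frame with columns `vina`, `cnn_score`,
#'   `cnn_affinity` (one row per pose); random annotations when NULL.
#' @param tolerance acceptable |measured - requested| (A^2, default 2).
#' @param sasa_cutoff manifest survivor threshold (default 20).
#' @param seed RNG seed (used for score annotations).
#' @return list with `poses` (list of `pose_record`s), `measured_sasa`, and
#'   `manifest` (survivor pose ids).
#' @export
gen_pose_set <- function(aromatic_burial_sasa, score_triples = NULL,
                         tolerance = 2, sasa_cutoff = 20, seed = 1) {
  n <- length(aromatic_burial_sasa)
  if (n == 0) {
    return(list(poses = list(), measured_sasa = numeric(0),
                manifest = .manifest(seed, list(survivors = character(0)),
                                     list(n_poses = 0, seed = seed))))
  }
  meas <- function(gap) {
    st <- .pose_complex(gap)
    sidechain_sasa(st, "B:2")
  }
  lo_gap <- 1.6
  hi_gap <- 14
  feas_lo <- meas(lo_gap)
  feas_hi <- meas(hi_gap)
  bad <- aromatic_burial_sasa < feas_lo - tolerance |
    aromatic_burial_sasa > feas_hi + tolerance
  if (any(bad)) {
    stop(sprintf("requested SASA %.1f unreachable; feasible range [%.1f, %.1f] A^2",
                 aromatic_burial_sasa[which(bad)[1]], feas_lo, feas_hi))
  }
  .with_seed(seed, {
    if (is.null(score_triples)) {
      score_triples <- data.frame(
        vina = round(runif(n, -8, -4), 2),
        cnn_score = round(runif(n, 0.05, 0.95), 3),
        cnn_affinity = round(runif(n, 2, 8), 2)
      )
    }
    poses <- vector("list", n)
    measured <- numeric(n)
    for (i in seq_len(n)) {
      target <- aromatic_burial_sasa[i]
      a <- lo_gap; b <- hi_gap
      va <- feas_lo; vb <- feas_hi
      for (it in 1:36) {
        mid <- (a + b) / 2
        vm <- meas(mid)
        if (abs(vm - target) <= tolerance * 0.5) { a <- mid; b <- mid; break }
        if (vm < target) { a <- mid; va <- vm } else { b <- mid; vb <- vm }
      }
      gap <- (a + b) / 2
      st <- .pose_complex(gap)
      measured[i] <- sidechain_sasa(st, "B:2")
      if (abs(measured[i] - target) > tolerance) {
        stop(sprintf("could not realise SASA %.1f A^2 (best %.1f)", target, measured[i]))
      }
      pid <- sprintf("pose_%02d", i)
      poses[[i]] <- pose_record(pid, st, "B",
                                as.list(score_triples[i, ]), "B:2")
      poses[[i]]$aromatic_sasa <- measured[i]
    }
    ids <- vapply(poses, function(p) p$pose_id, "")
    manifest <- .manifest(seed, planted_truth = list(
      requested_sasa = aromatic_burial_sasa,
      measured_sasa = measured,
      survivors = ids[measured <= sasa_cutoff]
    ), parameters = list(n_poses = n, tolerance = tolerance,
                         sasa_cutoff = sasa_cutoff, seed = seed))
    list(poses = poses, measured_sasa = measured, manifest = manifest)
  })
}

# --- energy system ----------------------------------------------------------

#' Synthetic host-guest system with a planted binding-energy ordering
#'
#' A rigid host bead cluster carries one negatively charged site and one
#' positively charged site far apart; the positively charged guest triad is
#' docked at the negative site in the "strong" complex (complementary
#' pairing) and at the positive site in the "decoy" complex (like charges at
#' contact). Both complexes share one topology, so the MM/GBSA-style energy
#' ordering strong < decoy is planted purely by geometry.
#'
#' @param strong_separation,decoy_separation guest-to-site contact distances
#'   (A); both must be at or beyond the Lennard-Jones minimum
#'   (2^(1/6) sigma, sigma = 3.0 A here).
#' @param guest_charge per-bead guest charge (e, default +0.5); flip the sign
#'   to invert the planted ordering.
#' @param jitter Gaussian positional noise on the guest beads (A, default 0);
#'   kept small relative to the separations so the ordering is preserved.
#' @param seed RNG seed (drives the jitter).
#' @return list with `strong`, `decoy` (complex `mol_structure`s),
#'   `topology`, `receptor_idx`, `ligand_idx`, `manifest`.
#' @export
gen_energy_system <- function(strong_separation = 3.5, decoy_separation = 3.5,
                              guest_charge = 0.5, jitter = 0, seed = 1) {
  sigma <- 3.0
  rmin <- 2^(1 / 6) * sigma
  if (strong_separation < rmin || decoy_separation < rmin) {
    stop(sprintf("separations must be >= the LJ contact distance %.2f A", rmin))
  }
  # host: two triangular charged sites 20 A apart plus neutral spacer beads
  site_a <- cbind(0, c(0, 1.8, -1.8), c(2.0, -1.2, -1.2))          # charge -0.5
  site_b <- sweep(site_a, 2, c(20, 0, 0), `+`)                     # charge +0.5
  spacer <- cbind(seq(4, 16, by = 4), 8, 0)  # off-axis: clash-free at both sites
  host <- rbind(site_a, site_b, spacer)
  host_q <- c(rep(-0.5, 3), rep(+0.5, 3), rep(0, nrow(spacer)))
  # guest: triangle matching the site geometry, offset along -x by separation
  guest_local <- cbind(0, c(0, 1.8, -1.8), c(2.0, -1.2, -1.2))
  if (jitter > 0) {
    guest_local <- .with_seed(seed, guest_local +
                                matrix(rnorm(length(guest_local), 0, jitter), ncol = 3))
  }
  place_guest <- function(site_center_x, sep) {
    sweep(guest_local, 2, c(site_center_x - sep, 0, 0), `+`)
  }
  strong_xyz <- rbind(host, place_guest(0, strong_separation))
  decoy_xyz <- rbind(host, place_guest(20, decoy_separation))
  n_host <- nrow(host)
  n_guest <- nrow(guest_local)
  mk <- function(xyz) {
    atoms <- .atoms_df(xyz, name = "C", resname = "DUM",
                       chain = rep(c("A", "B"), c(n_host, n_guest)))
    atoms$resid <- seq_len(nrow(atoms))
    mol_structure(atoms)
  }
  top_atoms <- data.frame(
    serial = seq_len(n_host + n_guest),
    charge = c(host_q, rep(guest_charge, n_guest)),
    gb_radius = 1.7, screen = 0.8, lj_sigma = sigma, lj_epsilon = 0.15,
    lcpo_p1 = 1, lcpo_p2 = -1, lcpo_p3 = 0, lcpo_p4 = 0, lcpo_radius = 1.7
  )
  manifest <- .manifest(seed, planted_truth = list(
    expected_order = if (guest_charge > 0) c("strong", "decoy") else c("decoy", "strong")
  ), parameters = list(strong_separation = strong_separation,
                       decoy_separation = decoy_separation,
                       guest_charge = guest_charge, seed = seed))
  list(strong = mk(strong_xyz), decoy = mk(decoy_xyz),
       topology = topology_params(top_atoms),
       receptor_idx = seq_len(n_host),
       ligand_idx = n_host + seq_len(n_guest),
       manifest = manifest)
}
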