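# Trajectory statistics driving pose adjudication: ligand RMSD after
# receptor-only fitting, CAPRI-style interface RMSD, RMSF, center-of-mass
# bound fraction, residue contact frequencies, occupancy grids, and average
# structures.

#' Define a binding site from a reference complex
#'
#' Site residues are receptor residues with any heavy atom within
#' `site_radius` of any peptide atom in the reference frame. The site is fixed
#' once defined; its center of mass uses the `com_atoms` name class
#' (default C-alpha only).
#'
#' @param traj a `mol_trajectory` or `mol_structure` used as reference.
#' @param peptide_selection `atom_selection` (or indices) of the peptide.
#' @param reference_frame frame index defining the site (default 1).
#' @param site_radius capture radius in Angstrom (default 5).
#' @param com_atoms atom-name class used for the site COM (default "calpha").
#' @return object of class `binding_site`: list with `site_residues`
#'   ("chain:resid"), `com_indices` (atom indices used for the site COM),
#'   `site_radius`, `com_atoms`.
#' @export
define_binding_site <- function(traj, peptide_selection, reference_frame = 1,
                                site_radius = 5, com_atoms = "calpha") {
  is_traj <- inherits(traj, "mol_trajectory")
  topo <- if (is_traj) traj$topology else traj
  xyz <- if (is_traj) frame_coords(traj, reference_frame) else get_coords(traj)
  a <- topo$atoms
  pep <- .resolve_indices(peptide_selection, nrow(a))
  if (length(pep) == 0) stop("empty peptide selection")
  rec <- setdiff(which(toupper(a$element) != "H"), pep)
  pxyz <- xyz[pep, , drop = FALSE]
  near <- vapply(rec, function(i) {
    min(sqrt(rowSums(sweep(pxyz, 2, xyz[i, ])^2))) <= site_radius
  }, logical(1))
  site_res <- unique(paste0(a$chain[rec[near]], ":", a$resid[rec[near]]))
  if (length(site_res) == 0) stop("empty binding site: no receptor residue within ",
                                  site_radius, " A of the peptide")
  reskey <- paste0(a$chain, ":", a$resid)
  com_sel <- select_atoms(topo, com_atoms)
  com_idx <- intersect(com_sel$indices, which(reskey %in% site_res))
  com_idx <- setdiff(com_idx, pep)
  if (length(com_idx) == 0) stop("no '", com_atoms, "' atoms in the site residues")
  structure(list(site_residues = site_res, com_indices = com_idx,
                 site_radius = site_radius, com_atoms = com_atoms),
            class = "binding_site")
}

#' Define a binding site from an explicit residue list
#'
#' Alternative to [define_binding_site()] when the site residues are known
#' (e.g. planted by a generator): fixes the site to the given residues and
#' resolves the COM atoms.
#'
#' @param structure a `mol_structure` (or `mol_trajectory` topology).
#' @param residues character vector of "chain:resid" identifiers.
#' @param com_atoms atom-name class for the site COM (default "calpha").
#' @return a `binding_site`.
#' @export
binding_site_from_residues <- function(structure, residues, com_atoms = "calpha") {
  if (inherits(structure, "mol_trajectory")) structure <- structure$topology
  a <- structure$atoms
  reskey <- paste0(a$chain, ":", a$resid)
  if (!all(residues %in% reskey)) {
    stop("unknown residue(s): ",
         paste(setdiff(residues, reskey), collapse = ", "))
  }
  com_sel <- select_atoms(structure, com_atoms)
  com_idx <- intersect(com_sel$indices, which(reskey %in% residues))
  if (length(com_idx) == 0) stop("no '", com_atoms, "' atoms in the site residues")
  base::structure(list(site_residues = residues, com_indices = com_idx,
                       site_radius = NA_real_, com_atoms = com_atoms),
                  class = "binding_site")
}

#' Ligand RMSD series after receptor-only fitting
#'
#' Per frame: superpose on `fit_selection` (receptor atoms, e.g. C-alpha in
#' secondary structure) onto the reference frame, then compute the RMSD of the
#' ligand selection relative to the reference with no further fitting.
#'
#' @param traj a `mol_trajectory`.
#' @param fit_selection `atom_selection`/indices used for the superposition.
#' @param ligand_selection `atom_selection`/indices over which RMSD is taken
#'   (heavy atoms recommended).
#' @param reference reference frame index (default 1).
#' @param mass_weighted_fit logical; mass-weight the superposition (default TRUE).
#' @return numeric vector, one RMSD (Angstrom) per frame; zero at the
#'   reference frame.
#' @export
ligand_rmsd_series <- function(traj, fit_selection, ligand_selection,
                               reference = 1, mass_weighted_fit = TRUE) {
  na <- n_atoms(traj)
  fit <- .resolve_indices(fit_selection, na)
  lig <- .resolve_indices(ligand_selection, na)
  if (length(fit) < 3) stop("fit selection needs >= 3 atoms")
  if (length(lig) == 0) stop("empty ligand selection")
  ref <- frame_coords(traj, reference)
  w <- if (mass_weighted_fit) atomic_mass(traj$topology$atoms$element[fit]) else NULL
  vapply(seq_len(n_frames(traj)), function(k) {
    fitted <- superpose(frame_coords(traj, k), ref, fit, weights = w)$coords
    rmsd_coords(fitted, ref, lig)
  }, numeric(1))
}

#' CAPRI-style interface RMSD
#'
#' Interface residues are residues of either partner with a heavy atom within
#' `interface_radius` of the other partner in the reference complex. The model
#' is superposed on the interface backbone atoms and the RMSD over those atoms
#' is returned.
#'
#' @param model a `mol_structure` or coordinate matrix matching the reference
#'   topology.
#' @param reference the reference complex, a `mol_structure`.
#' @param partner_a,partner_b `atom_selection`/indices of the two partners.
#' @param interface_radius Angstrom (default 10).
#' @return list with `irmsd` (Angstrom, NA when the interface is empty),
#'   `interface_residues`, `unbound_like` (TRUE when irmsd > 10),
#'   `defined` (FALSE with a `diagnostic` message when the interface is empty).
#' @export
interface_rmsd <- function(model, reference, partner_a, partner_b,
                           interface_radius = 10) {
  a <- reference$atoms
  na <- nrow(a)
  ia <- .resolve_indices(partner_a, na)
  ib <- .resolve_indices(partner_b, na)
  xyz <- get_coords(reference)
  heavy <- toupper(a$element) != "H"
  ha <- ia[heavy[ia]]
  hb <- ib[heavy[ib]]
  # residues of either partner with a heavy atom near the other partner
  near_b <- vapply(ha, function(i) {
    min(sqrt(rowSums(sweep(xyz[hb, , drop = FALSE], 2, xyz[i, ])^2))) <= interface_radius
  }, logical(1))
  near_a <- vapply(hb, function(i) {
    min(sqrt(rowSums(sweep(xyz[ha, , drop = FALSE], 2, xyz[i, ])^2))) <= interface_radius
  }, logical(1))
  reskey <- paste0(a$chain, ":", a$resid)
  iface_res <- unique(c(reskey[ha[near_b]], reskey[hb[near_a]]))
  if (length(iface_res) == 0) {
    return(list(irmsd = NA_real_, interface_residues = character(0),
                unbound_like = NA, defined = FALSE,
                diagnostic = "empty interface: partners farther apart than the interface radius"))
  }
  bb <- which(reskey %in% iface_res & a$name %in% .BACKBONE_NAMES & heavy)
  mob <- .as_coords(model)
  if (nrow(mob) != na) stop("structural mismatch: model does not match reference topology")
  fitted <- superpose(mob, xyz, bb)$coords
  val <- rmsd_coords(fitted, xyz, bb)
  list(irmsd = val, interface_residues = iface_res, unbound_like = val > 10,
       defined = TRUE, diagnostic = NULL)
}

#' Root-mean-square fluctuation per residue
#'
#' Frames are superposed onto the first frame over `align_selection`; each
#' atom's RMSF is the root mean squared deviation from its time-averaged
#' position, and residue values are mass-weighted means over the selected
#' atoms of the residue.
#'
#' @param traj a `mol_trajectory` (>= 2 frames).
#' @param selection atoms reported (default all heavy atoms).
#' @param align_selection atoms used for the fit (default: the selection).
#' @return data.frame with columns `residue` ("chain:resid") and `rmsf`
#'   (Angstrom); attribute `per_atom` carries atomic values.
#' @export
rmsf <- function(traj, selection = NULL, align_selection = NULL) {
  if (n_frames(traj) < 2) stop("RMSF undefined for a single frame")
  a <- traj$topology$atoms
  na <- nrow(a)
  sel <- .resolve_indices(if (is.null(selection))
    which(toupper(a$element) != "H") else selection, na)
  fitsel <- .resolve_indices(if (is.null(align_selection)) sel else align_selection, na)
  ref <- frame_coords(traj, 1)
  w <- atomic_mass(a$element[fitsel])
  aligned <- lapply(seq_len(n_frames(traj)), function(k) {
    superpose(frame_coords(traj, k), ref, fitsel, weights = w)$coords[sel, , drop = FALSE]
  })
  arr <- simplify2array(aligned)            # n_sel x 3 x n_frames
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply(sweep(arr, c(1, 2), mean_pos)^2, c(1, 3), sum)  # n_sel x n_frames
  atom_rmsf <- sqrt(rowMeans(dev2))
  reskey <- paste0(a$chain[sel], ":", a$resid[sel])
  am <- atomic_mass(a$element[sel])
  res_rmsf <- vapply(unique(reskey), function(rk) {
    m <- reskey == rk
    sum(atom_rmsf[m] * am[m]) / sum(am[m])
  }, numeric(1))
  out <- data.frame(residue = unique(reskey), rmsf = unname(res_rmsf),
                    stringsAsFactors = FALSE)
  attr(out, "per_atom") <- data.frame(index = sel, rmsf = atom_rmsf)
  out
}

#' Bound fraction from the peptide-to-site center-of-mass distance
#'
#' Per frame: distance between the peptide COM (mass-weighted heavy atoms)
#' and the site COM (site `com_atoms`, e.g. C-alpha only); the frame is bound
#' iff the distance is at or below `unbound_cutoff`.
#'
#' @param traj a `mol_trajectory`.
#' @param site a `binding_site` from [define_binding_site()].
#' @param peptide_selection `atom_selection`/indices of the peptide.
#' @param unbound_cutoff Angstrom; frames above it are unbound (default 6).
#' @return list with `fraction`, `distance` (per-frame series, Angstrom) and
#'   `bound` (logical mask).
#' @export
bound_fraction <- function(traj, site, peptide_selection, unbound_cutoff = 6) {
  a <- traj$topology$atoms
  na <- nrow(a)
  pep <- .resolve_indices(peptide_selection, na)
  pep <- pep[toupper(a$element[pep]) != "H"]
  if (length(pep) == 0) stop("empty peptide selection")
  if (length(site$com_indices) == 0) stop("empty binding site")
  pw <- atomic_mass(a$element[pep])
  dist_series <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- frame_coords(traj, k)
    pcom <- colSums(xyz[pep, , drop = FALSE] * pw) / sum(pw)
    scom <- colMeans(xyz[site$com_indices, , drop = FALSE])
    sqrt(sum((pcom - scom)^2))
  }, numeric(1))
  bound <- dist_series <= unbound_cutoff
  list(fraction = mean(bound), distance = dist_series, bound = bound)
}

# --- contact detection ------------------------------------------------------

.SALT_BASIC <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ", HIS = c("ND1", "NE2"))
.SALT_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
.CATION_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ")

#' Contact detection thresholds
#'
#' Geometric conventions per contact kind: hydrogen bond = donor-acceptor
#' heavy-atom distance <= 3.5 A (with a D-H...A angle >= 120 degrees when the
#' hydrogen is present); salt bridge = basic N (Arg/Lys/His) to acidic O
#' (Asp/Glu) <= 4.0 A; van der Waals = heavy-atom distance <=
#' r_i + r_j + 0.5 A; cation-pi = charged N within 6.0 A of an aromatic ring
#' centroid and within 60 degrees of the ring normal.
#'
#' @param hbond_dist,saltbridge_dist,vdw_pad,cation_pi_dist distances (A).
#' @param hbond_angle_min minimum D-H...A angle (degrees).
#' @param cation_pi_angle_max maximum angle from the ring normal (degrees).
#' @param frequency_cutoff sustained-contact threshold on frequency (0.25:
#'   contacts at or below it are dropped from the filtered view).
#' @return list of class `contact_spec`.
#' @export
contact_spec <- function(hbond_dist = 3.5, hbond_angle_min = 120,
                         saltbridge_dist = 4.0, vdw_pad = 0.5,
                         cation_pi_dist = 6.0, cation_pi_angle_max = 60,
                         frequency_cutoff = 0.25) {
  stopifnot(hbond_dist > 0, saltbridge_dist > 0, cation_pi_dist > 0,
            frequency_cutoff >= 0, frequency_cutoff <= 1)
  structure(list(hbond_dist = hbond_dist, hbond_angle_min = hbond_angle_min,
                 saltbridge_dist = saltbridge_dist, vdw_pad = vdw_pad,
                 cation_pi_dist = cation_pi_dist,
                 cation_pi_angle_max = cation_pi_angle_max,
                 frequency_cutoff = frequency_cutoff),
            class = "contact_spec")
}

# contacts present in one frame between residues of group_a and group_b;
# returns data.frame(res_a, res_b, kind)
.frame_contacts <- function(atoms, xyz, ia, ib, spec) {
  reskey <- paste0(atoms$chain, ":", atoms$resid)
  heavy <- toupper(atoms$element) != "H"
  out <- list()
  add <- function(res_a, res_b, kind) {
    out[[length(out) + 1]] <<- data.frame(res_a = res_a, res_b = res_b,
                                          kind = kind, stringsAsFactors = FALSE)
  }
  polar <- toupper(atoms$element) %in% c("N", "O")
  pa <- ia[polar[ia] & heavy[ia]]
  pb <- ib[polar[ib] & heavy[ib]]
  # hydrogens bonded to a polar heavy atom (within 1.25 A) for angle checks
  hyd <- which(toupper(atoms$element) == "H")
  if (length(pa) > 0 && length(pb) > 0) {
    for (i in pa) {
      d <- sqrt(rowSums(sweep(xyz[pb, , drop = FALSE], 2, xyz[i, ])^2))
      for (j in pb[d <= spec$hbond_dist]) {
        ok <- TRUE
        if (length(hyd) > 0) {
          # treat i as donor when it carries an H; require D-H...A angle
          dh <- sqrt(rowSums(sweep(xyz[hyd, , drop = FALSE], 2, xyz[i, ])^2))
          hs <- hyd[dh <= 1.25]
          if (length(hs) > 0) {
            ang <- vapply(hs, function(h) {
              v1 <- xyz[i, ] - xyz[h, ]
              v2 <- xyz[j, ] - xyz[h, ]
              acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
            }, numeric(1))
            ok <- any(ang >= spec$hbond_angle_min)
          }
        }
        if (ok) add(reskey[i], reskey[j], "hydrogen_bond")
      }
    }
  }
  # salt bridges
  basic <- ia[vapply(ia, function(i) {
    rn <- atoms$resname[i]
    rn %in% names(.SALT_BASIC) && atoms$name[i] %in% .SALT_BASIC[[rn]]
  }, logical(1))]
  acidic <- ib[vapply(ib, function(i) {
    rn <- atoms$resname[i]
    rn %in% names(.SALT_ACIDIC) && atoms$name[i] %in% .SALT_ACIDIC[[rn]]
  }, logical(1))]
  sb_pairs <- rbind(
    if (length(basic) && length(acidic)) expand.grid(basic, acidic),
    {
      basic_b <- ib[vapply(ib, function(i) {
        rn <- atoms$resname[i]
        rn %in% names(.SALT_BASIC) && atoms$name[i] %in% .SALT_BASIC[[rn]]
      }, logical(1))]
      acidic_a <- ia[vapply(ia, function(i) {
        rn <- atoms$resname[i]
        rn %in% names(.SALT_ACIDIC) && atoms$name[i] %in% .SALT_ACIDIC[[rn]]
      }, logical(1))]
      if (length(basic_b) && length(acidic_a)) expand.grid(acidic_a, basic_b) else NULL
    }
  )
  if (!is.null(sb_pairs) && nrow(sb_pairs) > 0) {
    for (k in seq_len(nrow(sb_pairs))) {
      i <- sb_pairs[k, 1]; j <- sb_pairs[k, 2]
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= spec$saltbridge_dist) {
        add(reskey[i], reskey[j], "salt_bridge")
      }
    }
  }
  # van der Waals (different residues across the two groups)
  ha <- ia[heavy[ia]]
  hb <- ib[heavy[ib]]
  for (i in ha) {
    d <- sqrt(rowSums(sweep(xyz[hb, , drop = FALSE], 2, xyz[i, ])^2))
    cut <- atoms$vdw[i] + atoms$vdw[hb] + spec$vdw_pad
    hitres <- unique(reskey[hb[d <= cut & reskey[hb] != reskey[i]]])
    for (rb in hitres) add(reskey[i], rb, "vdw")
  }
  # cation-pi, both orientations
  .cat_pi <- function(cat_idx, ring_group) {
    ring_res <- unique(reskey[ring_group][atoms$resname[ring_group] %in% names(.RING_ATOMS)])
    for (rr in ring_res) {
      members <- ring_group[reskey[ring_group] == rr]
      rn <- atoms$resname[members[1]]
      ratoms <- members[atoms$name[members] %in% .RING_ATOMS[[rn]]]
      if (length(ratoms) < 3) next
      ctr <- colMeans(xyz[ratoms, , drop = FALSE])
      rc <- sweep(xyz[ratoms, , drop = FALSE], 2, ctr)
      normal <- svd(rc)$v[, 3]
      for (i in cat_idx) {
        v <- xyz[i, ] - ctr
        dd <- sqrt(sum(v^2))
        if (dd > spec$cation_pi_dist) next
        ang <- acos(abs(sum(v * normal)) / dd) * 180 / pi
        if (ang <= spec$cation_pi_angle_max) add(reskey[i], rr, "cation_pi")
      }
    }
  }
  cat_a <- ia[vapply(ia, function(i) {
    rn <- atoms$resname[i]
    rn %in% names(.CATION_ATOMS) && atoms$name[i] %in% .CATION_ATOMS[[rn]]
  }, logical(1))]
  cat_b <- ib[vapply(ib, function(i) {
    rn <- atoms$resname[i]
    rn %in% names(.CATION_ATOMS) && atoms$name[i] %in% .CATION_ATOMS[[rn]]
  }, logical(1))]
  if (length(cat_a) > 0) .cat_pi(cat_a, ib)
  if (length(cat_b) > 0) .cat_pi(cat_b, ia)
  if (length(out) == 0) {
    return(data.frame(res_a = character(0), res_b = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

#' Residue contact frequencies over a trajectory
#'
#' Detects hydrogen-bond, salt-bridge, van der Waals and cation-pi contacts
#' between the two atom groups in every frame and reports per-(pair, kind)
#' frequencies. Pairs at or below the frequency cutoff are dropped from the
#' filtered view; the full table is returned as the audit.
#'
#' @param traj a `mol_trajectory`.
#' @param group_a,group_b `atom_selection`/indices of the two partners
#'   (e.g. receptor and peptide).
#' @param spec a [contact_spec()].
#' @return list with `filtered` and `full` data.frames (columns `res_a`,
#'   `res_b`, `kind`, `frequency`).
#' @export
contact_frequencies <- function(traj, group_a, group_b, spec = contact_spec()) {
  a <- traj$topology$atoms
  na <- nrow(a)
  ia <- .resolve_indices(group_a, na)
  ib <- .resolve_indices(group_b, na)
  nf <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  for (k in seq_len(nf)) {
    fc <- .frame_contacts(a, frame_coords(traj, k), ia, ib, spec)
    if (nrow(fc) == 0) next
    keys <- paste(fc$res_a, fc$res_b, fc$kind, sep = "|")
    for (key in keys) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    empty <- data.frame(res_a = character(0), res_b = character(0),
                        kind = character(0), frequency = numeric(0))
    return(list(filtered = empty, full = empty))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  full <- data.frame(
    res_a = vapply(parts, `[`, "", 1), res_b = vapply(parts, `[`, "", 2),
    kind = vapply(parts, `[`, "", 3),
    frequency = vapply(keys, function(k) counts[[k]] / nf, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  full <- full[order(-full$frequency, full$res_a, full$res_b, full$kind), ]
  rownames(full) <- NULL
  list(filtered = full[full$frequency > spec$frequency_cutoff, ], full = full)
}

#' Occupancy grid of selected atoms over a trajectory
#'
#' Counts selected-atom visits per voxel; frames must be aligned beforehand.
#' Total counts equal `n_frames x n_selected`.
#'
#' @param traj a `mol_trajectory`.
#' @param selection `atom_selection`/indices counted.
#' @param spacing voxel edge in Angstrom (default 0.5).
#' @return list with `origin`, `spacing`, `dims` and `counts` (3D array).
#' @export
occupancy_grid <- function(traj, selection = NULL, spacing = 0.5) {
  sel <- .resolve_indices(selection, n_atoms(traj))
  all_xyz <- do.call(rbind, lapply(seq_len(n_frames(traj)), function(k) {
    frame_coords(traj, k)[sel, , drop = FALSE]
  }))
  lo <- apply(all_xyz, 2, min) - spacing / 2
  idx <- floor(sweep(all_xyz, 2, lo) / spacing) + 1
  dims <- apply(idx, 2, max)
  counts <- array(0L, dims)
  lin <- idx[, 1] + (idx[, 2] - 1) * dims[1] + (idx[, 3] - 1) * dims[1] * dims[2]
  tab <- table(lin)
  counts[as.integer(names(tab))] <- as.integer(tab)
  list(origin = lo, spacing = spacing, dims = dims, counts = counts)
}

#' Average structure after mass-weighted fitting
#'
#' Each frame is superposed onto the first frame by a mass-weighted fit over
#' `fit_selection`, then coordinates are averaged arithmetically.
#'
#' @param traj a `mol_trajectory`.
#' @param fit_selection `atom_selection`/indices used for the fit (default all).
#' @return a `mol_structure` with averaged coordinates.
#' @export
average_structure <- function(traj, fit_selection = NULL) {
  na <- n_atoms(traj)
  fit <- .resolve_indices(fit_selection, na)
  if (length(fit) < 3) stop("fit selection needs >= 3 atoms")
  ref <- frame_coords(traj, 1)
  w <- atomic_mass(traj$topology$atoms$element[fit])
  acc <- matrix(0, na, 3)
  for (k in seq_len(n_frames(traj))) {
    acc <- acc + superpose(frame_coords(traj, k), ref, fit, weights = w)$coords
  }
  set_coords(traj$topology, acc / n_frames(traj))
}
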