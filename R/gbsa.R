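# Single-trajectory MM/GBSA-style rescoring: all-pair Coulomb and
# Lennard-Jones molecular-mechanics terms, generalized Born polar solvation
# with pairwise descreening and OBC-style rescaling, and an LCPO surface-area
# nonpolar term. The solute entropic contribution is deliberately omitted, so
# totals are relative binding energies.

.COULOMB_K <- 332.0637   # kcal mol^-1 A e^-2
.GB_K <- 166.0319        # .COULOMB_K / 2

#' Per-atom energy parameters
#'
#' @param atoms data.frame with one row per atom: `serial`, `charge` (e),
#'   `gb_radius` (A), `screen` (GB descreening scale, default 0.8 when
#'   absent), `lj_sigma` (A), `lj_epsilon` (kcal/mol), and LCPO columns
#'   `lcpo_p1..lcpo_p4`, `lcpo_radius`.
#' @param dielectric_interior,dielectric_solvent relative dielectrics
#'   (defaults 1.0 and 78.5).
#' @param surface_tension gamma in kcal/mol/A^2 for the nonpolar term
#'   (default 0.0072).
#' @param surface_offset beta in kcal/mol added per species (default 0).
#' @return object of class `topology_params`.
#' @export
topology_params <- function(atoms, dielectric_interior = 1.0,
                            dielectric_solvent = 78.5,
                            surface_tension = 0.0072, surface_offset = 0) {
  need <- c("serial", "charge", "gb_radius", "lj_sigma", "lj_epsilon")
  if (!all(need %in% names(atoms))) {
    stop("topology lacks column(s): ", paste(setdiff(need, names(atoms)), collapse = ", "))
  }
  if (any(atoms$gb_radius <= 0)) stop("gb_radius must be > 0")
  if (dielectric_interior <= 0 || dielectric_solvent <= 0) stop("dielectrics must be > 0")
  if (is.null(atoms$screen)) atoms$screen <- 0.8
  for (col in c("lcpo_p1", "lcpo_p2", "lcpo_p3", "lcpo_p4")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- switch(col, lcpo_p1 = 1, lcpo_p2 = -1, 0)
  }
  if (is.null(atoms$lcpo_radius)) atoms$lcpo_radius <- atoms$gb_radius
  structure(list(atoms = atoms, dielectric_interior = dielectric_interior,
                 dielectric_solvent = dielectric_solvent,
                 surface_tension = surface_tension,
                 surface_offset = surface_offset),
            class = "topology_params")
}

#' Write / read a topology as CSV
#' @param topology a `topology_params`.
#' @param path CSV file path.
#' @return (read) a `topology_params` with default globals.
#' @export
write_topology <- function(topology, path) {
  write.csv(topology$atoms, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) topology_params(read.csv(path))

.subset_topology <- function(topology, idx) {
  topology$atoms <- topology$atoms[idx, , drop = FALSE]
  topology
}

#' Coulomb and Lennard-Jones pair energies
#'
#' All-pair (no cutoff) electrostatics `332.0637 q_i q_j / r_ij` and 12-6
#' Lennard-Jones with Lorentz-Berthelot combination. `pairs` restricts the
#' sum, e.g. to intermolecular pairs.
#'
#' @param coords coordinate matrix (n x 3).
#' @param topology a `topology_params` with n atom rows.
#' @param pairs optional 2-column integer matrix of atom-index pairs; default
#'   all unique i < j pairs.
#' @return list with `E_coulomb` and `E_lj` in kcal/mol.
#' @export
coulomb_lj_energy <- function(coords, topology, pairs = NULL) {
  a <- topology$atoms
  n <- nrow(coords)
  if (nrow(a) != n) stop("topology/coordinate atom count mismatch")
  if (is.null(pairs)) {
    pairs <- t(combn(n, 2))
  }
  i <- pairs[, 1]; j <- pairs[, 2]
  dv <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  if (any(r < 1e-6)) {
    k <- which(r < 1e-6)[1]
    stop("singularity: atoms ", i[k], " and ", j[k], " overlap")
  }
  ec <- sum(.COULOMB_K * a$charge[i] * a$charge[j] / r)
  sig <- (a$lj_sigma[i] + a$lj_sigma[j]) / 2
  eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
  sr6 <- (sig / r)^6
  elj <- sum(4 * eps * (sr6^2 - sr6))
  list(E_coulomb = ec, E_lj = elj)
}

# Effective Born radii via the pairwise descreening integral with OBC
# rescaling (alpha = 1.0, beta = 0.8, gamma = 4.85). Dielectric offset 0 so
# the isolated-ion effective radius equals its intrinsic radius exactly.
.effective_born_radii <- function(coords, topology,
                                  alpha = 1.0, beta = 0.8, gamma = 4.85) {
  a <- topology$atoms
  n <- nrow(coords)
  rho <- a$gb_radius
  s <- a$screen
  I <- numeric(n)
  for (i in seq_len(n)) {
    dv <- sweep(coords, 2, coords[i, ])
    r <- sqrt(rowSums(dv^2))
    for (j in seq_len(n)) {
      if (j == i) next
      sr <- s[j] * rho[j]
      if (r[j] + sr <= rho[i]) next  # j's descreening sphere inside i
      L <- max(rho[i], abs(r[j] - sr))
      U <- r[j] + sr
      term <- 0.5 * (1 / L - 1 / U +
                       0.25 * (r[j] - sr^2 / r[j]) * (1 / U^2 - 1 / L^2) +
                       0.5 * log(L / U) / r[j])
      if (rho[i] < sr - r[j]) term <- term + (1 / rho[i] - 1 / L)
      I[i] <- I[i] + term
    }
  }
  psi <- I * rho
  reff <- 1 / (1 / rho - tanh(alpha * psi - beta * psi^2 + gamma * psi^3) / rho)
  if (any(!is.finite(reff) | reff <= 0)) {
    bad <- which(!is.finite(reff) | reff <= 0)[1]
    stop("non-positive effective Born radius for atom serial ", a$serial[bad])
  }
  reff
}

#' Generalized Born polar solvation energy
#'
#' `G = -166.0319 (1/eps_in - 1/eps_solv) sum_ij q_i q_j / f_GB` over the full
#' double sum including self terms, with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))` and effective radii
#' from the pairwise-descreening integral with OBC rescaling.
#'
#' @param coords coordinate matrix (n x 3).
#' @param topology a `topology_params`.
#' @return list with `G_gb` (kcal/mol) and `effective_radii`.
#' @export
gb_polar <- function(coords, topology) {
  a <- topology$atoms
  q <- a$charge
  n <- nrow(coords)
  if (length(q) != n) stop("topology/coordinate atom count mismatch")
  pref <- -.GB_K * (1 / topology$dielectric_interior - 1 / topology$dielectric_solvent)
  reff <- .effective_born_radii(coords, topology)
  d2 <- as.matrix(dist(coords))^2
  rr <- outer(reff, reff)
  fgb <- sqrt(d2 + rr * exp(-d2 / (4 * rr)))
  g <- pref * sum(outer(q, q) / fgb)
  list(G_gb = g, effective_radii = reff)
}

#' Single-frame MM/GBSA energy decomposition
#'
#' Single-trajectory convention: complex, receptor and ligand energies are all
#' evaluated on the same frame coordinates, and
#' `dG = G(complex) - G(receptor) - G(ligand)`. The nonpolar term is
#' `gamma * SASA_LCPO + beta` per species; no entropy term.
#'
#' @param coords complex coordinate matrix (n x 3).
#' @param topology a `topology_params` for the complex.
#' @param receptor_idx,ligand_idx disjoint, covering atom index sets.
#' @param structure optional `mol_structure` for the complex; when NULL a
#'   bead-atom structure is synthesised from the topology for the LCPO term.
#' @return object of class `energy_decomposition`: list with `E_coulomb`,
#'   `E_lj`, `G_gb`, `G_np`, `G_total` (kcal/mol), each the
#'   complex-minus-parts difference.
#' @export
gbsa_frame <- function(coords, topology, receptor_idx, ligand_idx,
                       structure = NULL) {
  n <- nrow(coords)
  receptor_idx <- .resolve_indices(receptor_idx, n)
  ligand_idx <- .resolve_indices(ligand_idx, n)
  if (length(intersect(receptor_idx, ligand_idx)) > 0) {
    stop("receptor/ligand partition overlaps")
  }
  if (length(union(receptor_idx, ligand_idx)) != n) {
    stop("receptor/ligand partition must cover all atoms")
  }
  # MM interaction terms: intermolecular pairs only (intramolecular terms
  # cancel in the single-trajectory difference)
  pairs <- as.matrix(expand.grid(receptor_idx, ligand_idx))
  mm <- coulomb_lj_energy(coords, topology, pairs)
  # GB: complex minus parts
  g_cpx <- gb_polar(coords, topology)$G_gb
  g_rec <- gb_polar(coords[receptor_idx, , drop = FALSE],
                    .subset_topology(topology, receptor_idx))$G_gb
  g_lig <- gb_polar(coords[ligand_idx, , drop = FALSE],
                    .subset_topology(topology, ligand_idx))$G_gb
  dg_gb <- g_cpx - g_rec - g_lig
  # nonpolar: gamma * LCPO SASA + beta per species
  st <- if (is.null(structure)) .bead_structure(coords, topology) else structure
  lc_cpx <- lcpo_sasa(st, topology)$total
  lc_rec <- lcpo_sasa(.subset_structure(st, receptor_idx),
                      .subset_topology(topology, receptor_idx))$total
  lc_lig <- lcpo_sasa(.subset_structure(st, ligand_idx),
                      .subset_topology(topology, ligand_idx))$total
  gam <- topology$surface_tension
  bet <- topology$surface_offset
  dg_np <- (gam * lc_cpx + bet) - (gam * lc_rec + bet) - (gam * lc_lig + bet)
  out <- list(E_coulomb = mm$E_coulomb, E_lj = mm$E_lj,
              G_gb = dg_gb, G_np = dg_np,
              G_total = mm$E_coulomb + mm$E_lj + dg_gb + dg_np)
  class(out) <- "energy_decomposition"
  out
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("dG = %.3f kcal/mol (coul %.3f, LJ %.3f, GB %.3f, NP %.3f)%s\n",
              x$G_total, x$E_coulomb, x$E_lj, x$G_gb, x$G_np,
              if (!is.null(x$sem)) sprintf(" +/- %.3f SEM", x$sem) else ""))
  invisible(x)
}

# bead structure for LCPO when no mol_structure accompanies the topology
.bead_structure <- function(coords, topology) {
  n <- nrow(coords)
  mol_structure(data.frame(
    serial = seq_len(n), name = paste0("C", seq_len(n)), element = "C",
    resname = "UNK", resid = seq_len(n), chain = "X",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE
  ))
}

.subset_structure <- function(structure, idx) {
  structure$atoms <- structure$atoms[idx, , drop = FALSE]
  structure
}

#' Trajectory-averaged MM/GBSA energies
#'
#' Evaluates [gbsa_frame()] on every `frame_stride`-th frame and reports the
#' mean decomposition with the standard error of the mean over frames.
#'
#' @param traj a `mol_trajectory` of the complex.
#' @param topology a `topology_params`.
#' @param receptor_idx,ligand_idx partition of the atoms.
#' @param frame_stride keep every k-th frame (default 1).
#' @return list with `mean` (an `energy_decomposition`), `sem` (of `G_total`),
#'   and `per_frame` (data.frame of all terms per analysed frame).
#' @export
gbsa_trajectory <- function(traj, topology, receptor_idx, ligand_idx,
                            frame_stride = 1) {
  keep <- seq(1, n_frames(traj), by = frame_stride)
  if (length(keep) < 2) stop("need at least 2 frames after stride")
  rows <- lapply(keep, function(i) {
    e <- gbsa_frame(frame_coords(traj, i), topology, receptor_idx, ligand_idx,
                    structure = frame_structure(traj, i))
    data.frame(frame = i, E_coulomb = e$E_coulomb, E_lj = e$E_lj,
               G_gb = e$G_gb, G_np = e$G_np, G_total = e$G_total)
  })
  pf <- do.call(rbind, rows)
  m <- list(E_coulomb = mean(pf$E_coulomb), E_lj = mean(pf$E_lj),
            G_gb = mean(pf$G_gb), G_np = mean(pf$G_np),
            G_total = mean(pf$G_total),
            sem = sd(pf$G_total) / sqrt(nrow(pf)))
  class(m) <- "energy_decomposition"
  list(mean = m, sem = m$sem, per_frame = pf)
}
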