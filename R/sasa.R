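# Solvent-accessible surface area: numerical Shrake-Rupley on a deterministic
# golden-section sphere point set, and the LCPO analytic approximation used by
# the nonpolar solvation term.

# Deterministic quasi-uniform unit-sphere points (golden-section spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by test points on the solvent-expanded sphere of each atom;
#' a point is exposed when outside every neighbouring atom's expanded sphere.
#' Deterministic: the point set is a golden-section spiral, not random.
#'
#' @param structure a `mol_structure` with vdW radii assigned.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points test points per atom (default 960, minimum 96).
#' @param include_hydrogens logical; hydrogens are excluded by default
#'   (united-atom convention).
#' @param atom_subset optional integer indices: compute areas only for these
#'   atoms (every non-hydrogen atom still occludes); others report 0.
#' @return object of class `sasa_result`: list with `per_atom` (Angstrom^2,
#'   0 for skipped hydrogens), `per_residue`, `sidechain_per_residue` (named
#'   by "chain:resid"), `probe_radius`, `n_sphere_points`.
#' @export
shrake_rupley <- function(structure, probe_radius = 1.4, n_points = 960,
                          include_hydrogens = FALSE, atom_subset = NULL) {
  if (n_points < 96) stop("n_points must be >= 96")
  a <- structure$atoms
  xyz <- get_coords(structure)
  active <- if (include_hydrogens) rep(TRUE, nrow(a)) else toupper(a$element) != "H"
  idx <- which(active)
  compute <- if (is.null(atom_subset)) idx else intersect(idx, atom_subset)
  r_exp <- a$vdw + probe_radius
  pts <- .sphere_points(n_points)
  per_atom <- numeric(nrow(a))
  for (i in compute) {
    ri <- r_exp[i]
    # neighbours whose expanded spheres can clip atom i's test sphere
    d2 <- rowSums(sweep(xyz[idx, , drop = FALSE], 2, xyz[i, ])^2)
    nb <- idx[d2 < (ri + r_exp[idx])^2 & idx != i]
    test <- sweep(pts * ri, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(test, 2, xyz[j, ])^2)
      exposed <- exposed & dj2 > r_exp[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- sum(exposed) / n_points * 4 * pi * ri^2
  }
  reskey <- paste0(a$chain, ":", a$resid)
  per_res <- tapply(per_atom, reskey, sum)
  side <- !(a$name %in% .BACKBONE_NAMES)
  side_res <- tapply(per_atom * side, reskey, sum)
  base::structure(list(per_atom = per_atom,
                 per_residue = per_res[unique(reskey)],
                 sidechain_per_residue = side_res[unique(reskey)],
                 probe_radius = probe_radius, n_sphere_points = n_points),
            class = "sasa_result")
}

#' Side-chain SASA of one residue
#'
#' Sum of per-atom Shrake-Rupley areas over the residue's non-backbone heavy
#' atoms (backbone = N, CA, C, O). The whole-structure SASA is computed so
#' burial by any neighbouring atom is accounted for.
#'
#' @param structure a `mol_structure`.
#' @param residue_id residue identifier "chain:resid" (e.g. "B:2") or an
#'   integer residue index (searched across chains; must be unique).
#' @param probe_radius,n_points passed to [shrake_rupley()].
#' @param sasa optional precomputed `sasa_result` to avoid recomputation.
#' @return side-chain SASA in Angstrom^2.
#' @export
sidechain_sasa <- function(structure, residue_id, probe_radius = 1.4,
                           n_points = 960, sasa = NULL) {
  a <- structure$atoms
  reskey <- paste0(a$chain, ":", a$resid)
  if (is.numeric(residue_id)) {
    hits <- unique(reskey[a$resid == residue_id])
    if (length(hits) == 0) stop("residue ", residue_id, " not found")
    if (length(hits) > 1) stop("residue index ", residue_id,
                               " ambiguous across chains; use 'chain:resid'")
    residue_id <- hits
  }
  if (!residue_id %in% reskey) stop("residue ", residue_id, " not found")
  sel <- reskey == residue_id & !(a$name %in% .BACKBONE_NAMES)
  if (is.null(sasa)) {
    sasa <- shrake_rupley(structure, probe_radius = probe_radius,
                          n_points = n_points, atom_subset = which(sel))
  }
  sum(sasa$per_atom[sel])
}

#' LCPO approximate solvent-accessible surface area
#'
#' Linear Combination of Pairwise Overlaps: per-atom SASA approximated as
#' `P1*S1 + P2*sum_j A_ij + P3*sum_{j,k} A_jk + P4*sum_j (A_ij * sum_k A_jk)`
#' where `S1` is the full solvent-expanded sphere area and `A_ij` is the area
#' of sphere i buried inside neighbour j's expanded sphere. Negative per-atom
#' values are clamped to zero. Hydrogens are excluded.
#'
#' @param structure a `mol_structure`.
#' @param topology a `topology_params` object carrying per-atom LCPO
#'   coefficients `lcpo_p1..lcpo_p4` and `lcpo_radius` (vdW radius used by the
#'   overlap formula); when NULL, the structure's vdW radii with neutral
#'   coefficients P = (1, -1, 0, 0) are used (exact for isolated pairs).
#' @param probe_radius solvent probe radius (default 1.4).
#' @return list with `per_atom` (Angstrom^2) and `total`.
#' @export
lcpo_sasa <- function(structure, topology = NULL, probe_radius = 1.4) {
  a <- structure$atoms
  xyz <- get_coords(structure)
  n <- nrow(a)
  heavy <- toupper(a$element) != "H"
  if (!is.null(topology)) {
    tp <- topology$atoms
    need <- c("lcpo_p1", "lcpo_p2", "lcpo_p3", "lcpo_p4", "lcpo_radius")
    if (!all(need %in% names(tp))) {
      stop("topology lacks LCPO coefficient column(s): ",
           paste(setdiff(need, names(tp)), collapse = ", "))
    }
    if (nrow(tp) != n) stop("topology/structure atom count mismatch")
    miss <- heavy & (is.na(tp$lcpo_p1) | is.na(tp$lcpo_radius))
    if (any(miss)) {
      stop("missing LCPO coefficients for atom serial ", a$serial[which(miss)[1]])
    }
    P <- cbind(tp$lcpo_p1, tp$lcpo_p2, tp$lcpo_p3, tp$lcpo_p4)
    rad <- tp$lcpo_radius
  } else {
    P <- matrix(rep(c(1, -1, 0, 0), each = n), nrow = n)
    rad <- a$vdw
  }
  r <- rad + probe_radius
  per_atom <- numeric(n)
  hv <- which(heavy)
  # pairwise buried areas A[i,j]: area of sphere i inside sphere j
  d <- as.matrix(dist(xyz[hv, , drop = FALSE]))
  ri <- r[hv]
  nh <- length(hv)
  A <- matrix(0, nh, nh)
  for (ii in seq_len(nh)) {
    for (jj in seq_len(nh)) {
      if (ii == jj) next
      dij <- d[ii, jj]
      if (dij >= ri[ii] + ri[jj] || dij < 1e-9) next
      if (dij + ri[ii] <= ri[jj]) {          # sphere i fully inside j
        A[ii, jj] <- 4 * pi * ri[ii]^2
      } else if (dij + ri[jj] <= ri[ii]) {   # j inside i: surface of i untouched
        A[ii, jj] <- 0
      } else {
        A[ii, jj] <- 2 * pi * ri[ii] *
          (ri[ii] - dij / 2 - (ri[ii]^2 - ri[jj]^2) / (2 * dij))
      }
    }
  }
  A[A < 0] <- 0
  rowA <- rowSums(A)
  for (ii in seq_len(nh)) {
    i <- hv[ii]
    nbrs <- which(A[ii, ] > 0)
    s1 <- 4 * pi * ri[ii]^2
    t2 <- sum(A[ii, nbrs])
    t3 <- 0
    t4 <- 0
    if (length(nbrs) > 0) {
      for (jj in nbrs) {
        # neighbours of i that also overlap j
        common <- nbrs[nbrs != jj & A[jj, nbrs] > 0]
        ajk <- sum(A[jj, common])
        t3 <- t3 + ajk
        t4 <- t4 + A[ii, jj] * ajk
      }
    }
    per_atom[i] <- max(0, P[i, 1] * s1 + P[i, 2] * t2 + P[i, 3] * t3 + P[i, 4] * t4)
  }
  list(per_atom = per_atom, total = sum(per_atom))
}
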