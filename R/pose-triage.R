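# NMR-informed pose triage: exclude ensemble-docking poses whose designated
# aromatic side chain is too solvent-exposed, then pick the top pose per
# scoring annotation (Vina-like, CNN pose score, CNN affinity).

#' Construct a pose record
#'
#' @param pose_id unique string identifier.
#' @param complex_structure `mol_structure` of receptor + peptide.
#' @param peptide_chain chain id of the peptide in the complex.
#' @param scores named list/vector with `vina` (lower is better), `cnn_score`
#'   (0..1, higher is better), `cnn_affinity` (higher is better).
#' @param aromatic_residue residue id "chain:resid" of the aromatic residue
#'   whose side-chain burial the filter tests.
#' @return object of class `pose_record` (field `aromatic_sasa` filled lazily
#'   by [sasa_filter()]).
#' @export
pose_record <- function(pose_id, complex_structure, peptide_chain, scores,
                        aromatic_residue) {
  need <- c("vina", "cnn_score", "cnn_affinity")
  miss <- setdiff(need, names(scores))
  if (length(miss) > 0) {
    stop("pose ", pose_id, " missing score(s): ", paste(miss, collapse = ", "))
  }
  structure(list(pose_id = pose_id, complex_structure = complex_structure,
                 peptide_chain = peptide_chain,
                 scores = as.list(scores)[need],
                 aromatic_residue = aromatic_residue,
                 aromatic_sasa = NA_real_),
            class = "pose_record")
}

#' SASA exclusion filter on a pose ensemble
#'
#' Computes the Shrake-Rupley side-chain SASA of each pose's designated
#' aromatic residue and excludes poses where it exceeds the cutoff
#' (strictly-greater excluded, so a pose at exactly the cutoff is retained;
#' set `strict_less = TRUE` to flip the boundary).
#'
#' @param poses list of `pose_record`s.
#' @param sasa_cutoff Angstrom^2 (default 20).
#' @param strict_less retain only strictly-below-cutoff poses when TRUE.
#' @param probe_radius,n_points passed to [shrake_rupley()].
#' @return list with `retained` (pose records, `aromatic_sasa` filled) and
#'   `audit` (data.frame: pose_id, aromatic_sasa, retained) covering every
#'   input pose exactly once.
#' @export
sasa_filter <- function(poses, sasa_cutoff = 20, strict_less = FALSE,
                        probe_radius = 1.4, n_points = 960) {
  if (length(poses) == 0) {
    return(list(retained = list(),
                audit = data.frame(pose_id = character(0),
                                   aromatic_sasa = numeric(0),
                                   retained = logical(0))))
  }
  vals <- vapply(poses, function(p) {
    st <- p$complex_structure
    reskey <- paste0(st$atoms$chain, ":", st$atoms$resid)
    if (!p$aromatic_residue %in% reskey) {
      stop("pose ", p$pose_id, ": aromatic residue ", p$aromatic_residue,
           " absent from complex")
    }
    sidechain_sasa(st, p$aromatic_residue, probe_radius = probe_radius,
                   n_points = n_points)
  }, numeric(1))
  keep <- if (strict_less) vals < sasa_cutoff else vals <= sasa_cutoff
  for (i in seq_along(poses)) poses[[i]]$aromatic_sasa <- vals[i]
  audit <- data.frame(pose_id = vapply(poses, function(p) p$pose_id, ""),
                      aromatic_sasa = vals, retained = keep,
                      stringsAsFactors = FALSE)
  list(retained = poses[keep], audit = audit)
}

#' Top pose per scoring function
#'
#' Pose #1 minimises the Vina-like score, pose #2 maximises the CNN pose
#' score, pose #3 maximises the CNN affinity. One pose may fill several slots.
#' Ties are broken by lexicographic pose id (and logged in the result).
#'
#' @param poses non-empty list of `pose_record`s.
#' @return list with `pose1`, `pose2`, `pose3` (pose records), `ids`
#'   (character vector) and `ties` (character vector of tie notes, possibly
#'   empty).
#' @export
select_top_poses <- function(poses) {
  if (length(poses) == 0) stop("no poses to select from")
  ids <- vapply(poses, function(p) p$pose_id, "")
  getscore <- function(key) {
    vapply(seq_along(poses), function(i) {
      v <- poses[[i]]$scores[[key]]
      if (is.null(v) || is.na(v)) stop("pose ", ids[i], " missing score '", key, "'")
      as.numeric(v)
    }, numeric(1))
  }
  ties <- character(0)
  pick <- function(vals, best_is_min, key) {
    target <- if (best_is_min) min(vals) else max(vals)
    cand <- which(vals == target)
    if (length(cand) > 1) {
      cand <- cand[order(ids[cand])]
      ties <<- c(ties, paste0(key, ": tie among {",
                              paste(ids[cand], collapse = ", "),
                              "}; '", ids[cand[1]], "' wins lexicographically"))
    }
    cand[1]
  }
  i1 <- pick(getscore("vina"), TRUE, "vina")
  i2 <- pick(getscore("cnn_score"), FALSE, "cnn_score")
  i3 <- pick(getscore("cnn_affinity"), FALSE, "cnn_affinity")
  list(pose1 = poses[[i1]], pose2 = poses[[i2]], pose3 = poses[[i3]],
       ids = c(pose1 = ids[i1], pose2 = ids[i2], pose3 = ids[i3]),
       ties = ties)
}
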