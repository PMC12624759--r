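# Rigid-body geometry primitives: weighted Kabsch superposition, RMSD,
# center of mass.

.as_coords <- function(x) {
  if (inherits(x, "mol_structure")) return(get_coords(x))
  m <- as.matrix(x)
  if (ncol(m) != 3) stop("coordinate set must have 3 columns")
  m
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' mass-weighted) RMSD between `mobile` and `reference` over `fit_indices`,
#' and applies it to all atoms of `mobile`.
#'
#' @param mobile coordinate matrix (n x 3) or `mol_structure`.
#' @param reference coordinate matrix or `mol_structure` with matching indices.
#' @param fit_indices `atom_selection` or integer vector (default: all atoms).
#' @param weights optional per-fit-atom weights (e.g. masses).
#' @return list with `rotation` (3 x 3, det = +1), `translation` (length 3),
#'   `coords` (all mobile atoms after fitting) and `rmsd` (over fit atoms,
#'   weighted if weights given). Fitted coordinates satisfy
#'   `coords = mobile %*% rotation + translation` (row-vector convention).
#' @export
superpose <- function(mobile, reference, fit_indices = NULL, weights = NULL) {
  mob <- .as_coords(mobile)
  ref <- .as_coords(reference)
  idx <- .resolve_indices(fit_indices, nrow(mob))
  if (length(idx) < 3) stop("degenerate fit: need at least 3 fit atoms")
  if (max(idx) > nrow(ref)) stop("structural mismatch: reference lacks fit atoms")
  x <- mob[idx, , drop = FALSE]
  y <- ref[idx, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, length(idx)) else {
    if (length(weights) != length(idx)) stop("weights length must match fit atoms")
    as.numeric(weights)
  }
  w <- w / sum(w)
  cx <- colSums(x * w)
  cy <- colSums(y * w)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  # collinearity check: centered fit atoms must span at least 2 dimensions
  if (qr(xc)$rank < 2) stop("degenerate fit: fit atoms are collinear")
  h <- t(xc * w) %*% yc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)  # row convention: x %*% rot
  trans <- cy - as.vector(cx %*% rot)
  fitted <- sweep(mob %*% rot, 2, trans, `+`)
  fit_rmsd <- sqrt(sum(w * rowSums((sweep(x %*% rot, 2, trans, `+`) - y)^2)))
  list(rotation = rot, translation = trans, coords = fitted, rmsd = fit_rmsd)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' No fitting is performed; use [superpose()] first if alignment is wanted.
#'
#' @param a,b coordinate matrices (n x 3) or `mol_structure`s.
#' @param indices `atom_selection` or integer vector (default: all atoms).
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(a, b, indices = NULL) {
  ca <- .as_coords(a)
  cb <- .as_coords(b)
  idx <- .resolve_indices(indices, nrow(ca))
  if (max(c(idx, 0)) > nrow(cb)) stop("structural mismatch: index beyond second set")
  if (nrow(ca) != nrow(cb) && is.null(indices)) {
    stop("structural mismatch: coordinate sets differ in size (",
         nrow(ca), " vs ", nrow(cb), ")")
  }
  if (length(idx) == 0) stop("empty selection for RMSD")
  sqrt(mean(rowSums((ca[idx, , drop = FALSE] - cb[idx, , drop = FALSE])^2)))
}

#' Center of mass of a coordinate set
#'
#' @param coords coordinate matrix (n x 3) or `mol_structure`. If a structure
#'   is given and `weights` is NULL, atomic masses from the element table are
#'   used; for a bare matrix the unweighted mean is returned.
#' @param indices `atom_selection` or integer vector (default: all atoms).
#' @param weights optional per-selected-atom weights.
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(coords, indices = NULL, weights = NULL) {
  is_struct <- inherits(coords, "mol_structure")
  xyz <- .as_coords(coords)
  idx <- .resolve_indices(indices, nrow(xyz))
  if (length(idx) == 0) stop("empty selection for center of mass")
  w <- if (!is.null(weights)) {
    if (length(weights) != length(idx)) stop("weights length must match selection")
    as.numeric(weights)
  } else if (is_struct) {
    atomic_mass(coords$atoms$element[idx])
  } else {
    rep(1, length(idx))
  }
  colSums(xyz[idx, , drop = FALSE] * w) / sum(w)
}
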