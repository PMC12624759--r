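# Grid-based cavity detection: embed the structure in a 1 A lattice, mark
# probe-inflated protein occupancy, score the buriedness of the remaining
# points by ray casting, clean with binary erosion/dilation, and report
# 6-connected cavity components with voxel volumes.

.STATE_CANDIDATE <- 0L
.STATE_PROTEIN <- 1L
.STATE_EXCLUDED <- 2L

# out[i,j,k] = arr[i+dx, j+dy, k+dz], FALSE outside the grid
.shift3 <- function(arr, dx, dy, dz) {
  d <- dim(arr)
  out <- array(FALSE, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(xs) < 1 || length(ys) < 1 || length(zs) < 1) return(out)
  out[xs - dx, ys - dy, zs - dz] <- arr[xs, ys, zs]
  out
}

.ray_directions <- function(n_rays) {
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  edges <- unique(rbind(
    as.matrix(expand.grid(c(-1, 1), c(-1, 1), 0)),
    as.matrix(expand.grid(c(-1, 1), 0, c(-1, 1))),
    as.matrix(expand.grid(0, c(-1, 1), c(-1, 1)))
  ))
  switch(as.character(n_rays),
         "6" = axes,
         "14" = rbind(axes, corners),
         "26" = rbind(axes, corners, edges),
         stop("n_rays must be 6, 14 or 26"))
}

#' Build the occupancy grid around a structure
#'
#' Voxels whose centers lie within (vdW radius + probe radius) of any atom
#' center are marked protein; all others start as candidate pocket points.
#'
#' @param structure a `mol_structure`.
#' @param spacing grid resolution in Angstrom (default 1.0).
#' @param probe_radius probe inflation radius in Angstrom (default 1.2).
#' @return object of class `pocket_grid`: list with `origin`, `spacing`,
#'   `dims`, `state` (integer array: 0 candidate, 1 protein, 2 excluded),
#'   `buriedness` (filled by [buriedness_scan()]), plus the parameters.
#' @export
build_grid <- function(structure, spacing = 1.0, probe_radius = 1.2) {
  if (spacing <= 0) stop("spacing must be > 0")
  a <- structure$atoms
  xyz <- get_coords(structure)
  pad <- 2 * max(a$vdw) + probe_radius
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  state <- array(.STATE_CANDIDATE, dims)
  rcut <- a$vdw + probe_radius
  for (i in seq_len(nrow(a))) {
    # voxel-index box around atom i, then exact distance test on centers
    ctr <- (xyz[i, ] - lo) / spacing + 1
    rv <- rcut[i] / spacing
    xs <- max(1, floor(ctr[1] - rv)):min(dims[1], ceiling(ctr[1] + rv))
    ys <- max(1, floor(ctr[2] - rv)):min(dims[2], ceiling(ctr[2] + rv))
    zs <- max(1, floor(ctr[3] - rv)):min(dims[3], ceiling(ctr[3] + rv))
    dx2 <- (xs - ctr[1])^2
    dy2 <- (ys - ctr[2])^2
    dz2 <- (zs - ctr[3])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= rv^2
    sub <- state[xs, ys, zs, drop = FALSE]
    sub[inside] <- .STATE_PROTEIN
    state[xs, ys, zs] <- sub
  }
  base::structure(list(origin = lo, spacing = spacing, dims = dims, state = state,
                 buriedness = NULL, probe_radius = probe_radius,
                 n_rays = NULL, burial_threshold = NULL),
            class = "pocket_grid")
}

#' @export
print.pocket_grid <- function(x, ...) {
  cat(sprintf("<pocket_grid> %d x %d x %d @ %.2f A; protein %d, candidate %d, excluded %d\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              sum(x$state == .STATE_PROTEIN), sum(x$state == .STATE_CANDIDATE),
              sum(x$state == .STATE_EXCLUDED)))
  invisible(x)
}

#' Buriedness scan of candidate voxels
#'
#' For each candidate voxel, counts how many of `n_rays` lattice directions
#' (6 axes, optionally 8 corner and 12 edge diagonals) hit a protein voxel
#' within `max_range`. Candidates with buriedness below `threshold` are
#' excluded.
#'
#' @param grid a `pocket_grid` from [build_grid()].
#' @param n_rays 6, 14 (default) or 26 scan directions.
#' @param max_range ray range in Angstrom (default 10).
#' @param threshold minimum buriedness kept (default 9).
#' @return the grid with `buriedness` filled and low-buriedness candidates
#'   marked excluded.
#' @export
buriedness_scan <- function(grid, n_rays = 14, max_range = 10, threshold = 9) {
  dirs <- .ray_directions(n_rays)
  protein <- grid$state == .STATE_PROTEIN
  bur <- array(0L, grid$dims)
  for (k in seq_len(nrow(dirs))) {
    dvec <- dirs[k, ]
    steplen <- grid$spacing * sqrt(sum(dvec^2))
    nsteps <- floor(max_range / steplen)
    hit <- array(FALSE, grid$dims)
    for (s in seq_len(nsteps)) {
      hit <- hit | .shift3(protein, s * dvec[1], s * dvec[2], s * dvec[3])
    }
    bur <- bur + hit
  }
  grid$buriedness <- bur
  kill <- grid$state == .STATE_CANDIDATE & bur < threshold
  grid$state[kill] <- .STATE_EXCLUDED
  grid$n_rays <- n_rays
  grid$burial_threshold <- threshold
  grid
}

# one binary erosion / dilation step with the 6-connected structuring element
.erode6 <- function(mask) {
  out <- mask
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    out <- out & .shift3(mask, d[1], d[2], d[3])
  }
  out
}

.dilate6 <- function(mask) {
  out <- mask
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    out <- out | .shift3(mask, d[1], d[2], d[3])
  }
  out
}

#' Morphological cleanup of the candidate set
#'
#' Binary erosion then dilation (an opening when steps are equal) with a
#' 6-connected structuring element, removing voxel-scale noise and smoothing
#' pocket boundaries. Dilation never re-enters protein voxels. Identity when
#' both step counts are zero.
#'
#' @param grid a `pocket_grid` after [buriedness_scan()].
#' @param erode_steps,dilate_steps non-negative iteration counts (default 1, 1).
#' @return the grid with the candidate set replaced by the cleaned mask.
#' @export
morph_clean <- function(grid, erode_steps = 1, dilate_steps = 1) {
  mask <- grid$state == .STATE_CANDIDATE
  if (erode_steps > 0) for (i in seq_len(erode_steps)) mask <- .erode6(mask)
  if (dilate_steps > 0) for (i in seq_len(dilate_steps)) mask <- .dilate6(mask)
  mask <- mask & grid$state != .STATE_PROTEIN
  newstate <- grid$state
  newstate[grid$state == .STATE_CANDIDATE & !mask] <- .STATE_EXCLUDED
  newstate[mask] <- .STATE_CANDIDATE
  grid$state <- newstate
  grid
}

# 6-connected component labels of a logical mask; 0 where mask is FALSE
.label_components6 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  lin <- which(mask)
  nxt <- 0L
  nd12 <- d[1] * d[2]
  neighbours <- function(v) {
    i <- ((v - 1) %% d[1]) + 1
    j <- ((v - 1) %/% d[1]) %% d[2] + 1
    k <- (v - 1) %/% nd12 + 1
    out <- c(
      ifelse(i > 1, v - 1L, NA), ifelse(i < d[1], v + 1L, NA),
      ifelse(j > 1, v - d[1], NA), ifelse(j < d[2], v + d[1], NA),
      ifelse(k > 1, v - nd12, NA), ifelse(k < d[3], v + nd12, NA)
    )
    out[!is.na(out)]
  }
  for (seed in lin) {
    if (labels[seed] != 0L) next
    nxt <- nxt + 1L
    frontier <- seed
    labels[seed] <- nxt
    while (length(frontier) > 0) {
      nb <- unique(unlist(lapply(frontier, neighbours)))
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- nxt
      frontier <- nb
    }
  }
  labels
}

#' Label pocket components and measure voxel volumes
#'
#' 6-connected components of the surviving candidate voxels; components below
#' `min_volume` are dropped; volume = voxel count x spacing^3. Lining residues
#' are residues with any atom within (vdW + probe + spacing) of a pocket voxel
#' center.
#'
#' @param grid a `pocket_grid` after [morph_clean()].
#' @param structure the `mol_structure` the grid was built from (for lining
#'   residues); may be NULL to skip lining assignment.
#' @param min_volume smallest reported pocket volume, Angstrom^3 (default 30).
#' @return list of `pocket` objects ordered by volume descending, each with
#'   `label`, `voxels` (linear indices), `volume`, `centroid`,
#'   `lining_residues` (character "chain:resid:resname"), `hydrophobic_score`
#'   (NA until [rank_pockets()]).
#' @export
label_pockets <- function(grid, structure = NULL, min_volume = 30) {
  mask <- grid$state == .STATE_CANDIDATE
  labels <- .label_components6(mask)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  pockets <- list()
  for (id in ids) {
    vox <- which(labels == id)
    vol <- length(vox) * grid$spacing^3
    if (vol < min_volume) next
    ind <- arrayInd(vox, grid$dims)
    centers <- sweep((ind - 1) * grid$spacing, 2, grid$origin, `+`)
    lining <- character(0)
    if (!is.null(structure)) {
      a <- structure$atoms
      xyz <- get_coords(structure)
      cut <- a$vdw + grid$probe_radius + grid$spacing
      near <- vapply(seq_len(nrow(a)), function(i) {
        min(sqrt(rowSums(sweep(centers, 2, xyz[i, ])^2))) <= cut[i]
      }, logical(1))
      lining <- unique(paste0(a$chain[near], ":", a$resid[near], ":", a$resname[near]))
    }
    pockets[[length(pockets) + 1]] <- base::structure(
      list(label = id, voxels = vox, volume = vol,
           centroid = colMeans(centers), lining_residues = lining,
           hydrophobic_score = NA_real_),
      class = "pocket"
    )
  }
  ord <- order(vapply(pockets, function(p) p$volume, numeric(1)), decreasing = TRUE)
  pockets[ord]
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket %d> volume %.1f A^3, centroid (%.1f, %.1f, %.1f), %d lining residues\n",
              x$label, x$volume, x$centroid[1], x$centroid[2], x$centroid[3],
              length(x$lining_residues)))
  invisible(x)
}

#' Rank pockets by volume and hydrophobicity
#'
#' The hydrophobic score is the fraction of lining residues in the
#' hydrophobic class (A, V, L, I, M, F, W, P) - a residue-class surrogate for
#' a hydrophobic-probe field, not equivalent to it.
#'
#' @param pockets list of `pocket` objects from [label_pockets()].
#' @param weights length-2 numeric c(volume, hydrophobicity); volumes are
#'   normalised by the largest pocket before weighting.
#' @return the pockets, hydrophobic scores filled, reordered by the weighted
#'   rank score (descending).
#' @export
rank_pockets <- function(pockets, weights = c(volume = 1, hydrophobicity = 1)) {
  if (length(pockets) == 0) return(pockets)
  hydro3 <- .AA3[.HYDROPHOBIC_RESIDUES]
  for (i in seq_along(pockets)) {
    lin <- pockets[[i]]$lining_residues
    resn <- vapply(strsplit(lin, ":"), function(x) x[3], character(1))
    pockets[[i]]$hydrophobic_score <- if (length(resn) > 0) mean(resn %in% hydro3) else 0
  }
  vols <- vapply(pockets, function(p) p$volume, numeric(1))
  hyd <- vapply(pockets, function(p) p$hydrophobic_score, numeric(1))
  score <- weights[1] * vols / max(vols) + weights[2] * hyd
  pockets[order(score, decreasing = TRUE)]
}

#' Detect pockets in one call
#'
#' Convenience wrapper: [build_grid()], [buriedness_scan()], [morph_clean()],
#' [label_pockets()], [rank_pockets()].
#'
#' @param structure a `mol_structure`.
#' @param spacing,probe_radius grid parameters.
#' @param n_rays,max_range,burial_threshold buriedness parameters.
#' @param erode_steps,dilate_steps morphology parameters.
#' @param min_volume smallest reported pocket (Angstrom^3).
#' @param weights ranking weights, see [rank_pockets()].
#' @return ranked list of `pocket` objects.
#' @export
find_pockets <- function(structure, spacing = 1.0, probe_radius = 1.2,
                         n_rays = 14, max_range = 10, burial_threshold = 9,
                         erode_steps = 1, dilate_steps = 1, min_volume = 30,
                         weights = c(volume = 1, hydrophobicity = 1)) {
  g <- build_grid(structure, spacing = spacing, probe_radius = probe_radius)
  g <- buriedness_scan(g, n_rays = n_rays, max_range = max_range,
                       threshold = burial_threshold)
  g <- morph_clean(g, erode_steps = erode_steps, dilate_steps = dilate_steps)
  rank_pockets(label_pockets(g, structure, min_volume = min_volume), weights)
}
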