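# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (loops, closed forms, eigen decompositions) and share no
# code with the package internals.

# Horn's quaternion method: minimal RMSD of b onto a (both n x 3), computed
# without constructing the rotation explicitly.
oracle_quaternion_rmsd <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  w <- if (is.null(weights)) rep(1, n) else weights / sum(weights) * n
  cm <- colSums(mobile * w) / sum(w)
  cr <- colSums(reference * w) / sum(w)
  x <- sweep(mobile, 2, cm)
  y <- sweep(reference, 2, cr)
  S <- t(x * w) %*% y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(w * rowSums(x^2)) + sum(w * rowSums(y^2)) - 2 * lmax) / sum(w)
  sqrt(max(0, msd))
}

# brute-force 6-connected binary erosion/dilation on a 3D logical array
oracle_erode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- TRUE
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + s[1]; jj <- j + s[2]; kk <- k + s[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          !mask[ii, jj, kk]) { nb <- FALSE; break }
    }
    out[i, j, k] <- nb
  }
  out
}

oracle_dilate <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) next
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + s[1]; jj <- j + s[2]; kk <- k + s[3]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && kk >= 1 && kk <= d[3] &&
          mask[ii, jj, kk]) { out[i, j, k] <- TRUE; break }
    }
  }
  out
}

# flood fill from a voxel index (6-connectivity) over a logical mask; returns
# the voxel count of the connected component
oracle_flood_count <- function(mask, start) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  stack <- list(start)
  count <- 0
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (seen[v[1], v[2], v[3]] || !mask[v[1], v[2], v[3]]) next
    seen[v[1], v[2], v[3]] <- TRUE
    count <- count + 1
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      w <- v + s
      if (all(w >= 1) && all(w <= d) && !seen[w[1], w[2], w[3]]) {
        stack[[length(stack) + 1]] <- w
      }
    }
  }
  count
}

# independent clustering metrics (naive loops)
oracle_cluster_metrics <- function(features, labels) {
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  n <- nrow(features)
  gm <- colMeans(features)
  sst <- 0
  for (i in seq_len(n)) sst <- sst + sum((features[i, ] - gm)^2)
  cent <- lapply(ks, function(k) colMeans(features[labels == k, , drop = FALSE]))
  sse <- 0
  for (i in seq_len(n)) sse <- sse + sum((features[i, ] - cent[[labels[i]]])^2)
  s <- vapply(ks, function(k) {
    rows <- which(labels == k)
    mean(vapply(rows, function(i) sqrt(sum((features[i, ] - cent[[k]])^2)), 0))
  }, 0)
  dbi <- mean(vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }, 0))
  }, 0))
  k <- length(ks)
  list(DBI = dbi,
       psF = ((sst - sse) / (k - 1)) / (sse / (n - k)),
       R2 = 1 - sse / sst)
}

# brute-force tryptic fragment enumeration: all (start, end) pairs bounded by
# cut sites, filtered by per-residue and global missed-cleavage caps
oracle_digest <- function(sequence, proline_rule = TRUE,
                          kmax = 3, rmax = 2, global_max = 3) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut <- which(res %in% c("K", "R"))
  if (proline_rule) cut <- cut[!(cut < n & res[cut + 1] == "P")]
  cut <- setdiff(cut, n)
  bounds <- c(0, cut, n)
  frags <- character(0)
  for (i in seq_len(length(bounds) - 1)) {
    for (j in seq(i + 1, length(bounds))) {
      internal <- bounds[bounds > bounds[i] & bounds < bounds[j]]
      if (length(internal) > global_max) next
      if (sum(res[internal] == "K") > kmax) next
      if (sum(res[internal] == "R") > rmax) next
      frags <- c(frags, paste0(substr(sequence, bounds[i] + 1, bounds[j]),
                               "@", bounds[i] + 1, "-", bounds[j]))
    }
  }
  sort(frags)
}

# shared tiny fixtures ------------------------------------------------------

# a synthetic 3-residue peptide PDB text (glycine-like), 4 atoms per residue
make_tripeptide_pdb <- function() {
  lines <- character(0)
  serial <- 0
  for (r in 1:3) {
    base <- c(3.8 * (r - 1), 0, 0)
    for (at in list(c("N", "N", -1.4, 0, 0), c("CA", "C", 0, 0, 0),
                    c("C", "C", 0.9, 1.1, 0), c("O", "O", 0.6, 2.3, 0))) {
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, at[1], r,
        base[1] + as.numeric(at[3]), base[2] + as.numeric(at[4]),
        base[3] + as.numeric(at[5]), at[2]))
    }
  }
  lines
}

# synthetic 160-residue single-chain backbone (N, CA, C, O per residue)
make_long_chain <- function(n_res = 160) {
  rows <- list()
  serial <- 0
  for (r in seq_len(n_res)) {
    base <- c(1.5 * r, 3 * sin(r / 5), 3 * cos(r / 5))
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    off <- rbind(c(-1.2, 0, 0), c(0, 0, 0), c(0.9, 1.0, 0), c(0.7, 2.2, 0))
    for (k in 1:4) {
      serial <- serial + 1
      rows[[serial]] <- data.frame(
        serial = serial, name = nm[k], element = el[k], resname = "ALA",
        resid = r, chain = "A",
        x = base[1] + off[k, 1], y = base[2] + off[k, 2], z = base[3] + off[k, 3],
        stringsAsFactors = FALSE)
    }
  }
  mol_structure(do.call(rbind, rows))
}

random_structure <- function(n = 10, seed = 1) {
  set.seed(seed)
  xyz <- matrix(rnorm(n * 3, sd = 3), n, 3)
  mol_structure(data.frame(
    serial = seq_len(n), name = paste0("C", seq_len(n)), element = "C",
    resname = "DUM", resid = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}
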