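# Summaries of printed experiment tables: SPR per-concentration kinetics and
# STD-NMR group epitope mapping (GEM).

#' Summarise an SPR kinetics table
#'
#' Plain (unweighted) arithmetic means of the per-concentration fitted
#' constants, plus a per-row consistency diagnostic flagging rows where
#' kd/ka deviates from the reported KD by more than `tol` (relative).
#'
#' @param table data.frame with columns `ka` (1/(M s)), `kd` (1/s), `KD` (M);
#'   other columns (e.g. analyte concentration) are passed through.
#' @param tol relative tolerance for the kd/ka vs KD diagnostic (default 0.1).
#' @return list with `mean_ka`, `mean_kd`, `mean_KD` and `diagnostics`
#'   (data.frame of inconsistent rows with their implied KD).
#' @export
kinetics_summary <- function(table, tol = 0.1) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("empty kinetics table")
  if (!all(c("ka", "kd", "KD") %in% names(table))) {
    stop("kinetics table needs columns ka, kd, KD")
  }
  if (any(table$ka <= 0 | table$kd <= 0 | table$KD <= 0)) {
    stop("rate and affinity constants must be positive")
  }
  implied <- table$kd / table$ka
  bad <- abs(implied - table$KD) / table$KD > tol
  diagnostics <- cbind(table[bad, , drop = FALSE], implied_KD = implied[bad])
  rownames(diagnostics) <- NULL
  list(mean_ka = mean(table$ka), mean_kd = mean(table$kd),
       mean_KD = mean(table$KD), diagnostics = diagnostics)
}

#' Group epitope mapping from STD integrals
#'
#' Normalises each proton's STD integral to the most strongly interacting
#' proton, which is set to exactly 100 percent.
#'
#' @param integrals named numeric vector of STD integrals (>= 0), one per
#'   proton label.
#' @return named numeric vector of percentages in (0, 100]; all tied maxima
#'   report exactly 100.
#' @export
gem_map <- function(integrals) {
  if (length(integrals) == 0) stop("no STD integrals supplied")
  if (any(integrals < 0)) stop("STD integrals must be >= 0")
  m <- max(integrals)
  if (m <= 0) stop("all STD integrals are zero; cannot normalise")
  pct <- 100 * integrals / m
  pct[integrals == m] <- 100  # exact at the reference proton(s)
  pct
}
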