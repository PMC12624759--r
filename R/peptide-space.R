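# Tripeptide chemical library enumeration and bookkeeping.

#' Construct a peptide species
#'
#' @param sequence 1-letter amino-acid string (upper case).
#' @param c_terminal_amide logical; C-terminal amidation (default TRUE, the
#'   library convention).
#' @param n_terminal_free logical; free N-terminus (default TRUE).
#' @param fixed_mods,variable_mods lists of `list(position, delta, name)`
#'   modifications (delta in amu).
#' @return object of class `peptide_species` with `monoisotopic_mass` and
#'   `net_charge_pH7` filled in.
#' @export
peptide_species <- function(sequence, c_terminal_amide = TRUE,
                            n_terminal_free = TRUE,
                            fixed_mods = list(), variable_mods = list()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) stop("empty peptide sequence")
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% names(.RESIDUE_MASSES))) {
    bad <- setdiff(res, names(.RESIDUE_MASSES))
    stop("alphabet error: unknown residue letter(s) ", paste(bad, collapse = ", "))
  }
  p <- structure(
    list(sequence = sequence, c_terminal_amide = c_terminal_amide,
         n_terminal_free = n_terminal_free,
         fixed_mods = fixed_mods, variable_mods = variable_mods),
    class = "peptide_species"
  )
  p$monoisotopic_mass <- monoisotopic_mass(p)
  p$net_charge_pH7 <- .net_charge(p)
  p
}

#' @export
print.peptide_species <- function(x, ...) {
  cat(sprintf("<peptide_species> %s%s, M = %.4f amu, z(pH7) = %+d\n",
              x$sequence, if (x$c_terminal_amide) "-NH2" else "",
              x$monoisotopic_mass, x$net_charge_pH7))
  invisible(x)
}

# Integer heuristic, not a titration: +1 free N-terminus, +1 per R/K,
# +round(0.1 per H), -1 per D/E, -1 for a free-acid C-terminus.
.net_charge <- function(p) {
  res <- strsplit(p$sequence, "")[[1]]
  ch <- sum(res %in% c("R", "K")) + round(0.1 * sum(res == "H")) -
    sum(res %in% c("D", "E"))
  if (p$n_terminal_free) ch <- ch + 1
  if (!p$c_terminal_amide) ch <- ch - 1
  as.integer(ch)
}

#' Enumerate the peptide chemical library
#'
#' All `|alphabet|^length` sequences in lexicographic order. The library
#' convention follows the screening campaign: C-terminal amides, free
#' N-termini, cysteine excluded from the default alphabet, so the default
#' tripeptide library has 19^3 = 6859 members.
#'
#' @param alphabet character vector of residue letters (default: the 20
#'   standard amino acids minus cysteine).
#' @param length peptide length (default 3).
#' @return data.frame with columns `sequence`, `c_terminal_amide`,
#'   `n_terminal_free`, `monoisotopic_mass`, `net_charge_pH7`.
#' @export
enumerate_tripeptides <- function(alphabet = setdiff(names(.RESIDUE_MASSES), "C"),
                                  length = 3) {
  if (length(alphabet) == 0) stop("alphabet must be non-empty")
  if (length < 1) stop("length must be >= 1")
  alphabet <- sort(unique(toupper(alphabet)))
  grids <- rev(rep(list(alphabet), length))  # last position varies fastest
  seqs <- do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  seqs <- sort(seqs)
  masses <- vapply(seqs, function(s) {
    sum(.RESIDUE_MASSES[strsplit(s, "")[[1]]]) + .WATER_MASS + .AMIDE_DELTA
  }, numeric(1))
  charges <- vapply(seqs, function(s) {
    res <- strsplit(s, "")[[1]]
    as.integer(1 + sum(res %in% c("R", "K")) + round(0.1 * sum(res == "H")) -
                 sum(res %in% c("D", "E")))
  }, integer(1))
  data.frame(sequence = seqs, c_terminal_amide = TRUE, n_terminal_free = TRUE,
             monoisotopic_mass = unname(masses), net_charge_pH7 = unname(charges),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the synthesis set from per-cavity rankings
#'
#' Takes the top `k` peptides from each cavity's ranked list (whole list when
#' shorter), concatenated in cavity order. Duplicate sequences across cavities
#' are retained and flagged.
#'
#' @param ranked_per_cavity named list: cavity id -> character vector of
#'   peptide sequences in rank order.
#' @param top_k number taken per cavity (default 8).
#' @return data.frame with columns `cavity`, `rank`, `sequence`, `duplicate`.
#' @export
select_synthesis_set <- function(ranked_per_cavity, top_k = 8) {
  if (length(ranked_per_cavity) == 0) stop("no cavity lists supplied")
  if (is.null(names(ranked_per_cavity))) {
    names(ranked_per_cavity) <- paste0("P", seq_along(ranked_per_cavity))
  }
  rows <- lapply(names(ranked_per_cavity), function(cv) {
    lst <- ranked_per_cavity[[cv]]
    n <- min(top_k, length(lst))
    if (n == 0) return(NULL)
    data.frame(cavity = cv, rank = seq_len(n), sequence = lst[seq_len(n)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$duplicate <- duplicated(out$sequence)
  out
}

#' Per-peptide descriptors
#'
#' @param p a `peptide_species` or a sequence string (amidated, free N-terminus
#'   assumed for a bare string).
#' @return list with `monoisotopic_mass` (amu), `net_charge_pH7`,
#'   `aromatic_count` (F/W/Y/H) and `hydrophobic_fraction` (A/V/L/I/M/F/W/P).
#' @export
peptide_descriptors <- function(p) {
  if (is.character(p)) p <- peptide_species(p)
  res <- strsplit(p$sequence, "")[[1]]
  list(
    monoisotopic_mass = p$monoisotopic_mass,
    net_charge_pH7 = p$net_charge_pH7,
    aromatic_count = sum(res %in% .AROMATIC_RESIDUES),
    hydrophobic_fraction = mean(res %in% .HYDROPHOBIC_RESIDUES)
  )
}
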