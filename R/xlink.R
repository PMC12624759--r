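# In-silico tryptic digestion, monoisotopic mass / m-over-z arithmetic, and
# crosslink delta-mass candidate search against observed peak lists.

#' Digestion settings
#'
#' Defaults mirror a trypsin search: cleavage C-terminal to K and R, no
#' cleavage before proline, per-residue missed-cleavage caps K <= 3 and
#' R <= 2 enforced jointly with a global cap of 3, carbamidomethyl cysteine
#' fixed, and at most one oxidised methionine variable.
#'
#' @param cleavage_residues residues cut after (default c("K","R")).
#' @param max_missed named integer vector of per-residue missed-cleavage caps.
#' @param global_max_missed overall cap on internal cleavage sites.
#' @param proline_rule logical; suppress cleavage before P.
#' @param fixed_mods data.frame(residue, delta) applied to every occurrence.
#' @param variable_mods data.frame(residue, delta, max_count) applied 0..max times.
#' @return list of class `digest_settings`.
#' @export
digest_settings <- function(cleavage_residues = c("K", "R"),
                            max_missed = c(K = 3, R = 2),
                            global_max_missed = 3,
                            proline_rule = TRUE,
                            fixed_mods = data.frame(residue = "C", delta = 57.02146),
                            variable_mods = data.frame(residue = "M", delta = 15.99491,
                                                       max_count = 1)) {
  if (any(max_missed < 0)) stop("max_missed must be >= 0")
  structure(list(cleavage_residues = cleavage_residues, max_missed = max_missed,
                 global_max_missed = global_max_missed, proline_rule = proline_rule,
                 fixed_mods = fixed_mods, variable_mods = variable_mods),
            class = "digest_settings")
}

#' In-silico protease digestion
#'
#' Cleaves C-terminal to the cleavage residues (skipping cuts before proline
#' when the proline rule is on) and enumerates every fragment whose internal
#' (missed) cleavage sites respect the per-residue and global caps.
#'
#' @param sequence protein sequence (1-letter).
#' @param settings a [digest_settings()] object.
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `sequence`, `missed` (internal cleavage sites).
#' @export
digest <- function(sequence, settings = digest_settings()) {
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% names(.RESIDUE_MASSES))) {
    stop("alphabet error: unknown residue letter(s) ",
         paste(setdiff(res, names(.RESIDUE_MASSES)), collapse = ", "))
  }
  n <- length(res)
  # cut positions: after residue i (i in cut_after), always after residue n
  cut_after <- which(res %in% settings$cleavage_residues)
  if (settings$proline_rule) {
    cut_after <- cut_after[!(cut_after < n & res[cut_after + 1] == "P")]
  }
  cut_after <- setdiff(cut_after, n)
  bounds <- c(0, cut_after, n)  # minimal peptides span (bounds[i]+1)..bounds[i+1]
  nmin <- length(bounds) - 1
  out <- list()
  for (i in seq_len(nmin)) {
    for (j in i:nmin) {
      internal <- if (j > i) cut_after[seq(i, j - 1)] else integer(0)
      if (length(internal) > settings$global_max_missed) break
      ok <- TRUE
      for (r in names(settings$max_missed)) {
        if (sum(res[internal] == r) > settings$max_missed[[r]]) { ok <- FALSE; break }
      }
      if (!ok) next
      out[[length(out) + 1]] <- data.frame(
        start = bounds[i] + 1, end = bounds[j + 1],
        sequence = substr(sequence, bounds[i] + 1, bounds[j + 1]),
        missed = length(internal), stringsAsFactors = FALSE
      )
    }
  }
  frag <- do.call(rbind, out)
  rownames(frag) <- NULL
  frag
}

#' Monoisotopic peptide mass
#'
#' Sum of standard monoisotopic residue masses plus water, minus 0.984016 amu
#' for a C-terminal amide, plus all modification deltas.
#'
#' @param p a `peptide_species`, or a sequence string (free termini assumed).
#' @return mass in amu.
#' @export
monoisotopic_mass <- function(p) {
  if (is.character(p)) {
    p <- list(sequence = toupper(p), c_terminal_amide = FALSE,
              fixed_mods = list(), variable_mods = list())
  }
  res <- strsplit(p$sequence, "")[[1]]
  if (!all(res %in% names(.RESIDUE_MASSES))) {
    stop("alphabet error: unknown residue letter(s) ",
         paste(setdiff(res, names(.RESIDUE_MASSES)), collapse = ", "))
  }
  m <- sum(.RESIDUE_MASSES[res]) + .WATER_MASS
  if (isTRUE(p$c_terminal_amide)) m <- m + .AMIDE_DELTA
  for (mod in c(p$fixed_mods, p$variable_mods)) {
    pos <- mod$position
    if (!is.null(pos) && (pos < 1 || pos > length(res))) {
      stop("modification position ", pos, " outside sequence")
    }
    m <- m + mod$delta
  }
  unname(m)
}

#' Mass-to-charge ratio of a protonated species
#'
#' Uses the hydrogen-atom-mass convention (1.007825 amu per charge), which
#' reproduces the campaign's printed calculated m/z values; set
#' `proton_mass = 1.007276` for the bare-proton convention.
#'
#' @param total_mass neutral monoisotopic mass (amu).
#' @param charge positive integer charge state.
#' @param proton_mass mass added per charge (amu).
#' @return m/z value.
#' @export
mz <- function(total_mass, charge, proton_mass = .MONO_H) {
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("charge must be a positive integer")
  }
  (total_mass + charge * proton_mass) / charge
}

#' Crosslink delta-mass candidate search
#'
#' For every digest fragment (expanded over variable-modification states),
#' adds the crosslink mass shift and matches the resulting m/z against the
#' observed peak list within a ppm tolerance.
#'
#' @param fragments data.frame from [digest()] (columns `sequence`, `start`,
#'   `end`).
#' @param delta_mass crosslink mass shift in amu (e.g. +574.3229 for the
#'   diazirine-tripeptide remnant).
#' @param observed_peaks data.frame with columns `mz` and `charge`.
#' @param ppm_tolerance match tolerance in ppm (default 10).
#' @param settings a [digest_settings()] supplying fixed/variable mods.
#' @return data.frame of candidates sorted by |ppm_error|: columns `sequence`,
#'   `start`, `end`, `mods`, `fragment_mass`, `total_mass`, `charge`,
#'   `mz_calc`, `mz_obs`, `ppm_error`.
#' @export
crosslink_search <- function(fragments, delta_mass, observed_peaks,
                             ppm_tolerance = 10, settings = digest_settings()) {
  stopifnot(is.data.frame(observed_peaks), all(c("mz", "charge") %in% names(observed_peaks)))
  cand <- list()
  for (fi in seq_len(nrow(fragments))) {
    seqs <- fragments$sequence[fi]
    res <- strsplit(seqs, "")[[1]]
    base <- sum(.RESIDUE_MASSES[res]) + .WATER_MASS
    fm <- settings$fixed_mods
    if (!is.null(fm) && nrow(fm) > 0) {
      for (k in seq_len(nrow(fm))) base <- base + fm$delta[k] * sum(res == fm$residue[k])
    }
    # variable-mod expansion: 0..min(max_count, occurrences) per mod
    states <- data.frame(extra = 0, label = "", stringsAsFactors = FALSE)
    vm <- settings$variable_mods
    if (!is.null(vm) && nrow(vm) > 0) {
      for (k in seq_len(nrow(vm))) {
        nmax <- min(vm$max_count[k], sum(res == vm$residue[k]))
        if (nmax == 0) next
        newstates <- lapply(seq_len(nmax), function(cnt) {
          data.frame(extra = states$extra + cnt * vm$delta[k],
                     label = paste0(states$label, cnt, "x", vm$residue[k],
                                    sprintf("%+0.4f", vm$delta[k]), ";"),
                     stringsAsFactors = FALSE)
        })
        states <- rbind(states, do.call(rbind, newstates))
      }
    }
    for (si in seq_len(nrow(states))) {
      fragment_mass <- base + states$extra[si]
      total <- fragment_mass + delta_mass
      for (pi in seq_len(nrow(observed_peaks))) {
        z <- observed_peaks$charge[pi]
        calc <- mz(total, z)
        obs <- observed_peaks$mz[pi]
        ppm <- 1e6 * (calc - obs) / obs
        if (abs(ppm) <= ppm_tolerance) {
          cand[[length(cand) + 1]] <- data.frame(
            sequence = seqs, start = fragments$start[fi], end = fragments$end[fi],
            mods = states$label[si], fragment_mass = fragment_mass,
            total_mass = total, charge = z, mz_calc = calc, mz_obs = obs,
            ppm_error = ppm, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(sequence = character(0), start = integer(0), end = integer(0),
                      mods = character(0), fragment_mass = numeric(0),
                      total_mass = numeric(0), charge = integer(0),
                      mz_calc = numeric(0), mz_obs = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, cand)
  out <- out[order(abs(out$ppm_error)), ]
  rownames(out) <- NULL
  out
}
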