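# Atom selection mini-grammar: conjunctions of chain / residue-range /
# atom-name-class clauses, e.g. "resid 103-117 and backbone and heavy".

#' Select atoms by expression
#'
#' Supported clauses, combined with `and`:
#' \itemize{
#'   \item `chain A [B ...]` - chain identifiers
#'   \item `resid 103-117` or `resid 5 7 9` - closed residue ranges / lists
#'   \item `resname ARG [GLU ...]` - 3-letter residue names
#'   \item `name CA [CB ...]` - atom names
#'   \item `backbone` - atoms named N, CA, C, O
#'   \item `sidechain` - non-backbone atoms
#'   \item `heavy` - non-hydrogen atoms
#'   \item `hydrogen` - hydrogen atoms
#'   \item `calpha` - shorthand for `name CA`
#'   \item `all` - every atom
#' }
#'
#' @param structure a `mol_structure` (or `mol_trajectory`, whose topology is used).
#' @param expression selection string.
#' @return object of class `atom_selection` with fields `expression` and
#'   `indices` (sorted, duplicate-free, possibly empty).
#' @export
select_atoms <- function(structure, expression) {
  if (inherits(structure, "mol_trajectory")) structure <- structure$topology
  a <- structure$atoms
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  if (length(clauses) == 0 || any(trimws(clauses) == "")) {
    stop("selection parse error: empty clause in '", expression, "'")
  }
  keep <- rep(TRUE, nrow(a))
  for (ci in seq_along(clauses)) {
    toks <- strsplit(trimws(clauses[ci]), "\\s+")[[1]]
    kw <- tolower(toks[1])
    args <- toks[-1]
    mask <- switch(kw,
      chain = {
        if (length(args) == 0) stop("selection parse error at clause ", ci,
                                    ": 'chain' needs at least one identifier")
        a$chain %in% args
      },
      resid = {
        if (length(args) == 0) stop("selection parse error at clause ", ci,
                                    ": 'resid' needs ranges or indices")
        ids <- integer(0)
        for (tk in args) {
          if (grepl("^-?[0-9]+--?[0-9]+$", tk) && grepl("-", substring(tk, 2))) {
            sp <- regmatches(tk, regexec("^(-?[0-9]+)-(-?[0-9]+)$", tk))[[1]]
            ids <- c(ids, seq(as.integer(sp[2]), as.integer(sp[3])))
          } else if (grepl("^-?[0-9]+$", tk)) {
            ids <- c(ids, as.integer(tk))
          } else {
            stop("selection parse error at clause ", ci, ": bad resid token '", tk, "'")
          }
        }
        a$resid %in% ids
      },
      resname = {
        if (length(args) == 0) stop("selection parse error at clause ", ci,
                                    ": 'resname' needs names")
        a$resname %in% toupper(args)
      },
      name = {
        if (length(args) == 0) stop("selection parse error at clause ", ci,
                                    ": 'name' needs atom names")
        a$name %in% toupper(args)
      },
      backbone = a$name %in% .BACKBONE_NAMES,
      sidechain = !(a$name %in% .BACKBONE_NAMES),
      heavy = toupper(a$element) != "H",
      hydrogen = toupper(a$element) == "H",
      calpha = a$name == "CA",
      all = rep(TRUE, nrow(a)),
      stop("selection parse error at clause ", ci, ": unknown keyword '", kw, "'")
    )
    keep <- keep & mask
  }
  base::structure(list(expression = expression, indices = which(keep)),
                  class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> '%s': %d atoms\n", x$expression, length(x$indices)))
  invisible(x)
}

# Accept an atom_selection, integer vector, or NULL (= all n atoms).
.resolve_indices <- function(sel, n) {
  if (is.null(sel)) return(seq_len(n))
  idx <- if (inherits(sel, "atom_selection")) sel$indices else as.integer(sel)
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > n)) {
    stop("selection indices out of range (1..", n, ")")
  }
  idx
}
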