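# Shared molecular data model and PDB input/output.
#
# Structures are plain data.frame-backed S3 objects; heavy PDB parsing and
# writing is delegated to bio3d, preceded by a fixed-width validation pass so
# malformed records are reported with their line numbers.

#' Construct a molecular structure
#'
#' @param atoms data.frame with columns serial, name, element, resname,
#'   resid, chain, x, y, z and optionally occupancy, bfactor.
#' @param metadata optional named list carried along unmodified.
#' @return object of class `mol_structure`. van der Waals radii are assigned
#'   from the element table into column `vdw`.
#' @export
mol_structure <- function(atoms, metadata = list()) {
  required <- c("serial", "name", "element", "resname", "resid", "chain",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty input: structure has zero atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) identifiers: ",
         key[which(duplicated(key))[1]])
  }
  atoms$vdw <- vdw_radius(atoms$element)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<mol_structure> %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              paste(unique(a$chain), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a structure or trajectory topology
#' @param x a `mol_structure` or `mol_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "mol_trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Extract the coordinate matrix of a structure
#' @param structure a `mol_structure`.
#' @return numeric matrix (n_atoms x 3), Angstrom.
#' @export
get_coords <- function(structure) {
  unname(as.matrix(structure$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a structure
#' @param structure a `mol_structure`.
#' @param xyz numeric matrix (n_atoms x 3).
#' @return the modified structure.
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(structure$atoms) || ncol(xyz) != 3) {
    stop("structural mismatch: coordinate matrix must be n_atoms x 3")
  }
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Construct a trajectory
#'
#' @param topology a `mol_structure` providing the atom table.
#' @param frames list of coordinate matrices (n_atoms x 3 each), ordered.
#' @param times optional numeric frame times (ns).
#' @return object of class `mol_trajectory`.
#' @export
mol_trajectory <- function(topology, frames, times = NULL) {
  if (!inherits(topology, "mol_structure")) stop("topology must be a mol_structure")
  if (length(frames) < 1) stop("trajectory needs at least one frame")
  na <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != na || ncol(f) != 3) {
      stop("structural mismatch: frame ", i, " is not ", na, " x 3")
    }
  }
  if (!is.null(times) && length(times) != length(frames)) {
    stop("frame_times length must equal number of frames")
  }
  structure(list(topology = topology, frames = frames, times = times),
            class = "mol_trajectory")
}

#' @export
print.mol_trajectory <- function(x, ...) {
  cat(sprintf("<mol_trajectory> %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `mol_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Coordinates of one trajectory frame
#' @param traj a `mol_trajectory`.
#' @param i frame index (1-based).
#' @return numeric matrix (n_atoms x 3).
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > length(traj$frames)) stop("frame index out of range: ", i)
  traj$frames[[i]]
}

#' One frame of a trajectory as a structure
#' @param traj a `mol_trajectory`.
#' @param i frame index.
#' @return a `mol_structure` with the topology's atom table and frame i coordinates.
#' @export
frame_structure <- function(traj, i) set_coords(traj$topology, frame_coords(traj, i))

# Validate fixed-width coordinate fields of ATOM/HETATM lines; returns the
# line numbers of records (used to attribute bio3d's output to input lines).
.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    substr(lines, 1, 4) == "ATOM" | substr(lines, 1, 6) == "HETATM"
  for (ln in which(is_atom)) {
    line <- lines[ln]
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(line, fld[1], fld[2])))
      if (is.na(v)) {
        stop("PDB parse error at line ", ln,
             ": malformed coordinate field (columns ", fld[1], "-", fld[2], ")")
      }
    }
  }
  which(is_atom)
}

.bio3d_to_structure <- function(pdb) {
  a <- pdb$atom
  elem <- a$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  if (any(blank)) {
    # fall back to first alphabetic character of the atom name
    elem[blank] <- substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", a$elety[blank])), 1, 1)
  }
  atoms <- data.frame(
    serial = a$eleno, name = trimws(a$elety), element = toupper(trimws(elem)),
    resname = trimws(a$resid), resid = a$resno, chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o), bfactor = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE
  )
  atoms
}

#' Parse a PDB-format string into a structure
#'
#' Reads ATOM/HETATM records; a file without MODEL blocks (or with one) yields
#' a single structure. Coordinates are in Angstrom.
#'
#' @param text character scalar (possibly multi-line) or character vector of lines.
#' @return a `mol_structure`.
#' @export
parse_structure <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  atom_lines <- .validate_pdb_lines(lines)
  if (length(atom_lines) == 0) stop("empty input: no ATOM/HETATM records")
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(lines, f)
  pdb <- suppressWarnings(bio3d::read.pdb(f, multi = FALSE, verbose = FALSE))
  mol_structure(.bio3d_to_structure(pdb))
}

#' Read a structure from a PDB file
#' @param path file path.
#' @return a `mol_structure`.
#' @export
read_structure <- function(path) parse_structure(readLines(path, warn = FALSE))

#' Parse a multi-MODEL PDB string into a trajectory
#'
#' The topology is taken from the first MODEL; frames are ordered by MODEL
#' number. All models must share one atom ordering.
#'
#' @param text character scalar or vector of lines.
#' @return a `mol_trajectory`.
#' @export
parse_trajectory <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  atom_lines <- .validate_pdb_lines(lines)
  if (length(atom_lines) == 0) stop("empty input: no ATOM/HETATM records")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    # bio3d tolerates ragged models by recycling; enforce equal atom counts
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts)) {
      stop("structural mismatch: unbalanced MODEL/ENDMDL blocks")
    }
    counts <- vapply(seq_along(model_starts), function(i) {
      sum(atom_lines > model_starts[i] & atom_lines < model_ends[i])
    }, integer(1))
    if (length(unique(counts)) != 1) {
      stop("structural mismatch: MODEL blocks have differing atom counts (",
           paste(unique(counts), collapse = ", "), ")")
    }
  }
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(lines, f)
  pdb <- suppressWarnings(bio3d::read.pdb(f, multi = TRUE, verbose = FALSE))
  topo <- mol_structure(.bio3d_to_structure(pdb))
  nf <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nf), function(i) {
    matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  })
  mol_trajectory(topo, frames)
}

#' Read a trajectory from a multi-MODEL PDB file
#' @param path file path.
#' @return a `mol_trajectory`.
#' @export
read_trajectory <- function(path) parse_trajectory(readLines(path, warn = FALSE))

#' Write a structure or trajectory in PDB format
#'
#' @param x a `mol_structure` or `mol_trajectory` (written as MODEL blocks).
#' @param path optional output file; when NULL the text is returned invisibly
#'   as a character vector of lines.
#' @return character vector of PDB lines, invisibly when `path` is given.
#' @export
write_structure <- function(x, path = NULL) {
  if (inherits(x, "mol_trajectory")) {
    atoms <- x$topology$atoms
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  } else {
    atoms <- x$atoms
    xyz <- matrix(as.vector(t(get_coords(x))), nrow = 1)
  }
  f <- if (is.null(path)) tempfile(fileext = ".pdb") else path
  bio3d::write.pdb(
    file = f, xyz = xyz,
    resno = atoms$resid, resid = atoms$resname, eleno = atoms$serial,
    elety = atoms$name, chain = atoms$chain,
    o = atoms$occupancy, b = atoms$bfactor, elesy = atoms$element
  )
  if (is.null(path)) {
    out <- readLines(f, warn = FALSE)
    unlink(f)
    return(out)
  }
  invisible(readLines(f, warn = FALSE))
}
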