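#' @keywords internal
"_PACKAGE"

SUBSTRATE_TYPES <- c("AHA-like", "HMD-like", "none")

#' Construct a molecular structure
#'
#' A `sc_structure` is the frame-invariant topology used throughout the
#' package: an ordered atom table with PDB-style labelling plus two extra
#' annotations that PDB has no native concept for, the substrate molecule
#' instance (`molecule_tag`, e.g. `"AHA_07"`) and its `substrate_type`
#' (`"AHA-like"`, `"HMD-like"` or `"none"`).
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `residue_name`,
#'   `chain_id`, `residue_number`, `x`, `y`, `z`, `bfactor`, `element`,
#'   `record` (ATOM/HETATM), `molecule_tag`, `substrate_type`.
#' @return object of class `sc_structure`
#' @export
sc_structure <- function(atoms) {
  required <- c("serial", "atom_name", "residue_name", "chain_id",
                "residue_number", "x", "y", "z", "bfactor", "element",
                "record", "molecule_tag", "substrate_type")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("structure atom table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("structure contains non-finite coordinates")
  bad <- !atoms$substrate_type %in% SUBSTRATE_TYPES
  if (any(bad))
    stop("unknown substrate_type value(s): ",
         paste(unique(atoms$substrate_type[bad]), collapse = ", "))
  atoms$serial <- as.integer(atoms$serial)
  atoms$residue_number <- as.integer(atoms$residue_number)
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_number, atom_name) within structure: ",
         key[which(duplicated(key))[1]])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "sc_structure")
}

#' @export
print.sc_structure <- function(x, ...) {
  a <- x$atoms
  nsub <- length(unique(a$molecule_tag[a$substrate_type != "none"]))
  cat("sc_structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain_id, a$residue_number))), "residues,",
      nsub, "substrate molecules\n")
  invisible(x)
}

#' Atom coordinates of a structure as an n x 3 matrix
#' @param structure an `sc_structure`
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Residue keys ("chain:resno") of a structure, in atom order of first
#' appearance
#' @param structure an `sc_structure`
#' @param protein_only keep only protein residues (ATOM records with
#'   substrate_type "none")
#' @return character vector of unique residue keys
#' @export
residue_keys <- function(structure, protein_only = FALSE) {
  a <- structure$atoms
  if (protein_only) a <- a[a$record == "ATOM" & a$substrate_type == "none", ]
  unique(paste0(a$chain_id, ":", a$residue_number))
}

#' Split atom indices by residue key
#' @noRd
residue_index <- function(structure, protein_only = FALSE) {
  a <- structure$atoms
  idx <- seq_len(nrow(a))
  if (protein_only) idx <- idx[a$record == "ATOM" & a$substrate_type == "none"]
  split(idx, paste0(a$chain_id, ":", a$residue_number)[idx])
}

#' Construct a trajectory
#'
#' A `sc_trajectory` couples a topology (`sc_structure`) with a dense
#' coordinate array of dimension `n_atoms x 3 x n_frames` (Angstrom). Every
#' frame carries exactly one coordinate triple per topology atom.
#'
#' @param topology an `sc_structure`
#' @param frames numeric array `n_atoms x 3 x n_frames`, or a list of
#'   `n_atoms x 3` matrices
#' @return object of class `sc_trajectory`
#' @export
sc_trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "sc_structure"))
  if (is.list(frames)) {
    n <- nrow(topology$atoms)
    frames <- array(unlist(frames, use.names = FALSE), dim = c(n, 3, length(frames)))
  }
  if (length(dim(frames)) != 3 || dim(frames)[2] != 3)
    stop("frames must be an n_atoms x 3 x n_frames array")
  if (dim(frames)[1] != nrow(topology$atoms))
    stop("frame coordinate count (", dim(frames)[1],
         ") does not match topology atom count (", nrow(topology$atoms), ")")
  if (dim(frames)[3] < 1) stop("trajectory must contain at least one frame")
  if (!all(is.finite(frames))) stop("trajectory contains non-finite coordinates")
  structure(list(topology = topology, frames = frames), class = "sc_trajectory")
}

#' Number of frames in a trajectory
#' @param traj an `sc_trajectory`
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' @export
print.sc_trajectory <- function(x, ...) {
  cat("sc_trajectory:", nrow(x$topology$atoms), "atoms x", n_frames(x), "frames\n")
  invisible(x)
}

#' Coordinates of one frame
#' @param traj an `sc_trajectory`
#' @param i frame index (1-based)
#' @return n_atoms x 3 matrix
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$frames[, , i, drop = TRUE]
}
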