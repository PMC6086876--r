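# Multi-model PDB and centroid-table I/O.
#
# The trajectory interchange format is multi-model PDB (MODEL/ENDMDL per
# frame) plus a CSV centroid-table dialect; coordinates are always Angstrom,
# residue numbering is 1-based PDB numbering preserved verbatim, and all
# writers emit LF line endings. Binary MD formats are deliberately out of
# scope: plain text keeps every stage bit-checkable.

DEFAULT_SUBSTRATE_RESNAMES <- c(AHA = "AHA-like", HMD = "HMD-like")

fmt_atom_name <- function(name) {
  # conventional PDB alignment: short names start in column 14
  if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
}

fmt_coord <- function(v) {
  s <- sprintf("%8.3f", v)
  if (any(nchar(s) > 8))
    stop("coordinate magnitude overflows fixed-width PDB columns (|x| too large): ",
         v[which(nchar(s) > 8)[1]])
  s
}

fmt_bfac <- function(v) {
  s <- sprintf("%6.2f", v)
  if (any(nchar(s) > 6))
    stop("B-factor value overflows fixed-width PDB columns: ",
         v[which(nchar(s) > 6)[1]])
  s
}

pdb_atom_lines <- function(atoms, xyz, bfactor = atoms$bfactor, occupancy = 1) {
  occ <- rep_len(occupancy, nrow(atoms))
  paste0(
    sprintf("%-6s", atoms$record),
    sprintf("%5d", atoms$serial %% 100000L),
    " ",
    vapply(atoms$atom_name, fmt_atom_name, character(1), USE.NAMES = FALSE),
    " ",
    sprintf("%3s", substr(atoms$residue_name, 1, 3)),
    " ",
    substr(paste0(atoms$chain_id, " "), 1, 1),
    sprintf("%4d", atoms$residue_number %% 10000L),
    "    ",
    fmt_coord(xyz[, 1]), fmt_coord(xyz[, 2]), fmt_coord(xyz[, 3]),
    sprintf("%6.2f", occ),
    fmt_bfac(bfactor),
    "          ",
    sprintf("%2s", substr(atoms$element, 1, 2))
  )
}

parse_num_field <- function(txt, lineno, what, blank_as = NULL) {
  v <- suppressWarnings(as.numeric(txt))
  blank <- grepl("^\\s*$", txt)
  if (!is.null(blank_as)) v[blank & is.na(v)] <- blank_as
  bad <- is.na(v)
  if (any(bad))
    stop("unparseable ", what, " field at line ", lineno[which(bad)[1]],
         ": '", txt[which(bad)[1]], "'")
  v
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' MODEL/ENDMDL records delimit frames; a file without MODEL records is read
#' as a single-frame trajectory. Coordinates are parsed from columns 31-54
#' (Angstrom). Substrate molecules are recognised by residue name via
#' `substrate_resnames` and assigned a `molecule_tag` synthesised from
#' (residue_name, chain, residue_number), e.g. `"AHA_07"` for the seventh
#' AHA instance encountered.
#'
#' @param path PDB file path
#' @param substrate_resnames named character vector mapping residue names to
#'   substrate types (default `c(AHA = "AHA-like", HMD = "HMD-like")`)
#' @return an [sc_trajectory()]
#' @export
read_multimodel_pdb <- function(path, substrate_resnames = DEFAULT_SUBSTRATE_RESNAMES) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # assign each atom line to a model block
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_of_atom <- model_id[is_atom]
  if (any(model_of_atom == 0))
    stop("ATOM records before the first MODEL record in ", path)
  atom_lines <- lines[is_atom]
  atom_linenos <- which(is_atom)

  models <- split(seq_along(atom_lines), model_of_atom)
  n_per <- lengths(models)
  if (length(unique(n_per)) != 1)
    stop("inconsistent atom count between models: model ",
         names(models)[which(n_per != n_per[1])[1]], " has ",
         n_per[which(n_per != n_per[1])[1]], " atoms, model ",
         names(models)[1], " has ", n_per[1])

  first <- models[[1]]
  fl <- atom_lines[first]
  ln <- atom_linenos[first]
  atoms <- data.frame(
    serial = as.integer(parse_num_field(substr(fl, 7, 11), ln, "serial")),
    atom_name = trimws(substr(fl, 13, 16)),
    residue_name = trimws(substr(fl, 18, 20)),
    chain_id = substr(fl, 22, 22),
    residue_number = as.integer(parse_num_field(substr(fl, 23, 26), ln, "residue number")),
    x = 0, y = 0, z = 0,
    bfactor = parse_num_field(substr(fl, 61, 66), ln, "B-factor", blank_as = 0),
    element = trimws(substr(fl, 77, 78)),
    record = trimws(substr(fl, 1, 6)),
    stringsAsFactors = FALSE
  )
  atoms$element[atoms$element == ""] <-
    substr(gsub("[^A-Za-z]", "", atoms$atom_name[atoms$element == ""]), 1, 1)

  # substrate typing and molecule-instance tags
  st <- substrate_resnames[atoms$residue_name]
  atoms$substrate_type <- ifelse(is.na(st), "none", unname(st))
  atoms$molecule_tag <- NA_character_
  sub <- which(atoms$substrate_type != "none")
  if (length(sub)) {
    inst <- paste(atoms$residue_name[sub], atoms$chain_id[sub],
                  atoms$residue_number[sub])
    uin <- unique(inst)
    uname <- atoms$residue_name[sub][match(uin, inst)]
    counter <- stats::ave(seq_along(uin), uname, FUN = seq_along)
    tags <- sprintf("%s_%02d", uname, counter)
    atoms$molecule_tag[sub] <- tags[match(inst, uin)]
  }
  atoms$molecule_tag[atoms$substrate_type == "none"] <- NA_character_

  n_atoms <- nrow(atoms)
  n_mod <- length(models)
  frames <- array(NA_real_, dim = c(n_atoms, 3, n_mod))
  for (k in seq_len(n_mod)) {
    bl <- atom_lines[models[[k]]]
    bn <- atom_linenos[models[[k]]]
    # label consistency across models
    if (k > 1) {
      lbl <- paste(substr(bl, 13, 16), substr(bl, 18, 26))
      ref <- paste(substr(fl, 13, 16), substr(fl, 18, 26))
      if (!identical(lbl, ref))
        stop("atom labelling in model ", k, " differs from model 1 (line ",
             bn[which(lbl != ref)[1]], ")")
    }
    frames[, 1, k] <- parse_num_field(substr(bl, 31, 38), bn, "x coordinate")
    frames[, 2, k] <- parse_num_field(substr(bl, 39, 46), bn, "y coordinate")
    frames[, 3, k] <- parse_num_field(substr(bl, 47, 54), bn, "z coordinate")
  }
  atoms$x <- frames[, 1, 1]; atoms$y <- frames[, 2, 1]; atoms$z <- frames[, 3, 1]
  sc_trajectory(sc_structure(atoms), frames)
}

#' Read a single-model PDB file as a structure
#' @inheritParams read_multimodel_pdb
#' @return an [sc_structure()] (first model if several are present)
#' @export
read_structure_pdb <- function(path, substrate_resnames = DEFAULT_SUBSTRATE_RESNAMES) {
  read_multimodel_pdb(path, substrate_resnames)$topology
}

#' Write a trajectory as a multi-model PDB file
#' @param traj an [sc_trajectory()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (k in seq_len(nf)) {
    writeLines(sprintf("MODEL %8d", k), con, sep = "\n")
    writeLines(pdb_atom_lines(traj$topology$atoms, traj$frames[, , k, drop = TRUE]),
               con, sep = "\n")
    writeLines("ENDMDL", con, sep = "\n")
  }
  writeLines("END", con, sep = "\n")
  invisible(path)
}

#' Write a structure as a single-model PDB file
#' @param structure an [sc_structure()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure_pdb <- function(structure, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(pdb_atom_lines(structure$atoms, coords(structure)), con, sep = "\n")
  writeLines("END", con, sep = "\n")
  invisible(path)
}

#' Write a point cloud as HETATM records
#'
#' One HETATM per point, in input order, with fixed-width PDB columns so the
#' file loads in standard viewers. Used to export the centroid cloud at each
#' clustering iteration. Point weights, when given, are written to the
#' B-factor column (display-clamped at 999.99 by the fixed field width).
#'
#' @param points n x 3 matrix of coordinates (Angstrom)
#' @param path output path
#' @param labels optional residue-name labels per point (first 3 characters
#'   used); default `"CEN"`
#' @param weights optional numeric weights written to the B-factor column
#' @return `path`, invisibly
#' @export
write_points_pdb <- function(points, path, labels = NULL, weights = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) && !all(is.finite(points)))
    stop("points contain non-finite coordinates")
  n <- nrow(points)
  lab <- if (is.null(labels)) rep("CEN", n) else rep_len(labels, n)
  w <- if (is.null(weights)) rep(0, n) else pmin(rep_len(weights, n), 999.99)
  atoms <- data.frame(
    serial = seq_len(max(n, 1))[seq_len(n)],
    atom_name = rep("C", n), residue_name = lab,
    chain_id = rep("C", n),
    residue_number = ((seq_len(max(n, 1)) - 1L) %% 9999L + 1L)[seq_len(n)],
    bfactor = w, element = rep("C", n), record = rep("HETATM", n),
    stringsAsFactors = FALSE
  )
  con <- file(path, "wb")
  on.exit(close(con))
  if (n) writeLines(pdb_atom_lines(atoms, points), con, sep = "\n")
  writeLines("END", con, sep = "\n")
  invisible(path)
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Every atom's B-factor field (columns 61-66) carries its residue's score,
#' the standard trick for colouring a structure by an external per-residue
#' quantity in molecular viewers. Residues without a score receive
#' `default_score`. Coordinates and every column outside 61-66 are unchanged
#' relative to [write_structure_pdb()].
#'
#' @param structure an [sc_structure()]
#' @param scores an [residue score map][contact_population_score] or a named
#'   numeric vector keyed by `"chain:resno"`
#' @param path output path
#' @param scale `"linear_0_99"` (min-max rescale of scored residues onto
#'   0..99.99; a constant score map writes 0.00 everywhere) or `"raw"`
#' @param default_score value for residues absent from `scores`
#' @return `path`, invisibly
#' @export
write_bfactor_pdb <- function(structure, scores, path,
                              scale = c("linear_0_99", "raw"),
                              default_score = 0) {
  scale <- match.arg(scale)
  if (inherits(scores, "sc_score_map"))
    scores <- stats::setNames(scores$score, paste0(scores$chain_id, ":", scores$residue_number))
  if (!all(is.finite(scores)))
    stop("non-finite score for residue(s): ",
         paste(names(scores)[!is.finite(scores)], collapse = ", "))
  if (scale == "linear_0_99" && length(scores)) {
    rng <- range(scores)
    scores[] <- if (diff(rng) == 0) 0 else (scores - rng[1]) / diff(rng) * 99.99
  }
  key <- paste0(structure$atoms$chain_id, ":", structure$atoms$residue_number)
  b <- unname(scores[key])
  b[is.na(b)] <- default_score
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(pdb_atom_lines(structure$atoms, coords(structure), bfactor = b),
             con, sep = "\n")
  writeLines("END", con, sep = "\n")
  invisible(path)
}

#' Write a centroid series as a CSV centroid table
#'
#' Dialect: header exactly `frame,molecule_tag,substrate_type,x,y,z`,
#' coordinates to 6 decimals, LF line endings.
#'
#' @param series an [sc_centroid_series()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_centroid_table <- function(series, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("frame,molecule_tag,substrate_type,x,y,z", con, sep = "\n")
  if (nrow(series))
    writeLines(sprintf("%d,%s,%s,%.6f,%.6f,%.6f",
                       series$frame, series$molecule_tag, series$substrate_type,
                       series$x, series$y, series$z), con, sep = "\n")
  invisible(path)
}

#' Read a CSV centroid table
#' @param path CSV path in the [write_centroid_table()] dialect
#' @return an [sc_centroid_series()]
#' @export
read_centroid_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  required <- c("frame", "molecule_tag", "substrate_type", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("centroid table lacks column(s): ", paste(missing, collapse = ", "))
  for (col in c("frame", "x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && nrow(df))
      stop("non-numeric value in column '", col, "' at data row ",
           which(is.na(v))[1])
    df[[col]] <- v
  }
  df$frame <- as.integer(df$frame)
  sc_centroid_series(df)
}
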