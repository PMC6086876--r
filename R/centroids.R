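# Per-molecule, per-frame centroid reduction. The centroid is the unweighted
# spatial mean over all atoms present for the molecule (hydrogens included
# when present); a typical ~23-atom substrate is thus reduced roughly
# 25-fold, and the centroid series is the unit of all downstream analysis.

#' Construct a centroid series
#'
#' A data.frame with one row per (frame, molecule) holding the molecule's
#' centroid. Attributes `n_frames` and `n_molecules` are derived; a series is
#' "complete" when every molecule appears in every frame, in which case
#' `nrow == n_frames * n_molecules`.
#'
#' @param df data.frame with columns `frame` (1-based integer),
#'   `molecule_tag`, `substrate_type`, `x`, `y`, `z`
#' @return object of classes `sc_centroid_series`, `data.frame`
#' @export
sc_centroid_series <- function(df) {
  required <- c("frame", "molecule_tag", "substrate_type", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("centroid series lacks column(s): ", paste(missing, collapse = ", "))
  df <- df[, required]
  if (nrow(df)) {
    if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
      stop("centroid series contains non-finite coordinates")
    if (anyDuplicated(paste(df$frame, df$molecule_tag)))
      stop("duplicate (frame, molecule_tag) entries in centroid series")
    df <- df[order(df$frame, df$molecule_tag), ]
  }
  rownames(df) <- NULL
  tags <- unique(df$molecule_tag)
  frames <- unique(df$frame)
  complete <- nrow(df) == length(tags) * length(frames)
  structure(df,
            n_frames = length(frames), n_molecules = length(tags),
            complete = complete,
            class = c("sc_centroid_series", "data.frame"))
}

#' @export
print.sc_centroid_series <- function(x, ...) {
  cat("sc_centroid_series:", nrow(x), "entries (",
      attr(x, "n_molecules"), "molecules x", attr(x, "n_frames"), "frames",
      if (!attr(x, "complete")) ", incomplete" else "", ")\n")
  invisible(x)
}

#' Centroid of a set of atom positions
#'
#' Unweighted arithmetic mean per coordinate ("spatially averaged"); no mass
#' weighting.
#'
#' @param atom_points n x 3 matrix (or coercible) of finite coordinates
#' @return length-3 numeric vector
#' @export
molecule_centroid <- function(atom_points) {
  m <- matrix(as.numeric(atom_points), ncol = 3)
  if (nrow(m) == 0) stop("cannot take the centroid of zero points")
  if (!all(is.finite(m))) stop("non-finite coordinates in centroid input")
  colMeans(m)
}

#' Reduce every substrate molecule to a per-frame centroid
#'
#' For each frame and each substrate molecule (identified by `molecule_tag`),
#' computes the unweighted mean of the molecule's atom coordinates. Protein
#' and other non-substrate atoms are ignored.
#'
#' @param traj an [sc_trajectory()] whose topology labels substrate atoms
#' @return an [sc_centroid_series()], complete by construction
#' @export
extract_centroid_series <- function(traj) {
  a <- traj$topology$atoms
  sub <- which(a$substrate_type != "none")
  if (!length(sub)) stop("trajectory contains no substrate atoms")
  if (anyNA(a$molecule_tag[sub]))
    stop("substrate atom(s) without molecule_tag at topology row(s): ",
         paste(utils::head(sub[is.na(a$molecule_tag[sub])], 5), collapse = ", "))
  nf <- n_frames(traj)
  groups <- split(sub, a$molecule_tag[sub])
  tags <- names(groups)
  types <- vapply(groups, function(i) a$substrate_type[i[1]], character(1))
  nm <- length(groups)
  # one 3 x nf centroid track per molecule
  xyz <- array(NA_real_, dim = c(nm, 3, nf))
  for (j in seq_len(nm)) {
    idx <- groups[[j]]
    xyz[j, , ] <- colMeans(traj$frames[idx, , , drop = FALSE], dims = 1)
  }
  df <- data.frame(
    frame = rep(seq_len(nf), each = nm),
    molecule_tag = rep(tags, nf),
    substrate_type = rep(unname(types), nf),
    x = as.numeric(xyz[, 1, ]), y = as.numeric(xyz[, 2, ]),
    z = as.numeric(xyz[, 3, ]),
    stringsAsFactors = FALSE
  )
  sc_centroid_series(df)
}

#' Restrict a centroid series to one substrate type
#' @param series an [sc_centroid_series()]
#' @param type `"AHA-like"` or `"HMD-like"`
#' @return an [sc_centroid_series()]
#' @export
filter_type <- function(series, type) {
  type <- match.arg(type, SUBSTRATE_TYPES)
  sc_centroid_series(as.data.frame(series)[series$substrate_type == type, ])
}
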