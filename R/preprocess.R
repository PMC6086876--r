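# Trajectory conditioning: center on an anchor selection, superpose every
# frame onto the first frame (Kabsch least-squares fit), re-center, strip to
# substrates. No periodic-boundary re-imaging is performed here: inputs are
# assumed re-imaged upstream by the MD engine's tooling.

#' Kabsch least-squares superposition of P onto Q
#'
#' Returns the proper rotation (det = +1, reflection-corrected via SVD) and
#' translation minimising the RMSD between corresponding rows, plus the RMSD
#' before and after. Apply as `x' = (x - centroid(P)) R^T + centroid(Q)`.
#'
#' @param P,Q n x 3 matrices of paired coordinates (n >= 3, non-collinear)
#' @return list with `rotation` (3 x 3), `translation` (length 3),
#'   `rmsd_before`, `rmsd_after`
#' @export
kabsch_fit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  if (nrow(P) < 3) stop("superposition needs at least 3 fit atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  if (s$d[2] < 1e-10 * max(s$d[1], 1))
    stop("degenerate (collinear) fit atom set: superposition is ill-defined")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rmsd_before <- sqrt(mean(rowSums((P - Q)^2)))
  fitted <- Pc %*% t(R)
  rmsd_after <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp),
       rmsd_before = rmsd_before, rmsd_after = rmsd_after)
}

#' Center each frame on the centroid of a selection
#'
#' Rigidly translates every frame so the geometric (unweighted) centroid of
#' the selected atoms sits at the origin. The canonical anchor in the
#' conditioning pipeline is a short stretch of core residues, e.g.
#' `"protein and resid 138-140"`.
#'
#' @param traj an [sc_trajectory()]
#' @param sel selection string (see [select_atoms()])
#' @return centered [sc_trajectory()]
#' @export
center_on_selection <- function(traj, sel) {
  idx <- select_atoms(traj$topology, sel)
  if (!length(idx)) stop("empty centering selection: '", sel, "'")
  frames <- traj$frames
  for (k in seq_len(dim(frames)[3])) {
    ctr <- colMeans(frames[idx, , k, drop = FALSE])
    frames[, , k] <- sweep(frames[, , k, drop = TRUE], 2, ctr)
  }
  out <- traj
  out$frames <- frames
  out$topology$atoms[, c("x", "y", "z")] <- frames[, , 1]
  out
}

#' Superpose every frame onto the first frame
#'
#' Each frame is rigidly transformed by the Kabsch fit of the fit selection
#' onto the corresponding atoms of frame 1 (the reference); frame 1 itself is
#' left unchanged. RMSDs are reported on the fit selection.
#'
#' @param traj an [sc_trajectory()]
#' @param fit_sel selection string; default all protein atoms
#' @return list with `trajectory` (superposed [sc_trajectory()]) and
#'   `alignment`, a data.frame with per-frame `rmsd_before` / `rmsd_after`
#'   and list-columns `rotation`, `translation`
#' @export
superpose_to_first_frame <- function(traj, fit_sel = "protein") {
  idx <- select_atoms(traj$topology, fit_sel)
  if (length(idx) < 3) stop("fit selection needs >= 3 atoms: '", fit_sel, "'")
  nf <- n_frames(traj)
  ref <- traj$frames[idx, , 1, drop = TRUE]
  frames <- traj$frames
  rot <- vector("list", nf); trl <- vector("list", nf)
  rb <- numeric(nf); ra <- numeric(nf)
  rot[[1]] <- diag(3); trl[[1]] <- c(0, 0, 0)
  for (k in seq_len(nf)[-1]) {
    fit <- kabsch_fit(frames[idx, , k, drop = TRUE], ref)
    frames[, , k] <- sweep(frames[, , k, drop = TRUE] %*% t(fit$rotation),
                           2, fit$translation, `+`)
    rot[[k]] <- fit$rotation; trl[[k]] <- fit$translation
    rb[k] <- fit$rmsd_before; ra[k] <- fit$rmsd_after
  }
  out <- traj
  out$frames <- frames
  alignment <- data.frame(frame = seq_len(nf), rmsd_before = rb, rmsd_after = ra)
  alignment$rotation <- rot
  alignment$translation <- trl
  list(trajectory = out, alignment = alignment)
}

#' Strip a trajectory to a selection
#'
#' Reduces topology and all frames to the selected atoms (relative order
#' preserved, frame count unchanged). The canonical use is removing protein,
#' water and counterions, keeping only substrate atoms: `strip(traj,
#' "substrate")`.
#'
#' @param traj an [sc_trajectory()]
#' @param keep selection string of atoms to keep
#' @return stripped [sc_trajectory()]
#' @export
strip <- function(traj, keep) {
  idx <- select_atoms(traj$topology, keep)
  if (!length(idx)) stop("strip selection matches no atoms: '", keep, "'")
  atoms <- traj$topology$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  sc_trajectory(sc_structure(atoms), traj$frames[idx, , , drop = FALSE])
}

#' Full trajectory conditioning pipeline
#'
#' Runs the conditioning stages in their canonical order: center each frame on
#' an anchor selection, superpose every frame onto the first frame using a fit
#' selection, re-center on the whole protein, and strip to substrate atoms.
#'
#' @param traj an [sc_trajectory()]
#' @param anchor_sel anchor for the initial per-frame centering
#' @param fit_sel fit selection for the superposition (default `"protein"`,
#'   i.e. all protein atoms; backbone-only fits can be expressed through the
#'   selection language)
#' @param recenter_sel selection for the final re-centering
#' @param strip_sel atoms kept in the output
#' @return list with `trajectory` (conditioned, stripped) and `alignment`
#'   (from [superpose_to_first_frame()])
#' @export
condition_trajectory <- function(traj, anchor_sel = "protein and resid 138-140",
                                 fit_sel = "protein", recenter_sel = "protein",
                                 strip_sel = "substrate") {
  t1 <- center_on_selection(traj, anchor_sel)
  sp <- superpose_to_first_frame(t1, fit_sel)
  t2 <- center_on_selection(sp$trajectory, recenter_sel)
  list(trajectory = strip(t2, strip_sel), alignment = sp$alignment)
}
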