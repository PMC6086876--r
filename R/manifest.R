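# Study-design bookkeeping. A competition study is systems x replicates
# simulations, each carrying n_molecules substrate molecules over n_frames
# frames: e.g. 3 systems x 30 replicates x 40 molecules = 3,600 per-molecule
# trajectories, each simulation contributing 40 x 10,000 = 400,000 substrate
# centroid records.

#' Compute the run manifest for a study design
#'
#' All derived quantities are recomputed from the counts on every call; the
#' manifest never stores stale derived values.
#'
#' @param n_systems number of protein systems
#' @param n_replicates replicate simulations per system
#' @param n_molecules substrate molecules per simulation (both types
#'   combined, e.g. 20 + 20 = 40)
#' @param n_frames frames per simulation
#' @param ns_per_replicate optional simulated nanoseconds per replicate, to
#'   report total simulated time
#' @return list of class `sc_manifest` with the design counts plus
#'   `n_simulations`, `total_trajectories` (per-molecule trajectories),
#'   `records_per_trajectory` (substrate records per simulation), and
#'   `total_ns_per_system` when a duration is given
#' @export
compute_manifest <- function(n_systems, n_replicates, n_molecules, n_frames,
                             ns_per_replicate = NULL) {
  stopifnot(n_systems >= 1, n_replicates >= 1, n_molecules >= 1, n_frames >= 1)
  out <- list(
    n_systems = as.integer(n_systems),
    n_replicates = as.integer(n_replicates),
    n_molecules = as.integer(n_molecules),
    n_frames = as.integer(n_frames),
    n_simulations = as.integer(n_systems * n_replicates),
    total_trajectories = as.integer(n_systems * n_replicates * n_molecules),
    records_per_trajectory = as.integer(n_molecules * n_frames)
  )
  if (!is.null(ns_per_replicate)) {
    out$ns_per_replicate <- ns_per_replicate
    out$total_ns_per_system <- n_replicates * ns_per_replicate
    out$total_ns <- n_systems * n_replicates * ns_per_replicate
  }
  class(out) <- "sc_manifest"
  out
}

#' @export
print.sc_manifest <- function(x, ...) {
  cat("Study design:", x$n_systems, "systems x", x$n_replicates,
      "replicates x", x$n_molecules, "molecules x", x$n_frames, "frames\n")
  cat("  simulations:            ", x$n_simulations, "\n")
  cat("  per-molecule trajectories:", x$total_trajectories, "\n")
  cat("  records per simulation:  ", x$records_per_trajectory, "\n")
  if (!is.null(x$total_ns_per_system))
    cat("  simulated time/system:   ", x$total_ns_per_system, "ns\n")
  invisible(x)
}
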