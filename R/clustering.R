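# Iterative nearest-unique-neighbour merge clustering with a distance cutoff.
#
# One iteration: (1) points with no neighbour within the cutoff are removed
# as isolated, low-density noise; (2) the remaining points are greedily
# matched into disjoint pairs in ascending order of inter-point distance,
# from the shortest pair up to the pair closest to the cutoff; (3) each
# matched pair is replaced by its unweighted midpoint (the spatial average of
# the two points), carrying the summed centroid count as a weight;
# (4) neighboured-but-unmatched points are carried forward unchanged.
# Iterating collapses a substrate centroid cloud onto its most populated
# positions in space; runs on molecules that reach an active site trace out
# surface channels.

#' Clustering parameters
#'
#' @param cutoff neighbour/merge distance cutoff in Angstrom (strict `<`);
#'   default 10.
#' @param max_iterations hard iteration cap; default 64
#' @param carry_unmatched carry neighboured-but-unmatched points forward
#'   (default) instead of dropping them; dropping discards density signal but
#'   is available for comparison
#' @param weight_average merge pairs at their weight-weighted mean instead of
#'   the plain midpoint (default FALSE: the merged point is the unweighted
#'   spatial average of the two points)
#' @return object of class `sc_cluster_params`
#' @export
cluster_params <- function(cutoff = 10, max_iterations = 64L,
                           carry_unmatched = TRUE, weight_average = FALSE) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, max_iterations = as.integer(max_iterations),
                 carry_unmatched = isTRUE(carry_unmatched),
                 weight_average = isTRUE(weight_average)),
            class = "sc_cluster_params")
}

#' Construct a centroid cloud
#'
#' The working object of the clustering stage: an ordered point set with an
#' integer weight per point (how many original centroids merged into it) and
#' the iteration index (0 = raw input).
#'
#' @param points n x 3 matrix (Angstrom)
#' @param weights integer weights, default all 1
#' @param iteration iteration index, default 0
#' @param substrate_type substrate type of the cloud (single type; clustering
#'   never mixes types)
#' @return object of class `sc_cloud`
#' @export
sc_cloud <- function(points, weights = NULL, iteration = 0L,
                     substrate_type = "AHA-like") {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  if (is.null(weights)) weights <- rep(1L, n)
  if (length(weights) != n) stop("one weight per point required")
  if (any(weights < 1)) stop("weights must be >= 1")
  structure(list(points = points, weights = as.numeric(weights),
                 iteration = as.integer(iteration),
                 substrate_type = substrate_type),
            class = "sc_cloud")
}

#' @export
print.sc_cloud <- function(x, ...) {
  cat("sc_cloud: iteration", x$iteration, "-", nrow(x$points), "points, total weight",
      sum(x$weights), "\n")
  invisible(x)
}

#' Pool a centroid series into an iteration-0 cloud
#'
#' All frames' centroids of a single-type series become one point cloud with
#' unit weights, the input to [cluster_to_convergence()]. Mixed substrate
#' types are refused: the clustering pairs each point with its nearest unique
#' neighbour *of the same type*.
#'
#' @param series an [sc_centroid_series()] containing a single substrate type
#' @return an [sc_cloud()]
#' @export
as_cloud <- function(series) {
  types <- unique(series$substrate_type)
  if (length(types) != 1)
    stop("clustering input mixes substrate types (",
         paste(types, collapse = ", "),
         "); filter to one type first (see filter_type)")
  sc_cloud(as.matrix(as.data.frame(series)[, c("x", "y", "z")]),
           substrate_type = types)
}

#' All point pairs closer than a cutoff, in merge order
#'
#' Enumerates every unordered index pair (i < j) with Euclidean distance
#' strictly below `cutoff`, sorted ascending by distance with ties broken by
#' (i, j) lexicographic order — the order in which the greedy matching
#' consumes them. Uses a cell-list grid for large inputs.
#'
#' @param points n x 3 matrix
#' @param cutoff distance cutoff (strict `<`)
#' @return data.frame with columns `i`, `j`, `dist` (possibly 0 rows)
#' @export
neighbor_pairs <- function(points, cutoff) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (n < 2) return(empty)
  if (n <= 2500) {
    d <- as.matrix(stats::dist(points))
    hit <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
    if (!nrow(hit)) return(empty)
    out <- data.frame(i = hit[, 1], j = hit[, 2], dist = d[hit])
  } else {
    out <- neighbor_pairs_grid(points, cutoff)
    if (!nrow(out)) return(empty)
  }
  out <- out[order(out$dist, out$i, out$j), ]
  rownames(out) <- NULL
  out
}

# Cell-list neighbour enumeration: bin points into cubic cells of edge
# `cutoff`; candidate pairs only arise within a cell or between one of the
# 13 forward half-neighbourhood cell offsets (each unordered cell pair
# visited once).
neighbor_pairs_grid <- function(points, cutoff) {
  lo <- apply(points, 2, min)
  cell <- floor(sweep(points, 2, lo) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  bins <- split(seq_len(nrow(points)), key)
  coord <- do.call(rbind, lapply(strsplit(names(bins), " "), as.integer))
  keymap <- stats::setNames(seq_along(bins), names(bins))
  offsets <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1), c(1, 1, 1),
    c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  ii <- list(); jj <- list(); dd <- list(); k <- 0L
  add_pairs <- function(a, b, self) {
    if (self) {
      if (length(a) < 2) return()
      cmb <- utils::combn(a, 2)
      pi <- cmb[1, ]; pj <- cmb[2, ]
    } else {
      g <- expand.grid(a = a, b = b)
      pi <- pmin(g$a, g$b); pj <- pmax(g$a, g$b)
    }
    dv <- sqrt(rowSums((points[pi, , drop = FALSE] - points[pj, , drop = FALSE])^2))
    keep <- dv < cutoff
    if (any(keep)) {
      k <<- k + 1L
      ii[[k]] <<- pi[keep]; jj[[k]] <<- pj[keep]; dd[[k]] <<- dv[keep]
    }
  }
  for (b in seq_along(bins)) {
    add_pairs(bins[[b]], NULL, self = TRUE)
    for (o in seq_len(nrow(offsets))) {
      nb <- keymap[paste(coord[b, 1] + offsets[o, 1],
                         coord[b, 2] + offsets[o, 2],
                         coord[b, 3] + offsets[o, 3])]
      if (!is.na(nb)) add_pairs(bins[[b]], bins[[nb]], self = FALSE)
    }
  }
  if (k == 0L) return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  data.frame(i = unlist(ii), j = unlist(jj), dist = unlist(dd))
}

# Greedy maximal matching over a pair list already in merge order: scan pairs
# in order, accept a pair when neither endpoint is already matched.
# Vectorised in rounds: within the still-eligible list, a pair whose two
# endpoints both make their first appearance in that pair is certainly
# accepted by the sequential greedy scan; accept all such pairs, drop pairs
# touching matched points, repeat.
greedy_match <- function(pairs) {
  sel_i <- integer(0); sel_j <- integer(0); sel_d <- numeric(0)
  while (nrow(pairs)) {
    np <- nrow(pairs)
    row <- seq_len(np)
    ends <- c(pairs$i, pairs$j)
    # earliest eligible row in which each endpoint value appears
    first_row <- stats::ave(c(row, row), ends, FUN = min)
    take <- first_row[row] == row & first_row[np + row] == row
    sel_i <- c(sel_i, pairs$i[take])
    sel_j <- c(sel_j, pairs$j[take])
    sel_d <- c(sel_d, pairs$dist[take])
    used <- c(pairs$i[take], pairs$j[take])
    keep <- !(pairs$i %in% used | pairs$j %in% used)
    pairs <- pairs[keep, , drop = FALSE]
  }
  ord <- order(sel_d, sel_i, sel_j)
  data.frame(i = sel_i[ord], j = sel_j[ord], dist = sel_d[ord])
}

#' One clustering iteration
#'
#' Removes isolated points (no neighbour strictly within the cutoff), greedily
#' merges the remainder into disjoint nearest-unique-neighbour pairs in
#' ascending-distance order, replaces each pair by its spatial average, and
#' (by default) carries unmatched-but-neighboured points forward. Output
#' point order: merged points in merge order, then carried points in original
#' index order.
#'
#' @param cloud an [sc_cloud()]
#' @param params an [cluster_params()]
#' @return list with `cloud` (next iteration) and `record` — a list holding
#'   `iteration`, `merges` (data.frame `i`, `j`, `dist` in merge order),
#'   `dropped` (isolated input indices) and `carried` (input indices carried
#'   forward)
#' @export
cluster_iteration <- function(cloud, params = cluster_params()) {
  stopifnot(inherits(cloud, "sc_cloud"))
  n <- nrow(cloud$points)
  if (n == 0) stop("cannot iterate on an empty cloud")
  pairs <- neighbor_pairs(cloud$points, params$cutoff)
  neighboured <- sort(unique(c(pairs$i, pairs$j)))
  dropped <- setdiff(seq_len(n), neighboured)
  merges <- greedy_match(pairs)
  matched <- c(merges$i, merges$j)
  carried <- if (params$carry_unmatched) setdiff(neighboured, matched) else integer(0)
  not_carried <- if (params$carry_unmatched) integer(0) else setdiff(neighboured, matched)

  pts <- cloud$points; w <- cloud$weights
  if (nrow(merges)) {
    wi <- w[merges$i]; wj <- w[merges$j]
    if (params$weight_average) {
      mpts <- (pts[merges$i, , drop = FALSE] * wi +
               pts[merges$j, , drop = FALSE] * wj) / (wi + wj)
    } else {
      mpts <- (pts[merges$i, , drop = FALSE] + pts[merges$j, , drop = FALSE]) / 2
    }
    mw <- wi + wj
  } else {
    mpts <- matrix(numeric(0), ncol = 3); mw <- numeric(0)
  }
  new_pts <- rbind(mpts, pts[carried, , drop = FALSE])
  new_w <- c(mw, w[carried])
  out <- sc_cloud(new_pts, if (length(new_w)) new_w else NULL,
                  iteration = cloud$iteration + 1L,
                  substrate_type = cloud$substrate_type)
  list(cloud = out,
       record = list(iteration = out$iteration, merges = merges,
                     dropped = c(dropped, not_carried), carried = carried))
}

#' Iterate the merge clustering to convergence
#'
#' Repeats [cluster_iteration()] on successively smaller clouds until an
#' iteration performs zero merges, a single point (or nothing) remains, or
#' `max_iterations` is reached. Optionally writes every iteration's cloud as
#' a HETATM PDB (`<run>_iter<k>.pdb`, k = 0 for the input) for overlay with
#' the protein structure in a molecular viewer.
#'
#' @param x an [sc_cloud()] or a single-substrate-type [sc_centroid_series()]
#'   (pooled over all frames via [as_cloud()])
#' @param params an [cluster_params()]
#' @param write_dir directory for per-iteration PDB snapshots, or NULL
#' @param run_name filename prefix for snapshots
#' @return list with `clouds` (list of [sc_cloud()], element 1 = input) and
#'   `history` (list of per-iteration records, see [cluster_iteration()])
#' @export
cluster_to_convergence <- function(x, params = cluster_params(),
                                   write_dir = NULL, run_name = "cluster") {
  cloud <- if (inherits(x, "sc_cloud")) x else as_cloud(x)
  snap <- function(cl) {
    if (!is.null(write_dir))
      write_points_pdb(cl$points,
                       file.path(write_dir, sprintf("%s_iter%d.pdb", run_name, cl$iteration)),
                       labels = "CEN", weights = cl$weights)
  }
  clouds <- list(cloud)
  history <- list()
  snap(cloud)
  while (nrow(cloud$points) > 1 &&
         cloud$iteration - clouds[[1]]$iteration < params$max_iterations) {
    step <- cluster_iteration(cloud, params)
    # a zero-merge iteration is the fixed point: the surviving points are
    # mutually beyond the cutoff, so stop and keep the pre-iteration cloud
    if (nrow(step$record$merges) == 0) break
    cloud <- step$cloud
    clouds[[length(clouds) + 1L]] <- cloud
    history[[length(history) + 1L]] <- step$record
    snap(cloud)
  }
  list(clouds = clouds, history = history)
}

#' Write a merge history as JSON lines
#' @param history history list from [cluster_to_convergence()]
#' @param path output path (one JSON object per iteration per line)
#' @return `path`, invisibly
#' @export
write_merge_history <- function(history, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (rec in history) {
    obj <- list(iteration = rec$iteration,
                merges = rec$merges,
                dropped = I(rec$dropped), carried = I(rec$carried))
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)),
               con, sep = "\n")
  }
  invisible(path)
}
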