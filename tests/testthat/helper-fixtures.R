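# Fixtures are built in code; independent brute-force oracles live here and
# deliberately share no code with the package implementation.

atom_row <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM", tag = NA_character_, stype = "none",
                     b = 0, elem = "C") {
  data.frame(serial = serial, atom_name = name, residue_name = resname,
             chain_id = chain, residue_number = resno, x = x, y = y, z = z,
             bfactor = b, element = elem, record = record,
             molecule_tag = tag, substrate_type = stype,
             stringsAsFactors = FALSE)
}

# two-residue protein + two 2-atom substrate molecules
toy_structure <- function() {
  sc_structure(rbind(
    atom_row(1, "N",  "ALA", "A", 1, 0, 0, 0),
    atom_row(2, "CA", "ALA", "A", 1, 1.5, 0, 0),
    atom_row(3, "CA", "ALA", "A", 2, 10, 0, 0),
    atom_row(4, "C1", "AHA", "X", 1, 20, 0, 0, record = "HETATM",
             tag = "AHA_01", stype = "AHA-like"),
    atom_row(5, "C2", "AHA", "X", 1, 22, 0, 0, record = "HETATM",
             tag = "AHA_01", stype = "AHA-like"),
    atom_row(6, "C1", "HMD", "Y", 1, 30, 5, 0, record = "HETATM",
             tag = "HMD_01", stype = "HMD-like"),
    atom_row(7, "C2", "HMD", "Y", 1, 30, 7, 0, record = "HETATM",
             tag = "HMD_01", stype = "HMD-like")))
}

# 3-frame trajectory translating everything by (1, 2, 3) per frame
toy_trajectory <- function() {
  s <- toy_structure()
  x0 <- coords(s)
  frames <- lapply(0:2, function(k) sweep(x0, 2, c(1, 2, 3) * k, `+`))
  sc_trajectory(s, frames)
}

small_decoy <- function(seed = 7, n_frames = 200, ...) {
  spec <- decoy_spec(n_protein_residues = 80, protein_radius = 20,
                     n_frames = n_frames, box_half_width = 50,
                     seed = seed, ...)
  sys <- make_decoy_system(spec)
  list(spec = spec, system = sys, traj = simulate_walkers(spec, sys))
}

both_sites <- function() {
  list(site_definition("empty", "resname PLP"),
       site_definition("occupied", "resname PLM"))
}

# ---- brute-force oracles -------------------------------------------------

oracle_neighbor_pairs <- function(pts, cutoff) {
  n <- nrow(pts)
  rows <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d < cutoff) rows[[length(rows) + 1]] <- c(i, j, d)
    }
  }
  if (!length(rows))
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  m <- do.call(rbind, rows)
  df <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), dist = m[, 3])
  df <- df[order(df$dist, df$i, df$j), ]
  rownames(df) <- NULL
  df
}

# sequential greedy matching by repeated minimum search (no vectorised rounds)
oracle_iteration <- function(pts, w, cutoff, carry = TRUE) {
  pr <- oracle_neighbor_pairs(pts, cutoff)
  neigh <- sort(unique(c(pr$i, pr$j)))
  used <- rep(FALSE, nrow(pts))
  mi <- integer(0); mj <- integer(0)
  for (r in seq_len(nrow(pr))) {
    i <- pr$i[r]; j <- pr$j[r]
    if (!used[i] && !used[j]) {
      used[i] <- TRUE; used[j] <- TRUE
      mi <- c(mi, i); mj <- c(mj, j)
    }
  }
  carried <- if (carry) setdiff(neigh, c(mi, mj)) else integer(0)
  list(points = rbind((pts[mi, , drop = FALSE] + pts[mj, , drop = FALSE]) / 2,
                      pts[carried, , drop = FALSE]),
       weights = c(w[mi] + w[mj], w[carried]),
       n_merges = length(mi))
}

oracle_cluster <- function(pts, cutoff, max_iter = 64) {
  w <- rep(1, nrow(pts))
  out <- list(list(points = pts, weights = w))
  for (it in seq_len(max_iter)) {
    if (nrow(pts) <= 1) break
    step <- oracle_iteration(pts, w, cutoff)
    if (step$n_merges == 0) break   # fixed point: keep the previous cloud
    pts <- step$points; w <- step$weights
    out[[length(out) + 1]] <- list(points = pts, weights = w)
  }
  out
}

# convex-combination certificate: rebuild every surviving point from the
# merge history as an explicit convex combination of the input points
reconstruct_coefficients <- function(n_input, history) {
  coef <- diag(n_input)
  for (rec in history) {
    m <- rec$merges
    merged <- if (nrow(m)) {
      do.call(rbind, lapply(seq_len(nrow(m)), function(r)
        (coef[m$i[r], ] + coef[m$j[r], ]) / 2))
    } else matrix(numeric(0), ncol = n_input)
    coef <- rbind(merged, coef[rec$carried, , drop = FALSE])
  }
  coef
}
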