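# Synthetic decoy systems with planted ground truth. These are validation
# controls, not a physical model of any MD: a spherical decoy "protein" shell
# of labelled residues, two cofactor-anchored site loci recessed below the
# shell, an optional surface channel polyline, and substrate walkers of two
# types. Free walkers diffuse by a reflected Gaussian random walk; "channeled"
# walkers are scripted to travel the polyline into a site by a known frame,
# giving exact expected answers for arrival detection, channel-residue
# enrichment and cluster-path recovery.

local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Specification of a synthetic decoy system
#'
#' Defaults mirror the competition design the package targets: twenty
#' substrate molecules of each of the two types diffusing around one protein,
#' a few of the A-type walkers scripted along the surface channel. Sizes with
#' no stated field convention (frame count, shell radius, box size, step
#' size) are fixed, realistic choices documented in the package vignette.
#'
#' @param n_protein_residues residues on the decoy shell
#' @param protein_radius shell radius in Angstrom; free walkers reflect here
#' @param channel_waypoints polyline (k x 3 matrix) of the planted surface
#'   channel, ending at the first site anchor; NULL plants the default
#'   great-circle arc
#' @param site_positions 2 x 3 matrix of site anchor positions; NULL places
#'   them recessed 4 Angstrom below the shell on the +x / -x axes
#' @param n_aha_like,n_hmd_like substrate molecule counts (default 20 + 20)
#' @param n_frames frames to simulate
#' @param step_sigma free-walker Gaussian step, Angstrom/frame per axis
#' @param box_half_width half-width of the cubic box (reflecting walls)
#' @param n_channel_walkers number of A-type walkers scripted along the
#'   channel (<= `n_aha_like`)
#' @param seed RNG seed for walker dynamics
#' @param placement_seed RNG seed for the structure and the initial walker
#'   positions; defaults to `seed` so systems generated with the same
#'   placement seed share starting coordinates
#' @return object of class `sc_decoy_spec`
#' @export
decoy_spec <- function(n_protein_residues = 200, protein_radius = 30,
                       channel_waypoints = NULL, site_positions = NULL,
                       n_aha_like = 20, n_hmd_like = 20,
                       n_frames = 2000, step_sigma = 1.0,
                       box_half_width = 60, n_channel_walkers = 3,
                       seed = 1, placement_seed = seed) {
  stopifnot(n_protein_residues >= 1, protein_radius > 0, step_sigma > 0,
            n_aha_like >= 0, n_hmd_like >= 0, n_frames >= 1,
            box_half_width > protein_radius)
  if (n_channel_walkers > n_aha_like)
    stop("n_channel_walkers cannot exceed n_aha_like")
  # recessed deep enough that a shell-reflected free walker can never come
  # within the default 3.5 A arrival cutoff of any anchor atom
  site_depth <- 5
  if (is.null(site_positions))
    site_positions <- rbind(c(protein_radius - site_depth, 0, 0),
                            c(-(protein_radius - site_depth), 0, 0))
  site_positions <- matrix(as.numeric(site_positions), ncol = 3)
  if (is.null(channel_waypoints)) {
    # great-circle arc just above the shell from the +z pole to the +x site
    th <- seq(pi / 2, 0, length.out = 6)
    arc <- (protein_radius + 2) * cbind(cos(th), 0, sin(th))
    channel_waypoints <- rbind(arc, site_positions[1, ])
  }
  channel_waypoints <- matrix(as.numeric(channel_waypoints), ncol = 3)
  if (any(abs(channel_waypoints) > box_half_width))
    stop("channel waypoints fall outside the box")
  structure(list(n_protein_residues = as.integer(n_protein_residues),
                 protein_radius = protein_radius,
                 channel_waypoints = channel_waypoints,
                 site_positions = site_positions,
                 n_aha_like = as.integer(n_aha_like),
                 n_hmd_like = as.integer(n_hmd_like),
                 n_frames = as.integer(n_frames), step_sigma = step_sigma,
                 box_half_width = box_half_width,
                 n_channel_walkers = as.integer(n_channel_walkers),
                 seed = as.integer(seed),
                 placement_seed = as.integer(placement_seed)),
            class = "sc_decoy_spec")
}

# near-uniform points on a sphere (Fibonacci lattice), deterministic
fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Minimum distance from points to a polyline
#' @param points n x 3 matrix
#' @param polyline k x 3 matrix of waypoints (k >= 2)
#' @return numeric vector of point-to-polyline distances
#' @export
dist_to_polyline <- function(points, polyline) {
  points <- matrix(as.numeric(points), ncol = 3)
  polyline <- matrix(as.numeric(polyline), ncol = 3)
  dmin <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(polyline) - 1)) {
    a <- polyline[s, ]; b <- polyline[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(points, 2, a)
    t <- if (len2 > 0) pmin(1, pmax(0, as.numeric(rel %*% ab) / len2)) else 0
    proj <- outer(t, ab)
    dmin <- pmin(dmin, sqrt(rowSums((rel - proj)^2)))
  }
  dmin
}

substrate_template <- function(n_atoms, spread = 1.4) {
  m <- matrix(stats::rnorm(n_atoms * 3, sd = spread), ncol = 3)
  sweep(m, 2, colMeans(m))   # exactly mean-centered: atoms average to walker pos
}

#' Build the decoy structure and its planted truth
#'
#' Residues (3 atoms each, chain A) are laid on a Fibonacci lattice over the
#' shell; two cofactor residues (PLP / PLM, chain P) anchor the "empty" and
#' "occupied" sites; substrate molecules are rigid dummy-atom clusters of 22
#' (A-type, residue name AHA, chain X) or 24 (B-type, HMD, chain Y) atoms,
#' matching realistic atom counts so the centroid reduction factor is
#' exercised. Deterministic given `placement_seed`.
#'
#' @param spec an [decoy_spec()]
#' @return list with `structure` ([sc_structure()], coordinates = frame-1
#'   positions) and `truth`: `channel` polyline, `roles` (named
#'   free/channeled per tag), `arrival_frames` (named, scripted channel
#'   walkers), `channel_residues` (residue numbers within 8 Angstrom of the
#'   polyline), `site_positions`, plus the per-type atom templates used
#' @export
make_decoy_system <- function(spec) {
  local_seed(spec$placement_seed, {
    res_ctr <- fibonacci_sphere(spec$n_protein_residues, spec$protein_radius)
    res_off <- rbind(c(-0.8, 0.4, 0), c(0, 0, 0), c(0.8, -0.4, 0.3))
    rows <- list()
    add <- function(record, name, resname, chain, resno, xyz, element, tag, stype) {
      rows[[length(rows) + 1L]] <<- data.frame(
        serial = 0L, atom_name = name, residue_name = resname, chain_id = chain,
        residue_number = resno, x = xyz[1], y = xyz[2], z = xyz[3],
        bfactor = 0, element = element, record = record,
        molecule_tag = tag, substrate_type = stype, stringsAsFactors = FALSE)
    }
    for (r in seq_len(spec$n_protein_residues))
      for (a in 1:3)
        add("ATOM", c("N", "CA", "C")[a], "ALA", "A", r,
            res_ctr[r, ] + res_off[a, ], c("N", "C", "C")[a],
            NA_character_, "none")
    cof_off <- rbind(c(0.8, 0, 0), c(-0.4, 0.7, 0), c(-0.4, -0.7, 0))
    for (a in 1:3) add("HETATM", paste0("P", a), "PLP", "P", 1L,
                       spec$site_positions[1, ] + cof_off[a, ], "P",
                       NA_character_, "none")
    for (a in 1:3) add("HETATM", paste0("Q", a), "PLM", "P", 2L,
                       spec$site_positions[2, ] + cof_off[a, ], "P",
                       NA_character_, "none")

    tmpl <- list("AHA-like" = substrate_template(22),
                 "HMD-like" = substrate_template(24))

    # starting positions: channeled walkers at the channel mouth, free
    # walkers uniformly in the shell between protein and box wall
    n_walk <- spec$n_aha_like + spec$n_hmd_like
    start <- matrix(NA_real_, n_walk, 3)
    roles <- character(n_walk)
    tags <- character(n_walk)
    types <- character(n_walk)
    r_lo <- spec$protein_radius + 6
    r_hi <- spec$box_half_width - 6
    for (w in seq_len(n_walk)) {
      is_aha <- w <= spec$n_aha_like
      types[w] <- if (is_aha) "AHA-like" else "HMD-like"
      idx <- if (is_aha) w else w - spec$n_aha_like
      tags[w] <- sprintf("%s_%02d", if (is_aha) "AHA" else "HMD", idx)
      if (is_aha && idx <= spec$n_channel_walkers) {
        roles[w] <- "channeled"
        start[w, ] <- spec$channel_waypoints[1, ] + stats::rnorm(3, sd = 0.5)
      } else {
        roles[w] <- "free"
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        start[w, ] <- u * stats::runif(1, r_lo, min(r_hi, r_lo + (r_hi - r_lo)))
      }
    }
    names(roles) <- tags

    ch_tags <- tags[roles == "channeled"]
    arrival_frames <- if (length(ch_tags)) {
      af <- pmax(2L, as.integer(round(
        seq(0.5, 0.8, length.out = length(ch_tags)) * spec$n_frames)))
      stats::setNames(af, ch_tags)
    } else stats::setNames(integer(0), character(0))

    for (w in seq_len(n_walk)) {
      off <- tmpl[[types[w]]]
      resname <- if (types[w] == "AHA-like") "AHA" else "HMD"
      chain <- if (types[w] == "AHA-like") "X" else "Y"
      resno <- if (types[w] == "AHA-like") w else w - spec$n_aha_like
      for (a in seq_len(nrow(off)))
        add("HETATM", paste0("C", a), resname, chain, resno,
            start[w, ] + off[a, ], "C", tags[w], types[w])
    }
    atoms <- do.call(rbind, rows)
    atoms$serial <- seq_len(nrow(atoms))
    # a residue lines the channel when any of its atoms is within 8 A of it
    prot <- atoms$record == "ATOM"
    datom <- dist_to_polyline(as.matrix(atoms[prot, c("x", "y", "z")]),
                              spec$channel_waypoints)
    dres <- tapply(datom, atoms$residue_number[prot], min)
    ch_res <- sort(as.integer(names(dres)[dres <= 8]))
    list(structure = sc_structure(atoms),
         truth = list(channel = spec$channel_waypoints, roles = roles,
                      arrival_frames = arrival_frames,
                      channel_residues = ch_res,
                      site_positions = spec$site_positions,
                      start_positions = stats::setNames(
                        split(start, row(start)), tags),
                      templates = tmpl))
  })
}

reflect_interval <- function(v, lim) {
  over <- v > lim;  v[over] <- 2 * lim - v[over]
  under <- v < -lim; v[under] <- -2 * lim - v[under]
  v
}

# arc-length-uniform position along a polyline at fraction f in [0, 1]
polyline_point <- function(poly, f) {
  seg <- sqrt(rowSums((poly[-1, , drop = FALSE] - poly[-nrow(poly), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  target <- f * cum[length(cum)]
  s <- findInterval(target, cum, rightmost.closed = TRUE)
  s <- min(max(s, 1), nrow(poly) - 1)
  t <- if (seg[s] > 0) (target - cum[s]) / seg[s] else 0
  poly[s, ] + t * (poly[s + 1, ] - poly[s, ])
}

#' Simulate substrate walkers around the decoy protein
#'
#' Free walkers follow a reflected Gaussian random walk (per-axis step
#' `step_sigma`) inside the box, with hard-sphere reflection off the protein
#' shell — since the site anchors sit 4 Angstrom below the shell and the
#' arrival cutoff is 3.5, free walkers can never register an arrival, making
#' them an exact negative control. Channeled walkers move arc-length-
#' uniformly along the planted polyline (plus 0.5 Angstrom Gaussian jitter),
#' reach the site anchor at their scripted arrival frame, and then hold
#' position near the anchor (attracted Ornstein-Uhlenbeck-like relaxation),
#' so they are retained at the site for the remainder of the run.
#'
#' @param spec an [decoy_spec()]
#' @param system result of [make_decoy_system()] (built from the same spec)
#' @return an [sc_trajectory()] with full substrate labelling; protein and
#'   cofactor atoms are static
#' @export
simulate_walkers <- function(spec, system) {
  truth <- system$truth
  atoms <- system$structure$atoms
  tags <- names(truth$roles)
  n_walk <- length(tags)
  nf <- spec$n_frames
  pos <- array(NA_real_, dim = c(n_walk, 3, nf))
  for (w in seq_len(n_walk)) pos[w, , 1] <- truth$start_positions[[tags[w]]]

  local_seed(spec$seed, {
    noise <- array(stats::rnorm(n_walk * 3 * nf), dim = c(n_walk, 3, nf))
    free <- which(truth$roles == "free")
    chan <- which(truth$roles == "channeled")
    for (k in seq_len(nf)[-1]) {
      if (length(free)) {
        p <- pos[free, , k - 1, drop = FALSE][, , 1] +
          spec$step_sigma * noise[free, , k, drop = FALSE][, , 1]
        p <- matrix(p, ncol = 3)
        p <- apply(p, 2, reflect_interval, lim = spec$box_half_width)
        p <- matrix(p, ncol = 3)
        r <- sqrt(rowSums(p^2))
        inside <- r < spec$protein_radius
        if (any(inside)) {
          scale <- (2 * spec$protein_radius - r[inside]) / r[inside]
          p[inside, ] <- p[inside, , drop = FALSE] * scale
        }
        pos[free, , k] <- p
      }
      for (w in chan) {
        fa <- truth$arrival_frames[[tags[w]]]
        site <- truth$channel[nrow(truth$channel), ]
        # traverse the surface waypoints over frames 1..fa-1, keeping clear
        # of the arrival cutoff, then drop onto the site exactly at frame fa
        surf <- truth$channel[-nrow(truth$channel), , drop = FALSE]
        if (nrow(surf) < 2) surf <- truth$channel
        if (k < fa) {
          f <- if (fa > 2) (k - 1) / (fa - 2) else 1
          base <- polyline_point(surf, min(f, 1))
          pos[w, , k] <- base + 0.35 * noise[w, , k]
        } else if (k == fa) {
          pos[w, , k] <- site + 0.3 * noise[w, , k]
        } else {
          pos[w, , k] <- site + 0.7 * (pos[w, , k - 1] - site) + 0.3 * noise[w, , k]
        }
      }
    }
  })

  # assemble atom-level frames: static protein/cofactor, rigid substrates
  n_atoms <- nrow(atoms)
  frames <- array(NA_real_, dim = c(n_atoms, 3, nf))
  static <- which(atoms$substrate_type == "none")
  sxyz <- as.matrix(atoms[static, c("x", "y", "z")])
  frames[static, , ] <- array(sxyz, dim = c(length(static), 3, nf))
  for (w in seq_len(n_walk)) {
    idx <- which(atoms$molecule_tag %in% tags[w])
    off <- truth$templates[[atoms$substrate_type[idx[1]]]]
    a <- nrow(off)
    frames[idx, , ] <- array(off, dim = c(a, 3, nf)) +
      aperm(array(pos[w, , ], dim = c(3, nf, a)), c(3, 1, 2))
  }
  sc_trajectory(system$structure, frames)
}
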