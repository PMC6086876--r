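single_atom_structure <- function() {
  sc_structure(rbind(
    atom_row(1, "CA", "ALA", "A", 1, 0, 0, 0),
    atom_row(2, "CA", "ALA", "A", 2, 50, 0, 0)))
}

series_of <- function(points, tag = "AHA_01", type = "AHA-like") {
  # one molecule visiting the given point per frame
  points <- matrix(points, ncol = 3)
  sc_centroid_series(data.frame(
    frame = seq_len(nrow(points)), molecule_tag = tag, substrate_type = type,
    x = points[, 1], y = points[, 2], z = points[, 3]))
}

test_that("contact population scores reflect time-averaged occupancy", {
  s <- single_atom_structure()
  far <- series_of(matrix(rep(c(0, 0, 200), 10), ncol = 3, byrow = TRUE))
  map <- contact_population_score(far, s, contact_cutoff = 5)
  expect_equal(map$score, c(0, 0))

  pinned <- series_of(matrix(rep(c(2, 0, 0), 10), ncol = 3, byrow = TRUE))
  map <- contact_population_score(pinned, s, contact_cutoff = 5)
  expect_equal(map$score[map$residue_number == 1], 1.0)
  expect_equal(map$score[map$residue_number == 2], 0.0)

  expect_error(contact_population_score(pinned, s, contact_cutoff = -1), "cutoff")
})

test_that("contact scores are monotone in the cutoff and conserve total events", {
  d <- small_decoy(seed = 6, n_frames = 30)
  ser <- extract_centroid_series(d$traj)
  s <- d$system$structure
  m3 <- contact_population_score(ser, s, 3)
  m5 <- contact_population_score(ser, s, 5)
  m8 <- contact_population_score(ser, s, 8)
  expect_true(all(m5$score >= m3$score))
  expect_true(all(m8$score >= m5$score))

  # conservation against a brute-force double loop on a reduced instance
  sub <- sc_centroid_series(as.data.frame(ser)[ser$frame <= 5, ])
  map <- contact_population_score(sub, s, 5)
  events <- 0
  xyz <- coords(s)
  prot <- s$atoms$record == "ATOM" & s$atoms$substrate_type == "none"
  for (r in unique(s$atoms$residue_number[prot])) {
    ra <- xyz[prot & s$atoms$residue_number == r, , drop = FALSE]
    for (row in seq_len(nrow(sub))) {
      dmin <- min(sqrt(rowSums(sweep(ra, 2, as.numeric(sub[row, c("x", "y", "z")]))^2)))
      if (dmin <= 5) events <- events + 1
    }
  }
  expect_equal(sum(map$score) * attr(map, "n_frames_used"), events)
})

test_that("scores are invariant to frame order and molecule relabelling", {
  d <- small_decoy(seed = 10, n_frames = 10)
  ser <- extract_centroid_series(d$traj)
  s <- d$system$structure
  base <- contact_population_score(ser, s, 5)

  df <- as.data.frame(ser)
  df$frame <- (max(df$frame) + 1) - df$frame          # reverse frame order
  df$molecule_tag <- sub("AHA", "ZZZ", df$molecule_tag)
  shuffled <- sc_centroid_series(df[sample(nrow(df)), ])
  expect_equal(contact_population_score(shuffled, s, 5)$score, base$score)
})

test_that("averaging score maps is the per-residue arithmetic mean", {
  d <- small_decoy(seed = 12, n_frames = 10)
  ser <- extract_centroid_series(d$traj)
  s <- d$system$structure
  map <- contact_population_score(ser, s, 5)
  expect_equal(average_score_maps(list(map))$score, map$score)

  zero <- map; zero$score <- 0
  expect_equal(average_score_maps(list(map, zero))$score, map$score / 2)

  set.seed(2)
  maps <- lapply(1:30, function(i) { m <- map; m$score <- runif(nrow(map)); m })
  avg <- average_score_maps(maps)
  brute <- rowMeans(vapply(maps, function(m) m$score, numeric(nrow(map))))
  expect_equal(avg$score, unname(brute), tolerance = 1e-12)
  expect_equal(attr(avg, "n_frames_used"), 30 * attr(map, "n_frames_used"))

  bad <- map; bad$residue_number[1] <- 999L
  expect_error(average_score_maps(list(map, bad)), "mismatch")
})

test_that("g(r) places a fixed substrate in the right bin and handles empties", {
  s <- single_atom_structure()
  ser <- series_of(matrix(rep(c(7.5, 0, 0), 5), ncol = 3, byrow = TRUE))
  rdf <- radial_distribution(ser, s, "resid 1", bin_width = 1, r_max = 12,
                             bulk_density = 0.01)
  expect_equal(sum(rdf$counts), 5)
  expect_equal(rdf$counts[8], 5)   # bin [7, 8)

  empty <- sc_centroid_series(data.frame(frame = integer(0),
                                         molecule_tag = character(0),
                                         substrate_type = character(0),
                                         x = numeric(0), y = numeric(0),
                                         z = numeric(0)))
  rdf0 <- radial_distribution(empty, s, "resid 1", bin_width = 1, r_max = 12,
                              bulk_density = 0.01)
  expect_true(all(rdf0$g_of_r == 0))
  expect_error(radial_distribution(ser, s, "resid 1", bulk_density = 0), "bulk_density")
})

test_that("g(r) approaches 1 for an ideal gas at known density", {
  point_ref <- sc_structure(atom_row(1, "CA", "ALA", "A", 1, 0, 0, 0))
  set.seed(14)
  half <- 30; nmol <- 400; nf <- 1500
  df <- data.frame(
    frame = rep(seq_len(nf), each = nmol),
    molecule_tag = rep(sprintf("AHA_%03d", seq_len(nmol)), nf),
    substrate_type = "AHA-like",
    x = runif(nmol * nf, -half, half),
    y = runif(nmol * nf, -half, half),
    z = runif(nmol * nf, -half, half))
  ser <- sc_centroid_series(df)
  rho <- nmol / (2 * half)^3
  rdf <- radial_distribution(ser, point_ref, "all", bin_width = 1, r_max = 15,
                             bulk_density = rho)
  inner <- rdf$r_mid > 2
  expect_true(all(abs(rdf$g_of_r[inner] - 1) < 0.15))
  expect_lt(mean(abs(rdf$g_of_r[inner] - 1)), 0.05)
})
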