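anchor_structure <- function() {
  sc_structure(rbind(
    atom_row(1, "P1", "PLP", "P", 1, 0, 0, 0, record = "HETATM"),
    atom_row(2, "CA", "ALA", "A", 1, 10, 0, 0)))
}

walk_series <- function(xs, tag = "AHA_01", type = "AHA-like") {
  sc_centroid_series(data.frame(frame = seq_along(xs), molecule_tag = tag,
                                substrate_type = type, x = xs, y = 0, z = 0))
}

test_that("arrival detection finds first entry and retention", {
  s <- anchor_structure()
  site <- site_definition("empty", "resname PLP")

  never <- walk_series(rep(25, 10))
  rec <- detect_arrivals(never, s, site)
  expect_true(is.na(rec$first_arrival_frame))
  expect_true(is.na(rec$retention_fraction))

  pinned <- walk_series(rep(2, 10))
  rec <- detect_arrivals(pinned, s, site)
  expect_equal(rec$first_arrival_frame, 1)
  expect_equal(rec$retention_fraction, 1.0)

  # enters at frame 4, leaves the site region at frame 8
  xs <- c(20, 10, 5, 3, 2, 4, 5.5, 30, 30, 30)
  rec <- detect_arrivals(walk_series(xs), s, site)
  expect_equal(rec$first_arrival_frame, 4)
  # frames 4..10: within 6 A for frames 4,5,6,7 -> 4/7
  expect_equal(rec$retention_fraction, 4 / 7)

  expect_error(site_definition("s", "all", arrival_cutoff = 7, site_region_cutoff = 6),
               "arrival_cutoff")
  expect_error(detect_arrivals(pinned, s, site_definition("x", "resname ZZZ")),
               "no atoms")
})

test_that("planted walkers are detected at exactly the scripted frames", {
  d <- small_decoy(seed = 7)
  ser <- extract_centroid_series(d$traj)
  rec <- detect_arrivals(ser, d$system$structure, both_sites(), replicate = 1)
  got <- rec[!is.na(rec$first_arrival_frame), ]
  truth <- d$system$truth$arrival_frames
  expect_setequal(got$molecule_tag, names(truth))
  expect_equal(got$first_arrival_frame[match(names(truth), got$molecule_tag)],
               unname(truth))
  expect_true(all(got$site_id == "empty"))
  expect_true(all(got$retention_fraction >= 0.95))
  # B-type molecules never arrive anywhere
  expect_true(all(is.na(rec$first_arrival_frame[rec$substrate_type == "HMD-like"])))
})

test_that("a larger arrival cutoff never delays arrival or shrinks counts", {
  d <- small_decoy(seed = 19, n_frames = 150)
  ser <- extract_centroid_series(d$traj)
  s <- d$system$structure
  tight <- detect_arrivals(ser, s, site_definition("empty", "resname PLP", 3.5, 8))
  loose <- detect_arrivals(ser, s, site_definition("empty", "resname PLP", 5, 8))
  both <- merge(tight, loose, by = "molecule_tag")
  arrived_tight <- !is.na(both$first_arrival_frame.x)
  expect_true(all(!is.na(both$first_arrival_frame.y[arrived_tight])))
  expect_true(all(both$first_arrival_frame.y[arrived_tight] <=
                  both$first_arrival_frame.x[arrived_tight]))
})

test_that("replicate counting reproduces planted per-site totals", {
  empty_rec <- detect_arrivals(walk_series(rep(100, 3)), anchor_structure(),
                               site_definition("empty", "resname PLP"))
  cnt <- count_reaching_replicates(empty_rec)
  expect_equal(cnt$counts$n_reaching, 0)

  # 30 replicates; plant A-type arrivals at "empty" in 16, at "occupied" in 25
  make_rec <- function(rep_id, site, arrived, type = "AHA-like") {
    data.frame(replicate = rep_id, molecule_tag = "AHA_01",
               substrate_type = type, site_id = site,
               first_arrival_frame = if (arrived) 5L else NA_integer_,
               retention_fraction = if (arrived) 1 else NA_real_)
  }
  recs <- do.call(rbind, c(
    lapply(1:30, function(r) make_rec(r, "empty", r <= 16)),
    lapply(1:30, function(r) make_rec(r, "occupied", r <= 25)),
    lapply(1:30, function(r) make_rec(r, "empty", FALSE, type = "HMD-like"))))
  class(recs) <- c("sc_arrivals", "data.frame")
  cnt <- count_reaching_replicates(recs, substrate_type = "AHA-like")
  expect_equal(cnt$counts$n_reaching[cnt$counts$site_id == "empty"], 16)
  expect_equal(cnt$counts$n_reaching[cnt$counts$site_id == "occupied"], 25)
  expect_equal(cnt$n_replicates, 30)
  expect_gt(cnt$fraction_any, 0.5)
  # the B-type class is empty: zero everywhere
  hmd <- count_reaching_replicates(recs, substrate_type = "HMD-like")
  expect_equal(hmd$counts$n_reaching, c(0, 0))
})

test_that("filtering to arriving molecules is a subset and idempotent", {
  d <- small_decoy(seed = 7)
  ser <- extract_centroid_series(d$traj)
  rec <- detect_arrivals(ser, d$system$structure, both_sites())
  sub <- filter_arriving(ser, rec)
  expect_equal(attr(sub, "n_molecules"), 3)
  expect_equal(nrow(sub), 3 * attr(ser, "n_frames"))
  expect_true(all(sub$molecule_tag %in% ser$molecule_tag))
  again <- filter_arriving(sub, rec)
  expect_equal(as.data.frame(again), as.data.frame(sub))

  none <- rec; none$first_arrival_frame <- NA_integer_
  expect_equal(nrow(filter_arriving(ser, none)), 0)
  all_arr <- rec; all_arr$first_arrival_frame <- 1L
  expect_equal(nrow(filter_arriving(ser, all_arr)), nrow(ser))
})

test_that("clustering arriving molecules recovers the planted path; the rest do not", {
  d <- small_decoy(seed = 7)
  ser <- extract_centroid_series(d$traj)
  rec <- detect_arrivals(ser, d$system$structure, both_sites())
  poly <- d$system$truth$channel

  arriving <- filter_type(filter_arriving(ser, rec), "AHA-like")
  run <- cluster_to_convergence(arriving)
  final <- run$clouds[[length(run$clouds)]]
  expect_true(all(dist_to_polyline(final$points, poly) < 6))

  non_tags <- setdiff(unique(ser$molecule_tag),
                      unique(arriving$molecule_tag))
  free <- sc_centroid_series(
    as.data.frame(ser)[ser$molecule_tag %in% non_tags &
                       ser$substrate_type == "AHA-like", ])
  run_free <- cluster_to_convergence(as_cloud(free))
  final_free <- run_free$clouds[[length(run_free$clouds)]]
  expect_gt(max(dist_to_polyline(final_free$points, poly)), 6)
})
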