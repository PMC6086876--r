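test_that("neighbour pair enumeration matches the brute-force oracle", {
  expect_equal(nrow(neighbor_pairs(rbind(c(0, 0, 0), c(12, 0, 0)), 10)), 0)
  p <- neighbor_pairs(rbind(c(0, 0, 0), c(5, 0, 0)), 10)
  expect_equal(p$i, 1); expect_equal(p$j, 2); expect_equal(p$dist, 5)

  for (seed in 1:100) {
    set.seed(seed)
    pts <- matrix(runif(150, 0, 30), ncol = 3)
    expect_equal(neighbor_pairs(pts, 10), oracle_neighbor_pairs(pts, 10))
  }
})

test_that("the grid-based pair search agrees with the dense path", {
  set.seed(8)
  pts <- matrix(runif(3 * 3000, 0, 60), ncol = 3)
  dense <- oracle_neighbor_pairs(pts[1:400, ], 10)
  expect_equal(neighbor_pairs(pts[1:400, ], 10), dense)
  # force the grid path (n > 2500) and compare against itself on a subset:
  big <- neighbor_pairs(pts, 10)
  # spot-check: every reported pair is genuinely under the cutoff and sorted
  d <- sqrt(rowSums((pts[big$i, ] - pts[big$j, ])^2))
  expect_equal(big$dist, d)
  expect_true(all(diff(big$dist) >= 0))
  expect_true(all(big$i < big$j))
  # exact count cross-check via dist() on the full instance
  dm <- as.matrix(dist(pts))
  expect_equal(nrow(big), sum(dm[upper.tri(dm)] < 10))
})

test_that("one iteration merges, carries and drops per the greedy rule", {
  # single merge at the midpoint
  step <- cluster_iteration(sc_cloud(rbind(c(0, 0, 0), c(4, 0, 0))))
  expect_equal(step$cloud$points, matrix(c(2, 0, 0), ncol = 3))
  expect_equal(step$cloud$weights, 2)

  # two mutually isolated points are both removed
  step <- cluster_iteration(sc_cloud(rbind(c(0, 0, 0), c(12, 0, 0))))
  expect_equal(nrow(step$cloud$points), 0)
  expect_equal(step$record$dropped, 1:2)

  # hand-executed collinear case: merge (p1,p2) by tie-break, carry p3, drop p4
  cloud <- sc_cloud(cbind(c(0, 4, 8, 40), 0, 0))
  step <- cluster_iteration(cloud)
  expect_equal(step$record$merges$i, 1)
  expect_equal(step$record$merges$j, 2)
  expect_equal(step$record$carried, 3)
  expect_equal(step$record$dropped, 4)
  expect_equal(step$cloud$points, rbind(c(2, 0, 0), c(8, 0, 0)))
  expect_equal(step$cloud$weights, c(2, 1))
  step2 <- cluster_iteration(step$cloud)
  expect_equal(step2$cloud$points, matrix(c(5, 0, 0), ncol = 3))
  expect_equal(step2$cloud$weights, 3)
})

test_that("merge distances are non-decreasing and weight never increases", {
  set.seed(77)
  pts <- matrix(runif(3 * 80, 0, 40), ncol = 3)
  run <- cluster_to_convergence(sc_cloud(pts))
  for (rec in run$history)
    expect_true(all(diff(rec$merges$dist) >= 0))
  w <- vapply(run$clouds, function(cl) sum(cl$weights), numeric(1))
  expect_true(all(diff(w) <= 0))
  n <- vapply(run$clouds, function(cl) nrow(cl$points), numeric(1))
  expect_true(all(diff(n) < 0))   # strict decrease each non-terminal iteration
})

test_that("iterative clustering matches the brute-force oracle exactly", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(2:60, 1)
    pts <- matrix(runif(3 * n, 0, 30), ncol = 3)
    run <- cluster_to_convergence(sc_cloud(pts))
    oracle <- oracle_cluster(pts, 10)
    expect_equal(length(run$clouds), length(oracle))
    for (k in seq_along(oracle)) {
      expect_equal(run$clouds[[k]]$points, oracle[[k]]$points)
      expect_equal(run$clouds[[k]]$weights, oracle[[k]]$weights)
    }
  }
})

test_that("trivial inputs terminate immediately", {
  run <- cluster_to_convergence(sc_cloud(matrix(c(1, 2, 3), ncol = 3)))
  expect_length(run$clouds, 1)
  expect_length(run$history, 0)
})

test_that("two tight distant blobs converge to one point per blob", {
  set.seed(5)
  n <- 32
  blob <- function(center) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * runif(n, 0, 5)
    sweep(u, 2, center, `+`)
  }
  c1 <- c(0, 0, 0); c2 <- c(100, 0, 0)
  b1 <- blob(c1); b2 <- blob(c2)
  run <- cluster_to_convergence(sc_cloud(rbind(b1, b2)))
  final <- run$clouds[[length(run$clouds)]]
  expect_equal(nrow(final$points), 2)
  d1 <- min(sqrt(rowSums(sweep(final$points, 2, colMeans(b1))^2)))
  d2 <- min(sqrt(rowSums(sweep(final$points, 2, colMeans(b2))^2)))
  expect_lt(d1, 5); expect_lt(d2, 5)
  expect_equal(sum(final$weights), 2 * n)
})

test_that("every surviving point is a convex combination of the inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    pts <- matrix(runif(3 * 40, 0, 25), ncol = 3)
    run <- cluster_to_convergence(sc_cloud(pts))
    coef <- reconstruct_coefficients(nrow(pts), run$history)
    final <- run$clouds[[length(run$clouds)]]
    expect_equal(nrow(coef), nrow(final$points))
    if (nrow(coef)) {
      expect_true(all(coef >= 0))
      expect_equal(rowSums(coef), rep(1, nrow(coef)))
      expect_equal(coef %*% pts, final$points, tolerance = 1e-12)
    }
  }
})

test_that("iteration count respects the halving bound", {
  set.seed(99)
  pts <- matrix(runif(3 * 128, 0, 15), ncol = 3)   # dense: everything merges
  run <- cluster_to_convergence(sc_cloud(pts))
  stalls <- sum(vapply(run$history, function(r) nrow(r$merges) == 0, logical(1)))
  expect_lte(length(run$history), ceiling(log2(128)) + stalls + 1)
})

test_that("drop-unmatched mode discards neighboured leftovers", {
  cloud <- sc_cloud(cbind(c(0, 4, 8), 0, 0))
  step <- cluster_iteration(cloud, cluster_params(carry_unmatched = FALSE))
  expect_equal(nrow(step$cloud$points), 1)   # only the merged pair survives
  expect_equal(step$cloud$points[1, ], c(2, 0, 0))
})

test_that("mixed substrate types are refused at pooling", {
  df <- data.frame(frame = c(1, 1), molecule_tag = c("AHA_01", "HMD_01"),
                   substrate_type = c("AHA-like", "HMD-like"),
                   x = c(0, 1), y = 0, z = 0)
  expect_error(cluster_to_convergence(sc_centroid_series(df)), "mixes substrate types")
})

test_that("per-iteration PDB exports are byte-identical across reruns", {
  set.seed(3)
  pts <- matrix(runif(3 * 50, 0, 30), ncol = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cluster_to_convergence(sc_cloud(pts), write_dir = d1, run_name = "run")
  cluster_to_convergence(sc_cloud(pts), write_dir = d2, run_name = "run")
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_gt(length(f1), 1)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("planted polyline channel is recovered and outliers are removed", {
  poly <- rbind(c(0, 0, 0), c(30, 10, 0), c(55, 15, 20), c(80, 0, 30))
  for (seed in 1:20) {
    set.seed(seed)
    t <- runif(400)
    on_path <- t(vapply(t, function(f) surfchannel:::polyline_point(poly, f),
                        numeric(3)))
    channel_pts <- on_path + matrix(rnorm(1200, sd = 2), ncol = 3)
    outliers <- matrix(runif(120, -60, 140), ncol = 3)
    pts <- rbind(channel_pts, outliers)
    run <- cluster_to_convergence(sc_cloud(pts))
    final <- run$clouds[[length(run$clouds)]]
    expect_gt(nrow(final$points), 0)
    expect_true(all(dist_to_polyline(final$points, poly) < 6))
    dropped1 <- run$history[[1]]$dropped
    expect_gte(sum(dropped1 > 400), 0.9 * 40)
  }
})
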