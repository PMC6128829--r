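# DBSCAN semantics against the brute-force oracle, parameter draws, plume
# attribution, and the moving-window sweep statistic.

test_that("dbscan handles degenerate configurations", {
  # 10 coincident points, minpts = 10: a single cluster of 10
  pts <- matrix(rep(c(5, 5), each = 10), ncol = 2)
  lab <- dbscan(pts, eps = 1, minpts = 10)
  expect_equal(lab, rep(1L, 10))
  # all pairwise distances beyond eps: all noise
  far <- cbind(seq(0, 900, by = 100), 0)
  expect_equal(dbscan(far, eps = 50, minpts = 2), rep(0L, 10))
})

test_that("dbscan agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    pts <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
    eps <- runif(1, 25, 200)
    minpts <- sample(2:10, 1)
    expect_equal(dbscan(pts, eps, minpts), oracle_dbscan(pts, eps, minpts),
                 info = sprintf("instance %d (n=%d eps=%.1f minpts=%d)",
                                i, n, eps, minpts))
  }
})

test_that("parameter draws are uniform within the configured ranges", {
  cfg <- sweep_config(n_draws = 1000, seed = 4L)
  d <- draw_parameters(cfg)
  expect_equal(nrow(d), 1000)
  expect_true(all(d$eps >= 25 & d$eps <= 200))
  expect_true(all(d$minpts %in% 4:10))
  # reproducible per seed
  expect_identical(d, draw_parameters(cfg))
  expect_false(identical(d$eps, draw_parameters(cfg, seed = 5L)$eps))
  # minPts frequencies within 4-sigma multinomial error at 1e5 draws
  big <- draw_parameters(sweep_config(n_draws = 1e5, seed = 8L))
  freq <- table(big$minpts) / 1e5
  se <- sqrt((1 / 7) * (6 / 7) / 1e5)
  expect_true(all(abs(freq - 1 / 7) < 4 * se))
})

test_that("plume clusters are attributed by centroid position", {
  g <- test_geometry()
  src <- c(mean(range(g$kronebreen[, 1])), mean(range(g$kronebreen[, 2])))
  near <- sweep(matrix(rnorm(24, 0, 20), ncol = 2), 2, src + c(100, 0), "+")
  labs <- rep(1L, 12)
  expect_true(find_plume_clusters(labs, near, g)$plume_found)
  # a mid-fjord cluster is not a plume cluster
  mid <- sweep(matrix(rnorm(24, 0, 20), ncol = 2), 2,
               c(mean(g$fjord[, 1]), mean(g$fjord[, 2])), "+")
  out <- find_plume_clusters(labs, mid, g)
  expect_false(out$plume_found)
  expect_gt(out$clusters$terminus_distance, g$buffer_distance)
  # no clusters at all
  expect_false(find_plume_clusters(rep(0L, 12), mid, g)$plume_found)
})

test_that("sweep extremes: dense terminus blob 100%, sparse or tiny 0%", {
  g <- test_geometry()
  src <- c(mean(range(g$kronebreen[, 1])), mean(range(g$kronebreen[, 2])))
  cfg <- sweep_config(n_draws = 300, seed = 2L)
  # 12 dives within a 10 m blob at the terminus: every draw clusters
  set.seed(1)
  blob <- sweep(matrix(runif(24, -5, 5), ncol = 2), 2, src + c(30, 0), "+")
  dates <- rep(as.Date("2012-08-10"), 12)
  sw <- windowed_sweep(dates, blob, g, cfg,
                       date_range = as.Date(c("2012-08-10", "2012-08-10")))
  expect_equal(sw$series$pct_tests, 100)
  expect_equal(sw$series$n_profiles, 12L)
  # 3 profiles cannot reach the smallest minPts
  sw3 <- windowed_sweep(dates[1:3], blob[1:3, ], g, cfg,
                        date_range = as.Date(c("2012-08-10", "2012-08-10")))
  expect_equal(sw3$series$pct_tests, 0)
  # sparse scatter with spacing >> 200 m never clusters
  grid_pts <- as.matrix(expand.grid(x = seq(431000, 437000, by = 600),
                                    y = seq(8750500, 8754500, by = 600)))
  swsp <- windowed_sweep(rep(as.Date("2012-08-10"), nrow(grid_pts)), grid_pts,
                         g, cfg,
                         date_range = as.Date(c("2012-08-10", "2012-08-10")))
  expect_equal(swsp$series$pct_tests, 0)
  # empty windows yield 0% with zero profiles
  swe <- windowed_sweep(dates, blob, g, cfg,
                        date_range = as.Date(c("2012-09-01", "2012-09-03")))
  expect_true(all(swe$series$pct_tests == 0))
  expect_true(all(swe$series$n_profiles == 0))
})

test_that("sweep is reproducible and monotone under densification", {
  g <- test_geometry()
  src <- c(mean(range(g$kronebreen[, 1])), mean(range(g$kronebreen[, 2])))
  set.seed(33)
  pts <- sweep(matrix(rnorm(20, 0, 60), ncol = 2), 2, src + c(150, 0), "+")
  dates <- rep(as.Date("2012-08-10"), 10)
  cfg <- sweep_config(n_draws = 400, seed = 6L)
  dr <- as.Date(c("2012-08-10", "2012-08-10"))
  s1 <- windowed_sweep(dates, pts, g, cfg, date_range = dr)
  s2 <- windowed_sweep(dates, pts, g, cfg, date_range = dr)
  expect_identical(s1$series, s2$series)
  # adding points inside the cluster footprint cannot lower pct_tests
  centre <- colMeans(pts)
  denser <- rbind(pts, matrix(rep(centre, 5), ncol = 2, byrow = TRUE))
  s3 <- windowed_sweep(c(dates, rep(dates[1], 5)), denser, g, cfg,
                       date_range = dr)
  expect_gte(s3$series$pct_tests, s1$series$pct_tests)
})

test_that("per-draw records are complete for non-empty windows", {
  g <- test_geometry()
  src <- c(mean(range(g$kronebreen[, 1])), mean(range(g$kronebreen[, 2])))
  pts <- sweep(matrix(rnorm(16, 0, 40), ncol = 2), 2, src + c(60, 0), "+")
  cfg <- sweep_config(n_draws = 50, seed = 9L)
  sw <- windowed_sweep(rep(as.Date("2012-08-12"), 8), pts, g, cfg,
                       date_range = as.Date(c("2012-08-11", "2012-08-13")))
  expect_true(all(vapply(sw$per_draw, nrow, 0L) == 50))
  pd <- sw$per_draw[[2]]
  expect_true(all(c("eps", "minpts", "n_clusters", "plume_found") %in%
                    names(pd)))
  # window series percentages stay within [0, 100]
  expect_true(all(sw$series$pct_tests >= 0 & sw$series$pct_tests <= 100))
  expect_true(all(sw$series$pct_profiles_in_clusters >= 0 &
                    sw$series$pct_profiles_in_clusters <= 100))
})
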