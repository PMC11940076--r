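# temporal-neighborhood and core-fix semantics -------------------------------

test_that("temporal neighborhood is the maximal gap-bounded run containing p", {
  x <- track(time = c(0, 2, 4, 30, 32) * 3600, lat = rep(0, 5), lon = rep(0, 5))
  # gap 4h -> 30h (26 h) breaks the run; p at hour 2
  expect_equal(temporal_neighborhood(x, 2, 1:5, "6h"), 1:3)
  # p on the far side of the break
  expect_equal(temporal_neighborhood(x, 4, 1:5, "6h"), 4:5)
  # singleton neighborhood
  expect_equal(temporal_neighborhood(x, 3, 3, "6h"), 3)
  # all gaps exceed the bound: p alone
  expect_equal(temporal_neighborhood(x, 2, 1:5, "1h"), 2)
  # the neighborhood must contain p
  expect_error(temporal_neighborhood(x, 1, 2:3, "6h"), "contain")
})

test_that("dwell test is inclusive at the threshold", {
  x <- track(time = c(0, 36, 72) * 3600, lat = rep(0, 3), lon = rep(0, 3))
  expect_false(is_core_point(x, 1:2, "72h"))   # span 36 h
  expect_true(is_core_point(x, 1:3, "72h"))    # span exactly 72 h
  expect_true(is_core_point(x, 1:3, "70h"))
  expect_error(is_core_point(x, integer(0), "72h"), "non-empty")
})

# full algorithm --------------------------------------------------------------

test_that("degenerate inputs are handled", {
  empty <- track(time = numeric(0), lat = numeric(0), lon = numeric(0))
  fit <- tdbscan(empty)
  expect_equal(fit$n_clusters, 0L)
  expect_length(fit$cluster, 0)
  # duplicate fixes are legal, distinct points
  x <- track(time = rep(seq(0, 96 * 3600, by = 3600), each = 2),
             lat = rep(10, 194), lon = rep(20, 194))
  fit <- tdbscan(x, eps_km = 1)
  expect_equal(fit$n_clusters, 1L)
  expect_true(all(fit$cluster == 0L))
  expect_error(tdbscan(x, eps_km = -1), "eps_km")
})

test_that("two distant stopovers joined by a flight leg give two clusters", {
  sim <- scenario_track("two_stop_flyway", seed = 1)
  fit <- tdbscan(sim$track)
  expect_equal(fit$n_clusters, 2L)
  # flight fixes (truth -1) are noise: far from either site
  mid <- sim$truth$labels == -1L
  d0 <- haversine_km(sim$track$lat, sim$track$lon, 45, 100)
  d1 <- haversine_km(sim$track$lat, sim$track$lon, 45 + 1000 / 111.195, 100)
  far <- mid & d0 > 25 & d1 > 25
  expect_true(all(fit$cluster[far] == -1L))
})

test_that("the same site visited one year apart forms two clusters; the
           spatial-only baseline merges them", {
  sim <- scenario_track("interannual_revisit", seed = 4)
  ft <- tdbscan(sim$track)
  fd <- dbscan_baseline(sim$track, eps_km = 25, min_pts = 4)
  expect_equal(ft$n_clusters, 2L)
  expect_equal(fd$n_clusters, 1L)
  # each year's fixes in one cluster each
  yr <- as.integer(format(sim$track$time, "%Y"))
  expect_equal(length(unique(ft$cluster[yr == 2023 & ft$cluster >= 0])), 1L)
  expect_equal(length(unique(ft$cluster[yr == 2024 & ft$cluster >= 0])), 1L)
})

test_that("engine matches the plain-R reference implementation", {
  skip_if_not_installed("geosphere")
  for (seed in 1:4) {
    x <- random_track(180, seed)
    ref <- ref_tdbscan(x, eps_km = 60, min_stay_s = 30 * 3600,
                       max_interval_s = 12 * 3600)
    got <- tdbscan(x, eps_km = 60, min_stay = 30 * 3600,
                   max_interval = 12 * 3600,
                   use_quadtree = FALSE, use_hull = FALSE)
    expect_identical(got$cluster, ref$cluster)
    expect_identical(got$is_core, ref$is_core)
    expect_identical(got$n_clusters, ref$n_clusters)
    # quadtree must not change anything
    got_qt <- tdbscan(x, eps_km = 60, min_stay = 30 * 3600,
                      max_interval = 12 * 3600, use_hull = FALSE)
    expect_identical(got_qt$cluster, ref$cluster)
  }
})

test_that("labeling invariants hold across scenarios and modes", {
  for (nm in c("two_stop_flyway", "multi_stop_migration", "uniform_noise")) {
    sim <- scenario_track(nm, seed = 9)
    for (hull in c(TRUE, FALSE)) {
      fit <- tdbscan(sim$track, use_hull = hull)
      lab <- fit$cluster
      expect_true(all(lab >= -1L & lab < fit$n_clusters))
      # every cluster non-empty and containing >= 1 core fix
      if (fit$n_clusters > 0)
        for (k in 0:(fit$n_clusters - 1)) {
          expect_gt(sum(lab == k), 0)
          expect_gt(sum(fit$is_core & lab == k), 0)
        }
      # core implies clustered; noise is never core
      expect_true(all(lab[fit$is_core] != -1L))
    }
  }
})

test_that("duplicating the track shifted by a year doubles the clusters", {
  sim <- scenario_track("two_stop_flyway", seed = 6)
  x <- sim$track
  shifted <- x
  shifted$time <- shifted$time + 366 * 86400
  both <- track(time = c(x$time, shifted$time),
                lat = c(x$lat, shifted$lat), lon = c(x$lon, shifted$lon))
  f1 <- tdbscan(x)
  f2 <- tdbscan(both)
  expect_equal(f2$n_clusters, 2L * f1$n_clusters)
  # the first copy is labeled exactly as the original
  n <- nrow(x)
  expect_identical(f2$cluster[seq_len(n)], f1$cluster)
  # the second copy reproduces the same partition under renumbering
  expect_equal(recognition_difference_rate(f2$cluster[(n + 1):(2 * n)],
                                           f1$cluster), 0)
})

test_that("scan order only renumbers clusters; core assignments are stable", {
  sim <- scenario_track("multi_stop_migration", seed = 3)
  base <- tdbscan(sim$track, use_hull = FALSE)
  part0 <- core_partition(base)
  for (s in c(101, 202)) {
    alt <- tdbscan(sim$track, use_hull = FALSE, shuffle_seed = s)
    expect_equal(alt$n_clusters, base$n_clusters)
    expect_identical(alt$is_core, base$is_core)
    expect_identical(core_partition(alt), part0)
  }
})

test_that("hull-guided expansion enqueues a subset of the added fixes", {
  db <- scenario_track("dense_blob", seed = 1)
  on <- tdbscan(db$track, use_hull = TRUE)
  off <- tdbscan(db$track, use_hull = FALSE)
  expect_lt(on$counts$queries, off$counts$queries / 10)
  expect_lte(recognition_difference_rate(on, off), 0.01)
})

# baseline DBSCAN -------------------------------------------------------------

test_that("baseline DBSCAN handles all-noise and single-blob inputs", {
  # pairwise distances all > eps, min_pts 2 -> all noise
  x <- track(time = 1:5 * 3600, lat = c(0, 10, 20, 30, 40), lon = rep(0, 5))
  fit <- dbscan_baseline(x, eps_km = 50, min_pts = 2)
  expect_true(all(fit$cluster == -1L))
  # one tight blob, generous eps -> one cluster
  set.seed(8)
  y <- track(time = 1:50 * 3600, lat = 40 + rnorm(50, sd = 0.01),
             lon = 100 + rnorm(50, sd = 0.01))
  fit <- dbscan_baseline(y, eps_km = 20, min_pts = 4)
  expect_equal(fit$n_clusters, 1L)
  expect_true(all(fit$cluster == 0L))
  expect_error(dbscan_baseline(y, eps_km = 20, min_pts = 0), "min_pts")
})

test_that("baseline DBSCAN reproduces an independent implementation", {
  # fixture: three well-separated Gaussian blobs plus three far-out
  # singletons; expected labels frozen from scikit-learn's DBSCAN
  # (haversine metric, eps 15 km, min_samples 4) on identical input
  set.seed(42)
  centers <- data.frame(lat = c(30, 31.2, 30.6), lon = c(110, 110.8, 112.1))
  pts <- do.call(rbind, lapply(1:3, function(i)
    data.frame(lat = centers$lat[i] + rnorm(25, sd = 0.03),
               lon = centers$lon[i] + rnorm(25, sd = 0.03))))
  far <- data.frame(lat = c(35, 36, 25), lon = c(105, 118, 115))
  d <- rbind(pts, far)
  x <- track(time = seq_len(nrow(d)) * 3600, lat = d$lat, lon = d$lon)
  fit <- dbscan_baseline(x, eps_km = 15, min_pts = 4)
  expected <- c(rep(0L, 25), rep(1L, 25), rep(2L, 25), rep(-1L, 3))
  expect_identical(fit$cluster, expected)
  expect_equal(sum(fit$is_core), 75L)
})
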