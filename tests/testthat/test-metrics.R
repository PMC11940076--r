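# Calinski-Harabasz ----------------------------------------------------------

test_that("CH equals a direct evaluation of the formula", {
  # hand-checkable pair of clusters in planar km
  x <- track(time = 1:4, lat = c(0, 1, 10, 11) / 111.195,
             lon = rep(0, 4))
  res <- calinski_harabasz(x, c(0L, 0L, 1L, 1L))
  p <- project_local(x$lat, x$lon, mean(x$lat), mean(x$lon))
  expect_equal(res$ch, ref_ch(p$x, p$y, c(0, 0, 1, 1)), tolerance = 1e-9)
  # randomized labelings
  for (seed in 1:5) {
    y <- random_track(120, seed)
    lab <- sample(0:3, 120, replace = TRUE)
    res <- calinski_harabasz(y, lab)
    p <- project_local(y$lat, y$lon, mean(y$lat), mean(y$lon))
    expect_equal(res$ch, ref_ch(p$x, p$y, lab), tolerance = 1e-9)
  }
})

test_that("between + within dispersion equals total sum of squares", {
  set.seed(23)
  y <- random_track(200, 23)
  lab <- sample(0:4, 200, replace = TRUE)
  res <- calinski_harabasz(y, lab)
  p <- project_local(y$lat, y$lon, mean(y$lat), mean(y$lon))
  tot <- sum((p$x - mean(p$x))^2 + (p$y - mean(p$y))^2)
  expect_equal(res$between_ss + res$within_ss, tot, tolerance = 1e-9)
})

test_that("CH is undefined for degenerate labelings and diverges as
           clusters collapse", {
  x <- random_track(50, 1)
  expect_error(calinski_harabasz(x, rep(0L, 50)), "k < 2")
  expect_error(calinski_harabasz(x, rep(-1L, 50)), "no clustered")
  expect_error(calinski_harabasz(x, 0:49), "n <= k")
  # two point-mass clusters: zero within-dispersion, infinite score
  z <- track(time = 1:6, lat = c(0, 0, 0, 1, 1, 1), lon = rep(0, 6))
  res <- calinski_harabasz(z, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_gt(res$ch, 1e300)
  # noise excluded by default, counted when asked
  w <- random_track(60, 2)
  lab <- c(rep(0L, 30), rep(1L, 25), rep(-1L, 5))
  expect_equal(calinski_harabasz(w, lab)$n, 55)
  expect_equal(calinski_harabasz(w, lab, include_noise = TRUE)$n, 60)
})

# recognition difference rate -------------------------------------------------

test_that("difference rate is zero for identical or renumbered labelings", {
  set.seed(4)
  lab <- sample(c(-1L, 0L, 1L, 2L), 200, replace = TRUE)
  expect_equal(recognition_difference_rate(lab, lab), 0)
  perm <- c(2L, 0L, 1L)
  relab <- lab
  relab[lab >= 0] <- perm[lab[lab >= 0] + 1L]
  expect_equal(recognition_difference_rate(lab, relab), 0)
})

test_that("difference rate is one when no point can agree", {
  a <- rep(0L, 10)
  b <- rep(-1L, 10)
  expect_equal(recognition_difference_rate(a, b), 1)
  expect_error(recognition_difference_rate(1:3, 1:4), "same point set")
})

test_that("difference rate counts overlap-matched disagreements", {
  # b splits a's cluster 0 (6 vs 4 points): parent matches larger child
  a <- c(rep(0L, 10), rep(1L, 4))
  b <- c(rep(0L, 6), rep(2L, 4), rep(1L, 4))
  expect_equal(recognition_difference_rate(a, b), 4 / 14)
})

test_that("difference rate is a symmetric pseudo-metric on random pairs", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 80
    a <- sample(c(-1L, 0L, 1L, 2L, 3L), n, replace = TRUE)
    b <- sample(c(-1L, 0L, 1L, 2L), n, replace = TRUE)
    r1 <- recognition_difference_rate(a, b)
    r2 <- recognition_difference_rate(b, a)
    expect_equal(r1, r2)
    expect_gte(r1, 0)
    expect_lte(r1, 1)
    expect_equal(recognition_difference_rate(a, a), 0)
  }
})

# confusion report -------------------------------------------------------------

test_that("confusion report conserves counts and scores exact matches", {
  set.seed(10)
  a <- sample(c(-1L, 0L, 1L), 50, replace = TRUE)
  b <- sample(c(-1L, 0L, 1L, 2L), 50, replace = TRUE)
  rep <- confusion_report(a, b)
  expect_equal(sum(rep$table), 50)
  expect_equal(unname(rowSums(rep$table)),
               unname(as.vector(table(a))))
  expect_equal(unname(colSums(rep$table)),
               unname(as.vector(table(b))))
  # identical labelings: diagonal table, all Jaccard 1
  rep2 <- confusion_report(a, a)
  expect_true(all(rep2$matches$jaccard == 1))
  expect_equal(rep2$difference_rate, 0)
})
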