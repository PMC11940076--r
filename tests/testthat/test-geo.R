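test_that("haversine distance matches closed-form great-circle arcs", {
  expect_identical(haversine_km(0, 0, 0, 0), 0)
  # quarter and half circumference with R = 6371 km
  expect_equal(haversine_km(0, 0, 0, 90), pi * 6371 / 2, tolerance = 1e-12)
  expect_equal(haversine_km(0, 0, 90, 0), pi * 6371 / 2, tolerance = 1e-12)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-12)
})

test_that("haversine is symmetric, non-negative and triangle-consistent", {
  set.seed(7)
  n <- 200
  lat <- runif(n, -80, 80)
  lon <- runif(n, -179, 179)
  i <- sample(n, 60, replace = TRUE)
  j <- sample(n, 60, replace = TRUE)
  k <- sample(n, 60, replace = TRUE)
  dij <- haversine_km(lat[i], lon[i], lat[j], lon[j])
  dji <- haversine_km(lat[j], lon[j], lat[i], lon[i])
  expect_true(all(abs(dij - dji) < 1e-9))
  expect_true(all(dij >= 0))
  dik <- haversine_km(lat[i], lon[i], lat[k], lon[k])
  dkj <- haversine_km(lat[k], lon[k], lat[j], lon[j])
  expect_true(all(dij <= dik + dkj + 1e-6))
})

test_that("haversine agrees with an independent implementation", {
  skip_if_not_installed("geosphere")
  set.seed(11)
  a <- cbind(runif(50, -179, 179), runif(50, -85, 85))  # lon, lat
  b <- cbind(runif(50, -179, 179), runif(50, -85, 85))
  ours <- haversine_km(a[, 2], a[, 1], b[, 2], b[, 1])
  ref <- geosphere::distHaversine(a, b, r = 6371000) / 1000
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("haversine rejects invalid coordinates", {
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 181, 0, 0), "longitude")
  expect_error(haversine_km(NaN, 0, 0, 0), "NA")
})

test_that("local projection maps the origin to (0,0) and degrees to km", {
  p <- project_local(c(45, 46), c(100, 100), 45, 100)
  expect_equal(p$x, c(0, 0))
  expect_equal(p$y, c(0, 111.195))
  expect_error(project_local(numeric(0), numeric(0), 0, 0), "at least one")
})

test_that("local projection distorts < 1% within 25 km at mid latitude", {
  set.seed(3)
  lat0 <- 45; lon0 <- 100
  # random points within ~25 km of the origin
  ang <- runif(300, 0, 2 * pi)
  rr <- sqrt(runif(300)) * 25
  lat <- lat0 + (rr * sin(ang)) / 111.195
  lon <- lon0 + (rr * cos(ang)) / (111.195 * cos(lat0 * pi / 180))
  hav <- haversine_km(lat0, lon0, lat, lon)
  p <- project_local(lat, lon, lat0, lon0)
  planar <- sqrt(p$x^2 + p$y^2)
  keep <- hav > 1  # relative error on non-degenerate distances
  expect_true(all(abs(planar[keep] - hav[keep]) / hav[keep] < 0.01))
})

test_that("convex hull handles canonical small inputs", {
  # triangle: all vertices kept, CCW from lowest-y point
  h <- convex_hull(c(0, 4, 2), c(0, 0, 3))
  expect_equal(h, c(1L, 2L, 3L))
  # unit square + center: interior point excluded
  h <- convex_hull(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  expect_setequal(h, 1:4)
  expect_equal(h[1], 1L)  # starts at lowest (y, x)
  # collinear points collapse to the two extremes
  h <- convex_hull(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(sort(h), c(1L, 4L))
  # duplicates removed, <= 2 distinct returned as-is
  expect_equal(sort(convex_hull(c(0, 0, 1), c(0, 0, 1))), c(1L, 3L))
  expect_equal(convex_hull(5, 5), 1L)
})

test_that("convex hull equals the brute-force half-plane hull", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(200)
    y <- rnorm(200)
    expect_setequal(convex_hull(x, y), brute_hull_vertices(x, y))
  }
})

test_that("every input point lies inside or on the hull (signed areas)", {
  set.seed(19)
  x <- runif(500); y <- runif(500)
  h <- convex_hull(x, y)
  hx <- x[h]; hy <- y[h]
  m <- length(h)
  for (e in seq_len(m)) {
    e2 <- if (e == m) 1L else e + 1L
    cr <- (hx[e2] - hx[e]) * (y - hy[e]) - (hy[e2] - hy[e]) * (x - hx[e])
    expect_true(all(cr >= -1e-12))  # CCW: nothing strictly right of an edge
  }
})
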