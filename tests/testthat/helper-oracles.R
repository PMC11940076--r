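# Independent oracles used across the suite.  These deliberately avoid the
# package's optimized code paths: plain R loops, linear scans, brute-force
# geometry.

# linear-scan haversine neighborhood (inclusive boundary), via geosphere
brute_radius_query <- function(lat, lon, clat, clon, eps_km) {
  d <- geosphere::distHaversine(cbind(lon, lat), c(clon, clat), r = 6371000)
  which(d / 1000 <= eps_km)
}

# brute-force convex hull vertex SET by the half-plane edge test:
# (i, j) is a hull edge iff every other point is strictly on its left
# (assumes points in general position: distinct, no 3 collinear)
brute_hull_vertices <- function(x, y) {
  n <- length(x)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
      if (all(cr[-c(i, j)] > 0)) on_hull[c(i, j)] <- TRUE
    }
  }
  which(on_hull)
}

# direct evaluation of the Calinski-Harabasz formula on planar points
ref_ch <- function(px, py, lab) {
  n <- length(lab)
  ks <- unique(lab)
  k <- length(ks)
  gx <- mean(px); gy <- mean(py)
  B <- 0; W <- 0
  for (g in ks) {
    m <- lab == g
    cx <- mean(px[m]); cy <- mean(py[m])
    B <- B + sum(m) * ((cx - gx)^2 + (cy - gy)^2)
    for (i in which(m)) W <- W + (px[i] - cx)^2 + (py[i] - cy)^2
  }
  (B / (k - 1)) / (W / (n - k))
}

# plain-R reference implementation of the dwell-time clustering:
# linear-scan neighborhoods, full-frontier expansion, no index
ref_tdbscan <- function(x, eps_km = 25, min_stay_s = 72 * 3600,
                        max_interval_s = 3 * 86400) {
  n <- nrow(x)
  tt <- as.numeric(x$time)
  lab <- rep(-1L, n)
  core <- rep(FALSE, n)
  visited <- rep(FALSE, n)
  k <- 0L
  nbrs <- function(i) brute_radius_query(x$lat, x$lon, x$lat[i], x$lon[i],
                                         eps_km)
  for (p in seq_len(n)) {
    if (visited[p] || lab[p] != -1L) next
    visited[p] <- TRUE
    Tn <- temporal_neighborhood(x, p, nbrs(p), max_interval_s)
    if (diff(range(tt[Tn])) < min_stay_s) next
    core[p] <- TRUE
    cid <- k
    k <- k + 1L
    newly <- Tn[lab[Tn] == -1L]
    lab[newly] <- cid
    queue <- newly[!visited[newly]]
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      if (visited[q]) next
      visited[q] <- TRUE
      Tq <- temporal_neighborhood(x, q, nbrs(q), max_interval_s)
      if (diff(range(tt[Tq])) < min_stay_s) next
      core[q] <- TRUE
      newly <- Tq[lab[Tq] == -1L]
      lab[newly] <- cid
      queue <- c(queue, newly[!visited[newly]])
    }
  }
  list(cluster = lab, is_core = core, n_clusters = k)
}

# small random track: a few loose spatial groups with time structure
random_track <- function(n, seed, spread_deg = 0.5, lat0 = 45, lon0 = 100,
                         gap_h = c(1, 10)) {
  set.seed(seed)
  g <- sample(1:4, n, replace = TRUE)
  lat <- lat0 + g * 0.8 + rnorm(n, sd = spread_deg)
  lon <- lon0 + g * 0.8 + rnorm(n, sd = spread_deg)
  tt <- cumsum(runif(n, gap_h[1] * 3600, gap_h[2] * 3600))
  track(time = tt + 1.6e9, lat = lat, lon = lon)
}

# fraction of points whose cluster matches under the greedy overlap matching
match_rate <- function(truth, labels) {
  1 - recognition_difference_rate(truth, labels)
}

# canonicalized core-point partition (groups sorted, ordered by their
# smallest member), for order-invariance checks modulo cluster renumbering
core_partition <- function(fit) {
  cores <- which(fit$is_core)
  p <- lapply(split(cores, fit$cluster[cores]), sort)
  unname(p[order(vapply(p, min, numeric(1)))])
}
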