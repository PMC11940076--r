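#' Spatiotemporal density clustering of a tracking dataset
#'
#' Clusters satellite fixes into stopover sites.  The method keeps
#' DBSCAN's spatial radius `eps_km` but replaces its minimum-neighbor
#' count with a dwell-time test: for each fix, the spatial neighborhood
#' (all fixes within `eps_km` great-circle distance) is sorted by time
#' and the maximal time-contiguous run containing the fix — consecutive
#' gaps no larger than `max_interval` — is its temporal neighborhood.
#' A fix is a *core* fix when that run spans at least `min_stay`.
#' Clusters are grown from core fixes through their temporal
#' neighborhoods, so two visits to the same location separated by more
#' than `max_interval` form two clusters, one per visit.
#'
#' Two performance devices, both result-preserving in intent, can be
#' toggled:
#' \describe{
#'   \item{`use_quadtree`}{neighborhood queries go through a quadtree
#'     spatial index instead of a linear scan.  Because the index prunes
#'     with a conservative bounding box and then applies the exact
#'     haversine filter, labels are identical with and without it.}
#'   \item{`use_hull`}{when a core fix adds its temporal neighborhood to
#'     a cluster, only the convex-hull vertices of the newly added fixes
#'     (in a local planar projection) are enqueued for further
#'     neighborhood queries, rather than all of them.  This skips
#'     redundant interior expansions; it can very occasionally miss
#'     points reachable only through an interior fix, changing on the
#'     order of 1% of assignments on dense data (see the package
#'     vignette).}
#' }
#'
#' The scan visits fixes in row order (deterministic); pass
#' `shuffle_seed` to randomize the visiting order instead.  Border fixes
#' reachable from two clusters keep the first label assigned.
#'
#' @param x A [track()] or a `data.frame` with columns `time`
#'   (`POSIXct`), `lat`, `lon`.
#' @param eps_km Spatial neighborhood radius in km.  Default 25, a
#'   scale suited to waterbird stopover sites.
#' @param min_stay Minimum dwell time for a core fix; seconds or a
#'   string like `"72h"` (default).
#' @param max_interval Maximum time gap between consecutive fixes of a
#'   temporal neighborhood; seconds or a string like `"3d"` (default).
#' @param use_quadtree Use the quadtree index for neighborhood queries.
#' @param use_hull Use convex-hull-guided cluster expansion.
#' @param shuffle_seed Optional integer; if given, fixes are visited in
#'   a seeded random order instead of row order.
#' @return An object of class `c("tdbscan", "stop_clustering")`: a list
#'   with elements
#'   \describe{
#'     \item{`cluster`}{integer per fix; `-1` = noise, clusters are
#'       `0..k-1` in discovery order,}
#'     \item{`is_core`}{logical per fix,}
#'     \item{`n_clusters`}{number of clusters `k`,}
#'     \item{`counts`}{operation counters: neighborhood `queries` and
#'       candidate `inspected` during pruning,}
#'     \item{`params`}{the resolved parameters,}
#'     \item{`data`}{the input track.}
#'   }
#'   `summary()` turns the fit into a stopover-site table; see
#'   [stopover_sites()].
#' @examples
#' sim <- simulate_track(scenario_library()$two_stop_flyway)
#' fit <- tdbscan(sim$track)
#' fit
#' summary(fit)
#' @export
tdbscan <- function(x, eps_km = 25, min_stay = "72h", max_interval = "3d",
                    use_quadtree = TRUE, use_hull = TRUE,
                    shuffle_seed = NULL) {
  x <- as_track(x)
  min_stay_s <- parse_duration(min_stay)
  max_interval_s <- parse_duration(max_interval)
  if (!is.finite(eps_km) || eps_km <= 0) stop("eps_km must be > 0")
  if (min_stay_s < 0) stop("min_stay must be >= 0")
  if (max_interval_s <= 0) stop("max_interval must be > 0")

  n <- nrow(x)
  scan_order <- seq_len(n) - 1L
  if (!is.null(shuffle_seed)) {
    old <- local_seed(shuffle_seed)
    on.exit(restore_seed(old), add = TRUE)
    scan_order <- sample(scan_order)
  }
  res <- cpp_tdbscan(x$lat, x$lon, time_seconds(x), as.integer(scan_order),
                     eps_km, min_stay_s, max_interval_s,
                     isTRUE(use_quadtree), isTRUE(use_hull))
  structure(
    list(cluster = res$labels, is_core = res$is_core,
         n_clusters = res$n_clusters,
         counts = list(queries = res$n_queries,
                       inspected = res$n_inspected),
         params = list(eps_km = eps_km, min_stay_s = min_stay_s,
                       max_interval_s = max_interval_s,
                       use_quadtree = isTRUE(use_quadtree),
                       use_hull = isTRUE(use_hull)),
         method = "T-DBSCAN",
         data = x, call = match.call()),
    class = c("tdbscan", "stop_clustering"))
}

#' Classic DBSCAN baseline on the same tracking data
#'
#' Spatial-only DBSCAN with the haversine metric, kept as a comparison
#' baseline: a fix is core when its `eps_km`-neighborhood (including
#' itself) holds at least `min_pts` fixes.  Ignoring time, it merges
#' revisits of the same site across periods into one cluster — the
#' failure mode the dwell-time method addresses.
#'
#' @inheritParams tdbscan
#' @param min_pts Minimum neighborhood size (including the fix itself)
#'   for a core fix; `>= 1`.
#' @return Object of class `c("dbscan_baseline", "stop_clustering")`,
#'   with the same fields as [tdbscan()].
#' @export
dbscan_baseline <- function(x, eps_km = 25, min_pts = 4L,
                            use_quadtree = TRUE) {
  x <- as_track(x)
  if (!is.finite(eps_km) || eps_km <= 0) stop("eps_km must be > 0")
  if (min_pts < 1) stop("min_pts must be >= 1")
  res <- cpp_dbscan(x$lat, x$lon, eps_km, as.integer(min_pts),
                    isTRUE(use_quadtree))
  structure(
    list(cluster = res$labels, is_core = res$is_core,
         n_clusters = res$n_clusters,
         counts = list(queries = res$n_queries,
                       inspected = res$n_inspected),
         params = list(eps_km = eps_km, min_pts = as.integer(min_pts),
                       use_quadtree = isTRUE(use_quadtree)),
         method = "DBSCAN",
         data = x, call = match.call()),
    class = c("dbscan_baseline", "stop_clustering"))
}

#' Temporal neighborhood of a fix within its spatial neighborhood
#'
#' Sorts the spatial neighborhood by time (ties by id) and returns the
#' maximal run containing `i` in which every consecutive time gap is at
#' most `max_interval`.
#'
#' @param x A [track()].
#' @param i 1-based row index of the query fix.
#' @param nbrs 1-based row indices of the spatial neighborhood of `i`;
#'   must contain `i`.
#' @param max_interval Gap bound; seconds or a duration string.
#' @return Sorted (by time, then id) integer vector of row indices,
#'   always containing `i`.
#' @export
temporal_neighborhood <- function(x, i, nbrs, max_interval) {
  x <- as_track(x)
  if (!(i %in% nbrs))
    stop("the spatial neighborhood must contain the query fix itself")
  gap <- parse_duration(max_interval)
  tt <- time_seconds(x)[nbrs]
  ord <- order(tt, nbrs)
  nbrs <- nbrs[ord]
  tt <- tt[ord]
  pos <- match(i, nbrs)
  lo <- pos
  while (lo > 1 && tt[lo] - tt[lo - 1] <= gap) lo <- lo - 1
  hi <- pos
  while (hi < length(nbrs) && tt[hi + 1] - tt[hi] <= gap) hi <- hi + 1
  nbrs[lo:hi]
}

#' Dwell-time (core fix) test
#'
#' A fix is core when its temporal neighborhood spans at least
#' `min_stay` (inclusive).
#'
#' @param x A [track()].
#' @param t_nbrs Row indices of a temporal neighborhood (non-empty).
#' @param min_stay Dwell threshold; seconds or a duration string.
#' @return Logical scalar.
#' @export
is_core_point <- function(x, t_nbrs, min_stay) {
  x <- as_track(x)
  if (length(t_nbrs) == 0L) stop("temporal neighborhood must be non-empty")
  tt <- time_seconds(x)[t_nbrs]
  (max(tt) - min(tt)) >= parse_duration(min_stay)
}

# run code under a temporary RNG seed, restoring the caller's state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
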