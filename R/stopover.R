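#' Summarize clusters as stopover sites
#'
#' One record per cluster (noise excluded): unweighted centroid of the
#' member fixes, arrival (earliest fix), departure (latest fix),
#' duration in days (1 decimal) and fix count, sorted by arrival.
#'
#' @param x A [track()] or `data.frame` with `time`/`lat`/`lon`.
#' @param cluster Integer labels per fix (`-1` = noise), e.g. the
#'   `cluster` field of a [tdbscan()] fit.  A fit object may be passed
#'   directly as `x`, in which case `cluster` is taken from it.
#' @return `data.frame` of class `stopover_sites` with columns
#'   `cluster`, `centroid_lat`, `centroid_lon`, `arrival`, `departure`
#'   (`POSIXct` UTC), `duration_days`, `n_fixes`.
#' @export
stopover_sites <- function(x, cluster = NULL) {
  if (inherits(x, "stop_clustering")) {
    cluster <- x$cluster
    x <- x$data
  }
  x <- as_track(x)
  stopifnot(length(cluster) == nrow(x))
  ids <- sort(unique(cluster[cluster >= 0]))
  rows <- lapply(ids, function(k) {
    m <- cluster == k
    tt <- x$time[m]
    data.frame(
      cluster = k,
      centroid_lat = mean(x$lat[m]),
      centroid_lon = mean(x$lon[m]),
      arrival = min(tt),
      departure = max(tt),
      duration_days = round(as.numeric(max(tt) - min(tt), units = "days"), 1),
      n_fixes = sum(m))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), centroid_lat = numeric(0),
               centroid_lon = numeric(0),
               arrival = as.POSIXct(character(0), tz = "UTC"),
               departure = as.POSIXct(character(0), tz = "UTC"),
               duration_days = numeric(0), n_fixes = integer(0))
  out <- out[order(out$arrival, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stopover_sites", "data.frame")
  out
}

#' @export
print.stopover_sites <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("No stopover sites (all fixes noise)\n")
    return(invisible(x))
  }
  cat(nrow(x), "stopover site(s):\n")
  df <- as.data.frame(x)
  df$arrival <- format(df$arrival, "%Y-%m-%d %H:%M", tz = "UTC")
  df$departure <- format(df$departure, "%Y-%m-%d %H:%M", tz = "UTC")
  df$centroid_lat <- round(df$centroid_lat, 4)
  df$centroid_lon <- round(df$centroid_lon, 4)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
print.stop_clustering <- function(x, ...) {
  n <- length(x$cluster)
  n_noise <- sum(x$cluster == -1L)
  cat(sprintf("%s clustering of %d fixes\n", x$method, n))
  if (x$method == "T-DBSCAN")
    cat(sprintf("  eps = %g km, min_stay = %gh, max_interval = %gh%s%s\n",
                x$params$eps_km, x$params$min_stay_s / 3600,
                x$params$max_interval_s / 3600,
                if (x$params$use_quadtree) "" else ", no quadtree",
                if (x$params$use_hull) "" else ", no hull"))
  else
    cat(sprintf("  eps = %g km, min_pts = %d\n",
                x$params$eps_km, x$params$min_pts))
  cat(sprintf("  clusters: %d   core fixes: %d   noise: %d (%.1f%%)\n",
              x$n_clusters, sum(x$is_core), n_noise,
              if (n) 100 * n_noise / n else 0))
  invisible(x)
}

#' @export
summary.stop_clustering <- function(object, ...) {
  stopover_sites(object)
}

#' Plot a clustered track
#'
#' Fixes in lon/lat, colored by cluster; noise in grey; stopover
#' centroids marked.
#'
#' @param x A [tdbscan()] or [dbscan_baseline()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stop_clustering <- function(x, ...) {
  d <- x$data
  lab <- x$cluster
  pal <- grDevices::hcl.colors(max(1L, x$n_clusters), "Dark 3")
  col <- ifelse(lab < 0, "grey70", pal[(lab %% length(pal)) + 1L])
  graphics::plot(d$lon, d$lat, col = col, pch = 16, cex = 0.5,
                 xlab = "Longitude", ylab = "Latitude",
                 main = sprintf("%s: %d cluster(s)", x$method, x$n_clusters),
                 ...)
  s <- stopover_sites(x)
  if (nrow(s))
    graphics::points(s$centroid_lon, s$centroid_lat, pch = 3, cex = 1.2,
                     lwd = 2)
  invisible(x)
}
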