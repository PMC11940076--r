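#' Read a tracking CSV
#'
#' Expects one row per fix with an ISO 8601 timestamp column and
#' latitude/longitude in decimal degrees.  Timestamps without a zone
#' designator are taken as UTC.  Rows with unparseable timestamps or
#' out-of-range coordinates are dropped with a message reporting the
#' counts; remaining rows are sorted by (timestamp, file order) and
#' given ids `0..n-1`.  Extra columns are preserved but ignored by the
#' algorithms.
#'
#' @param path CSV file path.
#' @param timestamp_col,lat_col,lon_col Column names in the file.
#' @return A [track()].
#' @export
read_track_csv <- function(path, timestamp_col = "timestamp",
                           lat_col = "latitude", lon_col = "longitude") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(timestamp_col, lat_col, lon_col), names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  tt <- parse_iso_time(as.character(raw[[timestamp_col]]))
  lat <- suppressWarnings(as.numeric(raw[[lat_col]]))
  lon <- suppressWarnings(as.numeric(raw[[lon_col]]))
  bad_time <- is.na(tt)
  bad_coord <- !bad_time &
    (is.na(lat) | is.na(lon) | lat < -90 | lat > 90 | lon < -180 | lon > 180)
  drop <- bad_time | bad_coord
  if (any(drop))
    message(sprintf(
      "read_track_csv: dropped %d row(s) (%d bad timestamp, %d bad coordinates) of %d",
      sum(drop), sum(bad_time), sum(bad_coord), nrow(raw)))
  keep <- which(!drop)
  if (!length(keep)) stop("no valid rows in ", path)
  keep <- keep[order(tt[keep], keep)]
  extra <- raw[keep, setdiff(names(raw), c(timestamp_col, lat_col, lon_col)),
               drop = FALSE]
  rownames(extra) <- NULL
  do.call(track, c(list(time = tt[keep], lat = lat[keep], lon = lon[keep]),
                   as.list(extra)))
}

# ISO 8601, 'T' or space separator, optional fractional seconds and 'Z'
parse_iso_time <- function(x) {
  x <- sub("Z$", "", sub(" ", "T", trimws(x)))
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  d <- is.na(out) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  out[d] <- as.POSIXct(x[d], format = "%Y-%m-%d", tz = "UTC")
  out
}

iso_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a track to CSV
#'
#' Columns `timestamp` (ISO 8601 UTC), `latitude`, `longitude` plus any
#' extra columns.  `read_track_csv()` of the result restores the track.
#'
#' @param x A [track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(x, path) {
  x <- as_track(x)
  out <- data.frame(timestamp = iso_utc(x$time),
                    latitude = x$lat, longitude = x$lon)
  extra <- setdiff(names(x), c("id", "time", "lat", "lon"))
  for (cn in extra) out[[cn]] <- x[[cn]]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-fix cluster labels alongside the input columns
#'
#' @param fit A `stop_clustering` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(fit, path) {
  stopifnot(inherits(fit, "stop_clustering"))
  x <- fit$data
  out <- data.frame(id = x$id, timestamp = iso_utc(x$time),
                    latitude = x$lat, longitude = x$lon,
                    cluster = fit$cluster, is_core = fit$is_core)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a stopover-site table to CSV
#' @param sites A [stopover_sites()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stopover_csv <- function(sites, path) {
  out <- data.frame(cluster_id = sites$cluster,
                    centroid_lat = sites$centroid_lat,
                    centroid_lon = sites$centroid_lon,
                    arrival_iso = iso_utc(sites$arrival),
                    departure_iso = iso_utc(sites$departure),
                    duration_days = sites$duration_days,
                    n_fixes = sites$n_fixes)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write stopover sites as a GeoJSON FeatureCollection
#'
#' RFC 7946 Point features, coordinates in `[lon, lat]` order, with the
#' same properties as the CSV writer.
#'
#' @inheritParams write_stopover_csv
#' @return `path`, invisibly.
#' @export
write_stopover_geojson <- function(sites, path) {
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sites$centroid_lon[i],
                                         sites$centroid_lat[i])),
         properties = list(cluster_id = sites$cluster[i],
                           arrival_iso = iso_utc(sites$arrival[i]),
                           departure_iso = iso_utc(sites$departure[i]),
                           duration_days = sites$duration_days[i],
                           n_fixes = sites$n_fixes[i]))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write run metrics as JSON
#'
#' Emits at least `n_clusters`, `n_noise` and `ch` (the
#' Calinski-Harabasz score, `null` when undefined for the labeling).
#'
#' @param fit A `stop_clustering` fit.
#' @param path Output path.
#' @return The metrics list, invisibly.
#' @export
write_metrics_json <- function(fit, path) {
  ch <- tryCatch(calinski_harabasz(fit)$ch, error = function(e) NULL)
  metrics <- list(n_points = length(fit$cluster),
                  n_clusters = fit$n_clusters,
                  n_noise = sum(fit$cluster == -1L),
                  n_core = sum(fit$is_core),
                  ch = ch,
                  queries = fit$counts$queries,
                  inspected = fit$counts$inspected)
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(metrics)
}

#' Write / read simulator ground truth
#'
#' Truth CSV has columns `point_id` (0-based) and `true_label`
#' (stopover visit index, `-1` = flight).
#'
#' @param sim A `sim_track` from [simulate_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(sim, path) {
  stopifnot(inherits(sim, "sim_track"))
  write.csv(data.frame(point_id = sim$track$id,
                       true_label = sim$truth$labels),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-point label CSV (`point_id`, label column)
#' @param path CSV path with columns `point_id` and a label column
#'   (`cluster` or `true_label`).
#' @return Integer label vector ordered by `point_id`.
#' @export
read_labels_csv <- function(path) {
  d <- read.csv(path)
  lab_col <- intersect(c("cluster", "true_label", "label"), names(d))
  if (!length(lab_col)) stop("no label column in ", path)
  id_col <- intersect(c("point_id", "id"), names(d))
  if (length(id_col)) d <- d[order(d[[id_col[1]]]), ]
  as.integer(d[[lab_col[1]]])
}
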