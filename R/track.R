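#' Construct a tracking dataset
#'
#' A track is a `data.frame` with one row per satellite fix and columns
#' `id` (0-based integer, unique), `time` (`POSIXct`, UTC), `lat`, `lon`
#' (decimal degrees WGS84).  Extra columns are carried along untouched.
#'
#' @param time `POSIXct` vector, or numeric seconds since the UTC epoch.
#' @param lat,lon Coordinates in decimal degrees.
#' @param ... Additional columns of the same length.
#' @return A `data.frame` of class `c("track", "data.frame")`.
#' @export
track <- function(time, lat, lon, ...) {
  if (is.numeric(time))
    time <- as.POSIXct(time, origin = "1970-01-01", tz = "UTC")
  stopifnot(inherits(time, "POSIXct"))
  n <- length(time)
  if (length(lat) == 1L) lat <- rep(lat, n)
  if (length(lon) == 1L) lon <- rep(lon, n)
  stopifnot(length(lat) == n, length(lon) == n)
  if (n > 0) {
    if (any(!is.finite(as.numeric(time)))) stop("timestamps must be finite")
    check_coords(lat, lon)
    check_lon_span(lon)
  }
  out <- data.frame(id = seq_len(n) - 1L, time = time,
                    lat = as.numeric(lat), lon = as.numeric(lon), ...)
  class(out) <- c("track", "data.frame")
  out
}

# coerce a data.frame-like input to a validated track
as_track <- function(x) {
  if (inherits(x, "track")) return(x)
  if (!is.data.frame(x))
    stop("expected a track or a data.frame with time/lat/lon columns")
  need <- c("time", "lat", "lon")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing track column(s): ", paste(miss, collapse = ", "))
  do.call(track, c(list(time = x$time, lat = x$lat, lon = x$lon),
                   x[setdiff(names(x), c("id", need))]))
}

#' Parse a humane duration string
#'
#' Grammar: a number followed by a unit suffix `s` (seconds), `m`
#' (minutes), `h` (hours) or `d` (days), e.g. `"72h"`, `"3d"`, `"90m"`.
#' Plain numeric input is taken as seconds.
#'
#' @param x Character scalar such as `"72h"`, or a number of seconds.
#' @return Duration in seconds (numeric scalar).
#' @export
parse_duration <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x) || x < 0)
      stop("duration must be a single non-negative number")
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("duration must be a scalar like '72h' or '3d'")
  m <- regmatches(x, regexec("^([0-9]+(?:\\.[0-9]+)?)([smhd])$", x))[[1]]
  if (length(m) != 3L)
    stop("cannot parse duration '", x,
         "'; expected <number><s|m|h|d>, e.g. '72h'")
  as.numeric(m[2]) * c(s = 1, m = 60, h = 3600, d = 86400)[[m[3]]]
}

time_seconds <- function(x) as.numeric(x$time)
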