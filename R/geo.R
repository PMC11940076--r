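#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere with mean earth radius 6371.0 km.
#' Vectors are recycled to the longest length.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84);
#'   latitudes in \[-90, 90\], longitudes in \[-180, 180\].
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 90)  # quarter of the equator, ~10007.5 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(c(lat1, lat2), c(lon1, lon2))
  cpp_haversine_km(as.numeric(lat1), as.numeric(lon1),
                   as.numeric(lat2), as.numeric(lon2))
}

#' Project coordinates to a local planar frame
#'
#' Equirectangular approximation about `origin`: x points east, y north,
#' both in km, using 111.195 km per degree of latitude and
#' `111.195 * cos(lat0)` km per degree of longitude.  Adequate for the
#' neighborhood scales the clustering operates at (distortion < 1% within
#' ~25 km of the origin at mid latitudes).
#'
#' @param lat,lon Coordinates in decimal degrees.
#' @param origin_lat,origin_lon Origin of the local frame, decimal degrees.
#' @return `data.frame` with columns `x`, `y` (km).
#' @export
project_local <- function(lat, lon, origin_lat, origin_lon) {
  if (length(lat) == 0L) stop("project_local() requires at least one point")
  check_coords(lat, lon)
  check_coords(origin_lat, origin_lon)
  data.frame(
    x = (lon - origin_lon) * cos(origin_lat * pi / 180) * 111.195,
    y = (lat - origin_lat) * 111.195
  )
}

#' Inverse of [project_local()]
#' @inheritParams project_local
#' @param x,y Planar offsets in km.
#' @return `data.frame` with columns `lat`, `lon`.
#' @keywords internal
local_to_geo <- function(x, y, origin_lat, origin_lon) {
  data.frame(
    lat = origin_lat + y / 111.195,
    lon = origin_lon + x / (111.195 * cos(origin_lat * pi / 180))
  )
}

#' Convex hull of planar points (Graham scan)
#'
#' Strictly convex hull: collinear interior-edge points are dropped.
#' Vertices are returned counter-clockwise starting from the lowest-y
#' (then lowest-x) point.  Exact duplicate coordinates are removed first;
#' inputs with two or fewer distinct points are returned as-is (ordered
#' by (y, x)).
#'
#' @param x,y Planar coordinates.
#' @return Integer vector of 1-based positions into `x`/`y`, in hull order.
#' @export
convex_hull <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(integer(0))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("convex_hull() requires finite coordinates")
  cpp_convex_hull(as.numeric(x), as.numeric(y)) + 1L
}

# validation shared by geometry and track ingestion
check_coords <- function(lat, lon) {
  if (any(is.na(lat)) || any(is.na(lon)))
    stop("coordinates must not be NA/NaN")
  if (any(lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]")
  if (any(lon < -180 | lon > 180))
    stop("longitude out of range [-180, 180]")
  invisible(TRUE)
}

# datasets spanning the antimeridian are not supported: the pruning box
# arithmetic assumes a contiguous longitude interval
check_lon_span <- function(lon) {
  if (length(lon) > 1 && diff(range(lon)) > 180)
    stop("dataset spans more than 180 degrees of longitude; ",
         "antimeridian-crossing regions are not supported")
  invisible(TRUE)
}
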