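#' Build a quadtree spatial index
#'
#' Recursively partitions the bounding box of the input coordinates (in
#' lon/lat degrees, expanded by 1e-9 degrees so boundary points fall
#' inside) into four sub-cells whenever a cell holds more than
#' `node_capacity` points, down to `max_depth` levels.  Radius queries
#' prune with a latitude-aware bounding box and then apply the exact
#' haversine filter, so query results are independent of the tree
#' parameters.
#'
#' @param lat,lon Point coordinates, decimal degrees.
#' @param node_capacity Maximum points per leaf before it splits.
#' @param max_depth Maximum subdivision depth.
#' @return An object of class `quadtree`.
#' @seealso [quadtree_query()]
#' @export
quadtree <- function(lat, lon, node_capacity = 16L, max_depth = 24L) {
  stopifnot(length(lat) == length(lon),
            node_capacity >= 1L, max_depth >= 1L)
  if (length(lat)) {
    check_coords(lat, lon)
    check_lon_span(lon)
  }
  ptr <- cpp_quadtree_build(as.numeric(lat), as.numeric(lon),
                            as.integer(node_capacity), as.integer(max_depth))
  structure(list(ptr = ptr, n = length(lat)), class = "quadtree")
}

#' Radius query against a quadtree
#'
#' Returns the indices of all indexed points within `eps_km` (inclusive)
#' great-circle distance of the query point — exactly the set a linear
#' haversine scan would return.
#'
#' @param tree A [quadtree()].
#' @param lat,lon Query point, decimal degrees.
#' @param eps_km Query radius in km, `>= 0`.
#' @return Sorted integer vector of 1-based point indices; attribute
#'   `inspected` holds the number of candidate points examined during
#'   pruning (the operation count used by the scaling diagnostics).
#' @export
quadtree_query <- function(tree, lat, lon, eps_km) {
  stopifnot(inherits(tree, "quadtree"))
  check_coords(lat, lon)
  if (!is.finite(eps_km) || eps_km < 0) stop("eps_km must be >= 0")
  res <- cpp_quadtree_query(tree$ptr, lat, lon, eps_km)
  structure(res$ids + 1L, inspected = res$inspected)
}

#' @export
print.quadtree <- function(x, ...) {
  s <- cpp_quadtree_stats(x$ptr)
  cat("Quadtree index:", s$n_points, "points,",
      s$n_nodes, "nodes, depth", s$depth,
      sprintf("(capacity %d, max depth %d)\n", s$node_capacity, s$max_depth))
  invisible(x)
}

#' Quadtree summary statistics
#' @param tree A [quadtree()].
#' @return List with `n_points`, `depth`, `n_nodes`, `node_capacity`,
#'   `max_depth`.
#' @export
quadtree_stats <- function(tree) {
  stopifnot(inherits(tree, "quadtree"))
  cpp_quadtree_stats(tree$ptr)
}
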