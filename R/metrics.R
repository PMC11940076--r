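#' Calinski-Harabasz clustering validity index
#'
#' Ratio of between- to within-cluster dispersion, each normalized by
#' its degrees of freedom:
#' `CH = (B / (k - 1)) / (W / (n - k))` with
#' `B = sum_j n_j |m_j - m|^2` and `W = sum_j sum_{i in C_j} |x_i - m_j|^2`.
#' Positions are projected to a local planar km frame centered on the
#' centroid of the scored fixes before computing squared Euclidean
#' dispersions (squared-degree dispersions would mix unequal units
#' across latitude).  Noise fixes are excluded unless
#' `include_noise = TRUE` (then treated as one extra cluster).  Higher
#' is better.
#'
#' @param x A [track()] / `data.frame`, or a `stop_clustering` fit (then
#'   `cluster` is taken from the fit).
#' @param cluster Integer labels per fix, `-1` = noise.
#' @param include_noise Score noise fixes as their own cluster.
#' @return Object of class `ch_score`: list with `ch`, `k`, `n`,
#'   `between_ss`, `within_ss` (km^2).
#' @export
calinski_harabasz <- function(x, cluster = NULL, include_noise = FALSE) {
  if (inherits(x, "stop_clustering")) {
    cluster <- x$cluster
    x <- x$data
  }
  x <- as_track(x)
  stopifnot(length(cluster) == nrow(x))
  keep <- if (include_noise) rep(TRUE, nrow(x)) else cluster >= 0
  if (!any(keep))
    stop("Calinski-Harabasz index undefined: no clustered fixes")
  lab <- cluster[keep]
  n <- sum(keep)
  k <- length(unique(lab))
  if (k < 2)
    stop("Calinski-Harabasz index undefined for k < 2 clusters")
  if (n <= k)
    stop("Calinski-Harabasz index undefined for n <= k")
  p <- project_local(x$lat[keep], x$lon[keep],
                     mean(x$lat[keep]), mean(x$lon[keep]))
  gm <- c(mean(p$x), mean(p$y))
  between_ss <- 0
  within_ss <- 0
  for (g in unique(lab)) {
    m <- lab == g
    cm <- c(mean(p$x[m]), mean(p$y[m]))
    between_ss <- between_ss + sum(m) * sum((cm - gm)^2)
    within_ss <- within_ss + sum((p$x[m] - cm[1])^2 + (p$y[m] - cm[2])^2)
  }
  structure(list(ch = (between_ss / (k - 1)) / (within_ss / (n - k)),
                 k = k, n = n,
                 between_ss = between_ss, within_ss = within_ss),
            class = "ch_score")
}

#' @export
print.ch_score <- function(x, ...) {
  cat(sprintf("Calinski-Harabasz index: %.4g (k = %d, n = %d)\n",
              x$ch, x$k, x$n))
  invisible(x)
}

# labels from fit or vector
cluster_labels <- function(x) {
  if (inherits(x, "stop_clustering")) x$cluster else as.integer(x)
}

# one-to-one greedy matching of clusters by descending overlap;
# noise (-1) is a reserved class matched to noise.
# returns data.frame(a, b, overlap) of matched real-cluster pairs.
match_clusters <- function(a, b) {
  ok <- a >= 0 & b >= 0
  if (!any(ok))
    return(data.frame(a = integer(0), b = integer(0), overlap = integer(0)))
  tab <- table(a[ok], b[ok])
  pairs <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(pairs) <- c("a", "b", "overlap")
  pairs$a <- as.integer(as.character(pairs$a))
  pairs$b <- as.integer(as.character(pairs$b))
  pairs <- pairs[pairs$overlap > 0, , drop = FALSE]
  pairs <- pairs[order(-pairs$overlap, pairs$a, pairs$b), , drop = FALSE]
  used_a <- integer(0)
  used_b <- integer(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$a[i] %in% used_a || pairs$b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, pairs$a[i])
    used_b <- c(used_b, pairs$b[i])
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recognition difference rate between two labelings
#'
#' Clusters of `b` are matched one-to-one to clusters of `a` by maximal
#' point overlap (greedy on descending overlap, ties broken by cluster
#' id); noise is matched to noise.  The rate is the fraction of points
#' whose matched label differs — 0 for identical partitions (up to
#' cluster renumbering), 1 when no point agrees.
#'
#' @param a,b `stop_clustering` fits or integer label vectors (`-1` =
#'   noise) over the same point set.
#' @return Numeric scalar in \[0, 1\].
#' @export
recognition_difference_rate <- function(a, b) {
  la <- cluster_labels(a)
  lb <- cluster_labels(b)
  if (length(la) != length(lb))
    stop("labelings must cover the same point set")
  n <- length(la)
  if (n == 0L) return(0)
  m <- match_clusters(la, lb)
  mapped <- m$b[match(la, m$a)]  # NA for unmatched/noise
  agree <- (la == -1L & lb == -1L) | (!is.na(mapped) & mapped == lb)
  1 - sum(agree) / n
}

#' Cluster-to-cluster confusion report
#'
#' Full contingency table between two labelings (noise as a reserved
#' row/column), the greedy overlap matching, and per-matched-pair
#' Jaccard indices.
#'
#' @inheritParams recognition_difference_rate
#' @return Object of class `confusion_report`: list with `table`
#'   (contingency matrix, dimnames are cluster ids with `"noise"`),
#'   `matches` (`data.frame` with `a`, `b`, `overlap`, `jaccard`), and
#'   `difference_rate`.
#' @export
confusion_report <- function(a, b) {
  la <- cluster_labels(a)
  lb <- cluster_labels(b)
  if (length(la) != length(lb))
    stop("labelings must cover the same point set")
  lev_a <- sort(unique(la))
  lev_b <- sort(unique(lb))
  tab <- table(factor(la, levels = lev_a), factor(lb, levels = lev_b))
  dimnames(tab) <- list(a = ifelse(lev_a < 0, "noise", lev_a),
                        b = ifelse(lev_b < 0, "noise", lev_b))
  m <- match_clusters(la, lb)
  if (nrow(m)) {
    m$jaccard <- vapply(seq_len(nrow(m)), function(i) {
      na <- sum(la == m$a[i])
      nb <- sum(lb == m$b[i])
      m$overlap[i] / (na + nb - m$overlap[i])
    }, numeric(1))
  } else {
    m$jaccard <- numeric(0)
  }
  structure(list(table = tab, matches = m,
                 difference_rate = recognition_difference_rate(la, lb)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("Cluster confusion report\n")
  print(x$table)
  if (nrow(x$matches)) {
    cat("\nMatched pairs (greedy by overlap):\n")
    print.data.frame(x$matches, row.names = FALSE, digits = 3)
  }
  cat(sprintf("\nRecognition difference rate: %.4g\n", x$difference_rate))
  invisible(x)
}
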