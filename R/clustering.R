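#' DBSCAN clustering of localization point patterns
#'
#' Density-based clustering with the classical core / directly-reachable /
#' noise semantics. A localization whose eps-neighbourhood (including itself)
#' contains at least `min_pts` localizations is a core point; a non-core
#' localization within `eps` of a core point is directly reachable; remaining
#' localizations are noise. A cluster is a maximal group of connected core
#' points together with their directly reachable points. Expansion proceeds
#' in input-index order, so a border point reachable from two clusters is
#' assigned to the cluster discovered first -- the classical DBSCAN ambiguity,
#' fixed here for reproducibility. The partition of core points is invariant
#' to input ordering.
#'
#' Defaults follow a Monte-Carlo calibration for RNAP localization data:
#' eps = 20 nm, min_pts = 4. Input should hold one point per trajectory (the
#' first localization of each track) for live-cell data.
#'
#' @param data Tibble with point coordinates.
#' @param eps Neighbourhood radius (um).
#' @param min_pts Minimum neighbourhood count, self inclusive.
#' @param x,y Coordinate column names.
#' @return The input tibble with `cluster` (integer id, NA for noise) and
#'   `role` (`"core"`, `"directly_reachable"`, `"noise"`) columns.
#' @examples
#' pts <- tibble::tibble(x = c(0, 0.005, 0.01, 0.002, 0.007, 1),
#'                       y = c(0, 0, 0, 0.005, 0.003, 1))
#' cluster_rnap(pts)
#' @export
cluster_rnap <- function(data, eps = 0.020, min_pts = 4, x = "x", y = "y") {
  if (eps <= 0) abort("eps must be positive")
  if (min_pts < 1) abort("min_pts must be >= 1")
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n < 1) abort("at least one point is required")
  xv <- data[[x]]
  yv <- data[[y]]
  if (!all(is.finite(xv) & is.finite(yv))) abort("coordinates must be finite")
  dmat <- as.matrix(stats::dist(cbind(xv, yv)))
  nb <- apply(dmat <= eps, 1, which, simplify = FALSE)
  core <- lengths(nb) >= min_pts
  labels <- rep(NA_integer_, n)
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    cluster_id <- cluster_id + 1L
    labels[i] <- cluster_id
    queue <- i
    while (base::length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      for (k in nb[[j]]) {
        if (is.na(labels[k])) {
          labels[k] <- cluster_id
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  data$cluster <- labels
  data$role <- dplyr::case_when(
    core ~ "core",
    !is.na(labels) ~ "directly_reachable",
    TRUE ~ "noise"
  )
  data
}

#' Per-cluster molecule counts
#'
#' @param clustered Output of [cluster_rnap()].
#' @return Tibble with `cluster` and `size`, noise excluded.
#' @export
cluster_sizes <- function(clustered) {
  clustered %>%
    dplyr::filter(!is.na(.data$cluster)) %>%
    dplyr::count(.data$cluster, name = "size")
}

#' Fraction of clustered molecules in large clusters
#'
#' For each threshold `t`, the fraction of clustered molecules (noise
#' excluded from the denominator) that sit in clusters of size strictly
#' greater than `t`. Fractions are monotone non-increasing in `t`.
#'
#' @param clustered Output of [cluster_rnap()] (or a tibble with a `size`
#'   column as from [cluster_sizes()]).
#' @param thresholds Integer size thresholds.
#' @return Tibble with `threshold` and `fraction`.
#' @examples
#' sizes <- tibble::tibble(size = c(40, 80))
#' cluster_size_fractions(sizes, thresholds = c(35, 70, 100))
#' @export
cluster_size_fractions <- function(clustered, thresholds = c(35, 70, 100)) {
  sizes <- if ("size" %in% names(clustered)) {
    clustered$size
  } else {
    cluster_sizes(clustered)$size
  }
  total <- sum(sizes)
  if (total == 0) abort("no clustered molecules: fractions are undefined")
  tibble::tibble(
    threshold = thresholds,
    fraction = purrr::map_dbl(thresholds, ~ sum(sizes[sizes > .x]) / total)
  )
}
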