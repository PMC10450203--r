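# Uniform 2D points in the (possibly scaled) spherocylinder outline, by
# rejection in the bounding rectangle. Used by the co-localization null,
# which works with the nucleoid *area* rather than a projected volume.
sample_uniform_area <- function(cell, n, seed = NULL) {
  with_seed(seed, {
    xs <- ys <- numeric(0)
    while (base::length(xs) < n) {
      m <- max(2L * (n - base::length(xs)), 256L)
      x <- runif(m, -cell$length / 2, cell$length / 2)
      y <- runif(m, -cell$width / 2, cell$width / 2)
      k <- in_cell_2d(x, y, cell, tol = 0)
      xs <- c(xs, x[k])
      ys <- c(ys, y[k])
    }
    tibble::tibble(x = xs[1:n], y = ys[1:n])
  })
}

new_pair_correlation <- function(r, g, n_pairs, bin_width, n_points,
                                 n_null_draws) {
  out <- tibble::tibble(r = r, g = g, n_pairs = n_pairs)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_points") <- n_points
  attr(out, "n_null_draws") <- n_null_draws
  class(out) <- c("pair_correlation", class(out))
  out
}

#' Pair-correlation function of one cell's localizations
#'
#' g(r) is the histogram of all pairwise 2D distances, normalized bin-wise by
#' the mean histogram of uniform draws of the same number of points in the 3D
#' volume of revolution of the cell boundary, projected to 2D. Molecules
#' spread evenly through the reference volume give a flat g(r) = 1; clustering
#' gives g(r) > 1 at short distances and g(r) < 1 at long ones. Bins where the
#' null histogram is empty are returned as NA.
#'
#' @param points Tibble with `x`, `y` (um) inside the cell; at least 2 rows.
#' @param cell A [cell_geometry()].
#' @param bin_width Histogram bin width (um).
#' @param r_max Largest distance binned (um); truncated with a warning if it
#'   exceeds the cell length.
#' @param n_null_draws Uniform reference draws averaged for the null.
#' @param null_region `"cell"` (default; the rotated cell boundary) or
#'   `"nucleoid"` for populations confined to the nucleoid.
#' @param seed Optional integer seed for the null draws.
#' @return A `pair_correlation` tibble with columns `r` (bin centres), `g`,
#'   `n_pairs`.
#' @export
pair_correlation_cell <- function(points, cell, bin_width = 0.01, r_max = 1.0,
                                  n_null_draws = 20,
                                  null_region = c("cell", "nucleoid"),
                                  seed = NULL) {
  stopifnot(inherits(cell, "cell_geometry"))
  null_region <- match.arg(null_region)
  n <- nrow(points)
  if (n < 2) abort("at least 2 points are required for pair correlation")
  if (r_max > cell$length) {
    warn("r_max exceeds the cell length; truncating")
    r_max <- cell$length
  }
  n_bins <- as.integer(round(r_max / bin_width))
  obs <- pair_dist_hist(points$x, points$y, bin_width, n_bins)
  null_acc <- with_seed(seed, {
    acc <- numeric(n_bins)
    for (d in seq_len(n_null_draws)) {
      u <- sample_uniform(cell, n, region = null_region, project = TRUE)
      acc <- acc + pair_dist_hist(u$x, u$y, bin_width, n_bins)
    }
    acc
  })
  null_mean <- null_acc / n_null_draws
  g <- if_else(null_mean > 0, obs / null_mean, NA_real_)
  r <- (seq_len(n_bins) - 0.5) * bin_width
  new_pair_correlation(r, g, obs, bin_width, n, n_null_draws)
}

#' Average pair-correlation functions across cells
#'
#' Unweighted per-bin mean of per-cell g(r); bins undefined (NA) in a cell
#' are excluded from that bin's mean.
#'
#' @param cells List of [pair_correlation_cell()] results with identical
#'   binning.
#' @return A `pair_correlation` tibble.
#' @export
mean_pair_correlation <- function(cells) {
  if (base::length(cells) == 0) abort("no pair-correlation results supplied")
  r0 <- cells[[1]]$r
  for (pc in cells) {
    if (!isTRUE(all.equal(pc$r, r0))) {
      abort("pair-correlation binning differs between cells")
    }
  }
  gmat <- vapply(cells, function(pc) pc$g, numeric(base::length(r0)))
  pmat <- vapply(cells, function(pc) pc$n_pairs, numeric(base::length(r0)))
  g <- rowMeans(gmat, na.rm = TRUE)
  g[rowSums(!is.na(gmat)) == 0] <- NA_real_
  new_pair_correlation(
    r0, g, rowSums(pmat),
    attr(cells[[1]], "bin_width"), attr(cells[[1]], "n_points"),
    attr(cells[[1]], "n_null_draws")
  )
}

#' @rdname pair_correlation_cell
#' @param object A `pair_correlation`.
#' @param ... Unused.
#' @export
autoplot.pair_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$r, .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(r ~ (mu * m)), y = "g(r)") +
    ggplot2::theme_minimal()
}

#' Place foci on the long axis at folded normalized positions
#'
#' Helper for reference geometries: maps folded normalized positions (0 =
#' pole, 0.5 = mid-cell) of either the cell or the shrunk nucleoid region to
#' physical axial coordinates. `side` picks the cell half (-1 or +1).
#'
#' @param cell A [cell_geometry()].
#' @param l_folded Folded normalized positions.
#' @param side Vector of -1/+1, one per focus.
#' @param region `"nucleoid"` (positions normalized to the shrunk-nucleoid
#'   length, the region rrn foci occupy) or `"cell"`.
#' @return Tibble of foci with `x`, `y`.
#' @export
foci_on_axis <- function(cell, l_folded, side,
                         region = c("nucleoid", "cell")) {
  region <- match.arg(region)
  stopifnot(base::length(l_folded) == base::length(side))
  L <- if (region == "nucleoid") cell$nucleoid_shrink[1] * cell$length else cell$length
  tibble::tibble(x = side * (0.5 - l_folded) * L, y = 0)
}

#' Co-localization fraction with rrn foci
#'
#' Fraction of query items (localizations or cluster centroids) whose nearest
#' focus lies within `radius`. With `null = TRUE` the query set is replaced by
#' uniform draws in the nucleoid area -- the cell outline with length and
#' width scaled by the nucleoid shrink factors -- and the mean fraction over
#' `n_null_draws` draws is returned, giving the random-co-localization
#' baseline.
#'
#' @param points Tibble with `x`, `y` (um); ignored when `null = TRUE` except
#'   for its size (unless `n_null_points` is given).
#' @param foci Tibble with focus centroids `x`, `y`; at least one row.
#' @param cell A [cell_geometry()].
#' @param radius Co-localization radius (um), default 200 nm.
#' @param null Compute the uniform-nucleoid baseline instead of the observed
#'   fraction?
#' @param n_null_points Points per null draw (default: `nrow(points)`).
#' @param n_null_draws Null draws averaged.
#' @param seed Optional integer seed for the null draws.
#' @return One-row tibble: `fraction`, `n_query`, `n_foci`, `null`.
#' @export
coloc_fraction <- function(points, foci, cell, radius = 0.200, null = FALSE,
                           n_null_points = NULL, n_null_draws = 10,
                           seed = NULL) {
  stopifnot(inherits(cell, "cell_geometry"))
  if (is.null(foci) || nrow(foci) == 0) {
    abort("at least one focus is required; the fraction is undefined")
  }
  if (radius <= 0) abort("radius must be positive")
  frac_of <- function(px, py) {
    dmin <- rep(Inf, base::length(px))
    for (i in seq_len(nrow(foci))) {
      dmin <- pmin(dmin, sqrt((px - foci$x[i])^2 + (py - foci$y[i])^2))
    }
    mean(dmin <= radius)
  }
  if (!null) {
    f <- frac_of(points$x, points$y)
    return(tibble::tibble(fraction = f, n_query = nrow(points),
                          n_foci = nrow(foci), null = FALSE))
  }
  n <- if (is.null(n_null_points)) nrow(points) else n_null_points
  shrunk <- cell_geometry(
    cell$nucleoid_shrink[1] * cell$length,
    cell$nucleoid_shrink[2] * cell$width,
    pole_gap = 0
  )
  fracs <- with_seed(seed, {
    vapply(seq_len(n_null_draws), function(d) {
      u <- sample_uniform_area(shrunk, n)
      frac_of(u$x, u$y)
    }, numeric(1))
  })
  tibble::tibble(fraction = mean(fracs), n_query = n,
                 n_foci = nrow(foci), null = TRUE)
}

#' Cross pair-correlation of localizations with foci
#'
#' Histogram of all point-to-focus distances normalized by the mean histogram
#' from uniform draws in the nucleoid area (the shrunk cell outline), the
#' same reference used by [coloc_fraction()]. Running it on uniform input
#' reproduces the flat dashed reference curve of an uncorrelated pattern.
#'
#' @inheritParams coloc_fraction
#' @inheritParams pair_correlation_cell
#' @return A `pair_correlation` tibble of the cross-correlation.
#' @export
cross_pair_correlation <- function(points, foci, cell, bin_width = 0.01,
                                   r_max = 1.0, n_null_draws = 20,
                                   seed = NULL) {
  stopifnot(inherits(cell, "cell_geometry"))
  if (nrow(foci) == 0) abort("at least one focus is required")
  if (r_max > cell$length) {
    warn("r_max exceeds the cell length; truncating")
    r_max <- cell$length
  }
  n_bins <- as.integer(round(r_max / bin_width))
  obs <- cross_dist_hist(points$x, points$y, foci$x, foci$y, bin_width, n_bins)
  shrunk <- cell_geometry(
    cell$nucleoid_shrink[1] * cell$length,
    cell$nucleoid_shrink[2] * cell$width,
    pole_gap = 0
  )
  null_acc <- with_seed(seed, {
    acc <- numeric(n_bins)
    for (d in seq_len(n_null_draws)) {
      u <- sample_uniform_area(shrunk, nrow(points))
      acc <- acc + cross_dist_hist(u$x, u$y, foci$x, foci$y, bin_width, n_bins)
    }
    acc
  })
  null_mean <- null_acc / n_null_draws
  g <- if_else(null_mean > 0, obs / null_mean, NA_real_)
  r <- (seq_len(n_bins) - 0.5) * bin_width
  new_pair_correlation(r, g, obs, bin_width, nrow(points), n_null_draws)
}
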