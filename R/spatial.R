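#' Build a normalized-cell heatmap
#'
#' Pools localizations from all cells whose length falls inside
#' `length_window`, maps each to normalized cell coordinates (l, w) using its
#' cell's geometry, and bins them on a fixed 2D grid over the unit square.
#' When a `mobility` column is present, `mobility_class` selects the
#' immobile or mobile subset. For track data pass one spatial sample per
#' track (see [track_positions()]) so long tracks are not over-weighted.
#'
#' @param locs Localization tibble with `cell_id`, `x`, `y` (um, cell frame)
#'   and optionally `mobility`.
#' @param cells Tibble with `cell_id`, `length`, `width` (um).
#' @param length_window `c(min, max)` cell length selection (um); NULL keeps
#'   all cells.
#' @param mobility_class `"all"`, `"immobile"` or `"mobile"`.
#' @param bins `c(n_long, n_short)` grid dimensions.
#' @param pole_gap Pole gap passed to each cell's geometry (um).
#' @return An object of class `rnap_heatmap`: counts matrix (`bins[1]` rows =
#'   long axis), bin edges, number of contributing cells and points.
#' @export
build_heatmap <- function(locs, cells, length_window = c(3.2, 4.0),
                          mobility_class = c("all", "immobile", "mobile"),
                          bins = c(50, 25), pole_gap = 0.150) {
  mobility_class <- match.arg(mobility_class)
  cells <- tibble::as_tibble(cells)
  if (!is.null(length_window)) {
    cells <- dplyr::filter(cells, .data$length >= length_window[1],
                           .data$length <= length_window[2])
  }
  sel <- dplyr::filter(tibble::as_tibble(locs),
                       .data$cell_id %in% cells$cell_id)
  if (mobility_class != "all") {
    if (!"mobility" %in% names(sel)) {
      abort("mobility_class filtering requires a 'mobility' column")
    }
    sel <- dplyr::filter(sel, .data$mobility == mobility_class)
  }
  if (nrow(sel) == 0) {
    warn("no localizations fall in the selected cells; empty heatmap")
  }
  norm <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    ci <- cells[i, ]
    pts <- dplyr::filter(sel, .data$cell_id == ci$cell_id)
    if (nrow(pts) == 0) return(NULL)
    geom <- cell_geometry(ci$length, ci$width, pole_gap = pole_gap)
    normalize_position(pts, geom)
  })
  edges_l <- seq(0, 1, length.out = bins[1] + 1)
  edges_w <- seq(0, 1, length.out = bins[2] + 1)
  counts <- matrix(0, bins[1], bins[2])
  if (nrow(norm) > 0) {
    il <- pmin(pmax(findInterval(norm$l, edges_l, rightmost.closed = TRUE),
                    1), bins[1])
    iw <- pmin(pmax(findInterval(norm$w, edges_w, rightmost.closed = TRUE),
                    1), bins[2])
    counts <- matrix(tabulate((iw - 1L) * bins[1] + il, bins[1] * bins[2]),
                     bins[1], bins[2])
  }
  structure(
    list(
      counts = counts, bins_l = edges_l, bins_w = edges_w,
      n_cells = nrow(cells), n_points = nrow(norm),
      length_window = length_window, mobility_class = mobility_class
    ),
    class = "rnap_heatmap"
  )
}

#' @export
print.rnap_heatmap <- function(x, ...) {
  cat(sprintf(
    "<rnap_heatmap> %d x %d bins, %d points from %d cells (%s)\n",
    nrow(x$counts), ncol(x$counts), x$n_points, x$n_cells, x$mobility_class
  ))
  invisible(x)
}

#' Immobile-minus-mobile difference map
#'
#' Both heatmaps are first normalized to unit total mass (so unequal track
#' counts do not dominate the sign), then subtracted elementwise; the result
#' sums to zero.
#'
#' @param h_immobile,h_mobile [build_heatmap()] results on identical grids.
#' @return An object of class `rnap_difference_map` holding the signed grid.
#' @export
difference_map <- function(h_immobile, h_mobile) {
  stopifnot(inherits(h_immobile, "rnap_heatmap"),
            inherits(h_mobile, "rnap_heatmap"))
  if (!identical(dim(h_immobile$counts), dim(h_mobile$counts)) ||
      !isTRUE(all.equal(h_immobile$bins_l, h_mobile$bins_l)) ||
      !isTRUE(all.equal(h_immobile$bins_w, h_mobile$bins_w))) {
    abort("difference_map requires identical binning")
  }
  d <- h_immobile$counts / sum(h_immobile$counts) -
    h_mobile$counts / sum(h_mobile$counts)
  structure(
    list(delta = d, bins_l = h_immobile$bins_l, bins_w = h_immobile$bins_w),
    class = "rnap_difference_map"
  )
}

#' Axial projection of a heatmap
#'
#' Marginal counts along the long or short axis. `folded = TRUE` (long axis
#' only) pools the two cell halves onto the folded coordinate
#' `l_folded = min(l, 1 - l)` in \[0, 0.5\].
#'
#' @param heatmap A [build_heatmap()] result.
#' @param axis `"long"` or `"short"`.
#' @param folded Fold the long-axis profile about mid-cell?
#' @return Tibble with bin `center`, `count` and normalized `density`.
#' @export
axial_profile <- function(heatmap, axis = c("long", "short"), folded = FALSE) {
  stopifnot(inherits(heatmap, "rnap_heatmap"))
  axis <- match.arg(axis)
  if (axis == "long") {
    counts <- rowSums(heatmap$counts)
    centers <- (head(heatmap$bins_l, -1) + tail(heatmap$bins_l, -1)) / 2
    if (folded) {
      fc <- pmin(centers, 1 - centers)
      counts <- tapply(counts, round(fc, 10), sum)
      centers <- as.numeric(names(counts))
      counts <- as.numeric(counts)
    }
  } else {
    if (folded) abort("folding applies to the long axis only")
    counts <- colSums(heatmap$counts)
    centers <- (head(heatmap$bins_w, -1) + tail(heatmap$bins_w, -1)) / 2
  }
  tibble::tibble(center = centers, count = counts,
                 density = counts / sum(counts))
}

#' Fraction of localizations in the exterior region of the cell
#'
#' The exterior fraction is the share of localizations whose folded long-axis
#' coordinate `l_folded = min(l, 1 - l)` lies within `cutoff` of the nearest
#' pole. Under a uniform axial distribution the expected value at the default
#' cutoff 0.25 is exactly 0.5; values above that indicate pole-proximal
#' enrichment, values below indicate pole depletion. The statistic is
#' invariant to rescaling the cell length.
#'
#' @param x Either a data frame with an `l_folded` (or `l`) column, or a
#'   [build_heatmap()] result.
#' @param cutoff Folded-coordinate cutoff, in (0, 0.5).
#' @return A single fraction.
#' @examples
#' exterior_fraction(data.frame(l_folded = c(0.1, 0.2, 0.4)))
#' @export
exterior_fraction <- function(x, cutoff = 0.25) {
  if (cutoff <= 0 || cutoff >= 0.5) abort("cutoff must lie in (0, 0.5)")
  if (inherits(x, "rnap_heatmap")) {
    # the exterior region in unfolded coordinates is [0, cutoff] and
    # [1 - cutoff, 1]; straddling bins contribute their overlap fraction
    counts <- rowSums(x$counts)
    lo <- head(x$bins_l, -1)
    hi <- tail(x$bins_l, -1)
    overlap <- pmax(0, pmin(hi, cutoff) - lo) +
      pmax(0, hi - pmax(lo, 1 - cutoff))
    w <- overlap / (hi - lo)
    return(sum(w * counts) / sum(counts))
  }
  lf <- if ("l_folded" %in% names(x)) x$l_folded else pmin(x$l, 1 - x$l)
  mean(lf <= cutoff)
}

#' @rdname build_heatmap
#' @param object An `rnap_heatmap`.
#' @param ... Unused.
#' @export
autoplot.rnap_heatmap <- function(object, ...) {
  df <- heatmap_grid_df(object$counts, object$bins_l, object$bins_w)
  ggplot2::ggplot(df, ggplot2::aes(.data$l, .data$w, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "count") +
    ggplot2::coord_equal(ratio = 0.5) +
    ggplot2::labs(x = "normalized long axis", y = "normalized short axis") +
    ggplot2::theme_minimal()
}

#' @rdname difference_map
#' @param object An `rnap_difference_map`.
#' @param ... Unused.
#' @export
autoplot.rnap_difference_map <- function(object, ...) {
  df <- heatmap_grid_df(object$delta, object$bins_l, object$bins_w)
  ggplot2::ggplot(df, ggplot2::aes(.data$l, .data$w, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "immobile - mobile") +
    ggplot2::coord_equal(ratio = 0.5) +
    ggplot2::labs(x = "normalized long axis", y = "normalized short axis") +
    ggplot2::theme_minimal()
}

heatmap_grid_df <- function(m, bins_l, bins_w) {
  cl <- (head(bins_l, -1) + tail(bins_l, -1)) / 2
  cw <- (head(bins_w, -1) + tail(bins_w, -1)) / 2
  tibble::tibble(
    l = rep(cl, times = base::length(cw)),
    w = rep(cw, each = base::length(cl)),
    value = as.vector(m)
  )
}
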