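#' Spherocylindrical cell geometry
#'
#' Defines the parametric geometry used throughout the package: the cell
#' boundary is a spherocylinder (a cylinder of length `length - width` capped
#' by hemispheres of radius `width/2`), and the nucleoid is a prolate spheroid
#' inset from the poles. Physical coordinates are in micrometres with the
#' origin at the cell centre and the x axis along the long axis.
#'
#' The nucleoid long semi-axis is `length/2 - pole_gap`; its short semi-axis is
#' `nucleoid_shrink[2] * width/2`, consistent with the shrink factor used to
#' estimate the nucleoid area in co-localization analysis.
#'
#' @param length Pole-to-pole cell length (um).
#' @param width Cell width/diameter (um); must be smaller than `length`.
#' @param pole_gap Separation between the nucleoid tip and the cell pole (um).
#' @param nucleoid_shrink Length-wise and width-wise scale factors of the
#'   nucleoid relative to the cell, used for the nucleoid-area estimate and the
#'   nucleoid short semi-axis.
#' @return An object of class `cell_geometry`.
#' @examples
#' cell <- cell_geometry(3, 1)
#' cell$nucleoid_a
#' @export
cell_geometry <- function(length, width, pole_gap = 0.150,
                          nucleoid_shrink = c(0.75, 0.75)) {
  stopifnot(is.numeric(length), is.numeric(width), is.numeric(pole_gap))
  if (!(length > width && width > 0)) {
    abort("cell geometry requires length > width > 0")
  }
  if (pole_gap < 0 || 2 * pole_gap >= length) {
    abort("pole_gap must satisfy 0 <= 2*pole_gap < length")
  }
  if (!is.numeric(nucleoid_shrink) || base::length(nucleoid_shrink) != 2) {
    abort("nucleoid_shrink must be a length-2 numeric (length, width scale)")
  }
  structure(
    list(
      length = length, width = width, pole_gap = pole_gap,
      nucleoid_shrink = nucleoid_shrink,
      nucleoid_a = length / 2 - pole_gap,
      nucleoid_b = nucleoid_shrink[2] * width / 2
    ),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> L = %.3f um, W = %.3f um, pole gap = %.3f um\n",
    x$length, x$width, x$pole_gap
  ))
  cat(sprintf(
    "  nucleoid spheroid: a = %.3f um, b = %.3f um\n",
    x$nucleoid_a, x$nucleoid_b
  ))
  invisible(x)
}

#' Read or write a cell geometry as YAML
#'
#' Serializes the geometry as `{length_um, width_um, pole_gap_um,
#' nucleoid_shrink}`.
#'
#' @param cell A [cell_geometry()].
#' @param path File path.
#' @return `read_cell_geometry()` returns a `cell_geometry`;
#'   `write_cell_geometry()` returns `path` invisibly.
#' @export
write_cell_geometry <- function(cell, path) {
  stopifnot(inherits(cell, "cell_geometry"))
  yaml::write_yaml(
    list(
      length_um = cell$length, width_um = cell$width,
      pole_gap_um = cell$pole_gap, nucleoid_shrink = cell$nucleoid_shrink
    ),
    path
  )
  invisible(path)
}

#' @rdname write_cell_geometry
#' @export
read_cell_geometry <- function(path) {
  y <- yaml::read_yaml(path)
  cell_geometry(
    length = y$length_um, width = y$width_um,
    pole_gap = y$pole_gap_um,
    nucleoid_shrink = as.numeric(unlist(y$nucleoid_shrink))
  )
}

# TRUE for 2D points inside the spherocylinder outline (projected boundary),
# with a tolerance in um on the boundary test.
in_cell_2d <- function(x, y, cell, tol = 1e-3) {
  hw <- cell$width / 2 + tol
  hc <- cell$length / 2 - cell$width / 2
  abs(y) <= hw &
    (abs(x) <= hc | (pmax(abs(x) - hc, 0))^2 + y^2 <= hw^2)
}

# TRUE for 3D points inside the spherocylinder volume.
in_cell_3d <- function(x, y, z, cell, tol = 0) {
  hw <- cell$width / 2 + tol
  hc <- cell$length / 2 - cell$width / 2
  r2 <- y^2 + z^2
  (abs(x) <= hc & r2 <= hw^2) |
    (abs(x) > hc & (abs(x) - hc)^2 + r2 <= hw^2)
}

# TRUE for 3D points inside the nucleoid spheroid.
in_nucleoid_3d <- function(x, y, z, cell, tol = 0) {
  a <- cell$nucleoid_a + tol
  b <- cell$nucleoid_b + tol
  (x / a)^2 + (y / b)^2 + (z / b)^2 <= 1
}

#' Map physical positions to normalized cell coordinates
#'
#' Positions are normalized by the cell length and width: `l = (x + L/2)/L`
#' runs from 0 at one pole to 1 at the other, `w = (y + W/2)/W` runs across the
#' short axis with 0.5 on the long axis, and `l_folded = min(l, 1 - l)` pools
#' the two cell halves so 0 is the nearest pole and 0.5 is mid-cell. Under this
#' folding a uniform distribution along the long axis has mean `l_folded` 0.25
#' and puts exactly half its mass in the exterior quarter (`l_folded <= 0.25`).
#'
#' @param data A data frame with physical coordinates (um), origin at the cell
#'   centre, long axis along x.
#' @param cell A [cell_geometry()].
#' @param x,y Column names of the coordinates.
#' @param tol Boundary tolerance in um (default 1 nm).
#' @return The input as a tibble with columns `l`, `w`, `l_folded` appended.
#' @examples
#' cell <- cell_geometry(3, 1)
#' normalize_position(data.frame(x = c(0, -1.5), y = 0), cell)
#' @export
normalize_position <- function(data, cell, x = "x", y = "y", tol = 1e-3) {
  stopifnot(inherits(cell, "cell_geometry"))
  xv <- data[[x]]
  yv <- data[[y]]
  ok <- in_cell_2d(xv, yv, cell, tol = tol)
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf(
      "point (%.4f, %.4f) lies outside the cell boundary", xv[i], yv[i]
    ))
  }
  l <- (xv + cell$length / 2) / cell$length
  w <- (yv + cell$width / 2) / cell$width
  dplyr::mutate(tibble::as_tibble(data),
    l = l, w = w, l_folded = pmin(l, 1 - l)
  )
}

#' @rdname normalize_position
#' @description `denormalize_position()` inverts the map, returning physical
#'   `x`, `y` from `l`, `w`.
#' @export
denormalize_position <- function(data, cell) {
  stopifnot(inherits(cell, "cell_geometry"))
  dplyr::mutate(tibble::as_tibble(data),
    x = .data$l * cell$length - cell$length / 2,
    y = .data$w * cell$width - cell$width / 2
  )
}

#' Uniform spatial sampling in the cell or nucleoid
#'
#' Draws points uniformly in the 3D spherocylindrical cell volume or in the
#' prolate-spheroid nucleoid by rejection sampling inside the region's bounding
#' box. With `project = TRUE` the transverse z dimension is dropped, giving the
#' 2D projection used by the pair-correlation null; the long-axis coordinate is
#' untouched by projection.
#'
#' @param cell A [cell_geometry()].
#' @param n Number of points (>= 1).
#' @param region `"cell"` or `"nucleoid"`.
#' @param project Drop the z coordinate?
#' @param seed Optional integer seed; the same seed reproduces the same draw.
#' @return A tibble with columns `x`, `y` (and `z` unless projected). The
#'   empirical rejection acceptance rate is attached as attribute
#'   `"acceptance_rate"`.
#' @examples
#' cell <- cell_geometry(3, 1)
#' pts <- sample_uniform(cell, 100, region = "nucleoid", seed = 1)
#' @export
sample_uniform <- function(cell, n, region = c("cell", "nucleoid"),
                           project = FALSE, seed = NULL) {
  stopifnot(inherits(cell, "cell_geometry"))
  region <- match.arg(region)
  if (!is.numeric(n) || n < 1) abort("n must be a positive count")
  n <- as.integer(n)
  if (region == "cell") {
    half <- c(cell$length / 2, cell$width / 2, cell$width / 2)
    keep <- function(x, y, z) in_cell_3d(x, y, z, cell)
  } else {
    half <- c(cell$nucleoid_a, cell$nucleoid_b, cell$nucleoid_b)
    keep <- function(x, y, z) in_nucleoid_3d(x, y, z, cell)
  }
  with_seed(seed, {
    got <- 0L
    proposed <- 0L
    xs <- ys <- zs <- numeric(0)
    while (got < n) {
      m <- max(2L * (n - got), 256L)
      x <- runif(m, -half[1], half[1])
      y <- runif(m, -half[2], half[2])
      z <- runif(m, -half[3], half[3])
      k <- keep(x, y, z)
      proposed <- proposed + m
      xs <- c(xs, x[k])
      ys <- c(ys, y[k])
      zs <- c(zs, z[k])
      got <- base::length(xs)
    }
    out <- tibble::tibble(x = xs[1:n], y = ys[1:n], z = zs[1:n])
    if (project) out <- dplyr::select(out, "x", "y")
    attr(out, "acceptance_rate") <- got / proposed
    out
  })
}
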