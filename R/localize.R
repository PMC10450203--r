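# Elliptical Gaussian + constant offset evaluated on a pixel-centre grid.
gauss2d_model <- function(par, xg, yg) {
  x0 <- par[1]; y0 <- par[2]
  A <- exp(par[3]); sx <- exp(par[4]); sy <- exp(par[5]); off <- par[6]
  A * exp(-outer(
    (yg - y0)^2 / (2 * sy^2),
    (xg - x0)^2 / (2 * sx^2), "+"
  )) + off
}

fit_gauss2d <- function(win, xg, yg, pixel) {
  off0 <- min(win)
  w <- pmax(win - off0, 0)
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  x0 <- sum(colSums(w) * xg) / tot
  y0 <- sum(rowSums(w) * yg) / tot
  s0 <- max(sqrt(sum(colSums(w) * (xg - x0)^2) / tot), pixel / 2)
  par0 <- c(x0, y0, log(max(max(w), 1e-6)), log(s0), log(s0), off0)
  fit <- tryCatch(
    optim(par0, function(p) sum((gauss2d_model(p, xg, yg) - win)^2),
          method = "BFGS", control = list(maxit = 500)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$convergence != 0) return(NULL)
  p <- fit$par
  # reject fits that wandered outside the window
  if (p[1] < min(xg) || p[1] > max(xg) || p[2] < min(yg) || p[2] > max(yg)) {
    return(NULL)
  }
  list(x = p[1], y = p[2], intensity = exp(p[3]),
       sigma_x = exp(p[4]), sigma_y = exp(p[5]))
}

#' Detect and localize spots in a single frame
#'
#' Candidate spots are local maxima of a difference-of-Gaussians (bandpass)
#' image exceeding `mean + threshold_k * sd` of the filtered image. Each
#' candidate is refined by least-squares fitting of a free elliptical Gaussian
#' plus offset in a fixed window; fits that fail to converge are dropped and
#' candidates whose window clips the image border are skipped (counted in the
#' `"skipped"` attribute).
#'
#' @param image Numeric matrix (row index = y); counts.
#' @param pixel Pixel size (um).
#' @param bandpass `c(sigma_small, sigma_large)` of the difference-of-Gaussians
#'   filter, in pixels.
#' @param threshold_k Detection threshold in SD multiples of the filtered
#'   image.
#' @param window Fit window size in pixels (odd).
#' @param frame Frame index stored with each localization.
#' @return Tibble of localizations: `x`, `y` (um), `frame`, `intensity`,
#'   `sigma_x`, `sigma_y`.
#' @examples
#' stk <- render_frames(data.frame(x = 5, y = 5), noise = FALSE)
#' detect_and_fit(stk[, , 1])
#' @export
detect_and_fit <- function(image, pixel = 0.1, bandpass = c(1, 3),
                           threshold_k = 4, window = 7, frame = 1L) {
  if (base::length(image) == 0 || !all(is.finite(image))) {
    abort("image must be a non-empty finite-valued matrix")
  }
  if (bandpass[1] >= bandpass[2]) {
    abort("bandpass requires sigma_small < sigma_large")
  }
  dog <- EBImage::gblur(image, sigma = bandpass[1]) -
    EBImage::gblur(image, sigma = bandpass[2])
  thr <- mean(dog) + threshold_k * sd(dog)
  ny <- nrow(image); nx <- ncol(image)
  # strict local maxima over the 8-neighbourhood, computed by shifts
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- dog
  is_max <- dog > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(ny + 1 + di), (2 + dj):(nx + 1 + dj)]
    # strict against earlier neighbours in scan order so a tied plateau
    # yields exactly one candidate
    if (di < 0 || (di == 0 && dj < 0)) {
      is_max <- is_max & (dog > nb)
    } else {
      is_max <- is_max & (dog >= nb)
    }
  }
  cand <- which(is_max, arr.ind = TRUE)
  half <- (window - 1) %/% 2
  skipped_border <- 0L
  skipped_fit <- 0L
  out <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (i - half < 1 || i + half > ny || j - half < 1 || j + half > nx) {
      skipped_border <- skipped_border + 1L
      next
    }
    win <- image[(i - half):(i + half), (j - half):(j + half)]
    xg <- ((j - half):(j + half) - 0.5) * pixel
    yg <- ((i - half):(i + half) - 0.5) * pixel
    f <- fit_gauss2d(win, xg, yg, pixel)
    if (is.null(f)) {
      skipped_fit <- skipped_fit + 1L
      next
    }
    out[[base::length(out) + 1]] <- tibble::tibble(
      x = f$x, y = f$y, frame = frame, intensity = f$intensity,
      sigma_x = f$sigma_x, sigma_y = f$sigma_y
    )
  }
  res <- if (base::length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(x = numeric(0), y = numeric(0), frame = integer(0),
                   intensity = numeric(0), sigma_x = numeric(0),
                   sigma_y = numeric(0))
  }
  attr(res, "skipped") <- c(border = skipped_border, no_fit = skipped_fit)
  res
}

#' Detect diffraction-limited foci from an averaged stack
#'
#' Frames are averaged and [detect_and_fit()] is applied to the mean image;
#' one focus record is returned per detected spot.
#'
#' @param stack Array `[rows, cols, frames]` (or a single matrix).
#' @inheritParams detect_and_fit
#' @return Tibble of foci: `x`, `y` (um), `amplitude`.
#' @export
detect_foci <- function(stack, pixel = 0.1, bandpass = c(1, 3),
                        threshold_k = 4, window = 7) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  if (dim(stack)[3] < 1) abort("at least one frame is required")
  avg <- apply(stack, c(1, 2), mean)
  locs <- detect_and_fit(avg, pixel = pixel, bandpass = bandpass,
                         threshold_k = threshold_k, window = window)
  tibble::tibble(x = locs$x, y = locs$y, amplitude = locs$intensity)
}

#' Merge repeated localizations in consecutive frames
#'
#' In fixed-cell data a molecule localized in several flanking frames should
#' be counted once: any localization within `radius` of a localization kept in
#' the immediately preceding frame is merged into that record (dropped), so a
#' run across consecutive frames collapses to its first appearance.
#'
#' @param locs Localization tibble with `frame`, `x`, `y`.
#' @param radius Merge radius (um), default 100 nm.
#' @return Filtered tibble; the number of merged records is attached as
#'   attribute `"merged"`.
#' @export
merge_repeat_localizations <- function(locs, radius = 0.100) {
  locs <- dplyr::arrange(tibble::as_tibble(locs), .data$frame)
  keep <- rep(TRUE, nrow(locs))
  frames <- sort(unique(locs$frame))
  prev_idx <- integer(0)
  prev_frame <- -Inf
  for (f in frames) {
    idx <- which(locs$frame == f)
    if (f - prev_frame != 1) prev_idx <- integer(0)
    if (base::length(prev_idx) > 0) {
      for (i in idx) {
        d2 <- (locs$x[prev_idx] - locs$x[i])^2 + (locs$y[prev_idx] - locs$y[i])^2
        if (any(d2 <= radius^2)) keep[i] <- FALSE
      }
    }
    # records in this frame that continue a run still suppress the next frame
    prev_idx <- idx
    prev_frame <- f
  }
  out <- locs[keep, ]
  attr(out, "merged") <- sum(!keep)
  out
}
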