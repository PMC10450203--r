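#' Simulate two-species Brownian tracks
#'
#' Generates single-molecule trajectories for the mobility pipeline. Each
#' track is assigned a species by a Bernoulli draw with probability
#' `f_immobile`; displacements per 15 ms frame are 2D Gaussian steps with
#' variance `2 * D_true * dt` per axis, and independent Gaussian localization
#' error of sd `loc_error_sigma` is added to every localization. There is no
#' species switching within a track.
#'
#' The apparent diffusion coefficient of a species with true coefficient `D`
#' is `D + loc_error_sigma^2 / dt`; with the defaults an immobile (`D = 0`)
#' molecule therefore shows an apparent D* of about 0.082 um^2/s. To generate
#' tracks whose D* follows the shape-4 gamma law exactly at a stated apparent
#' value, set `loc_error_sigma = 0` and pass the apparent coefficient as the
#' true one.
#'
#' @param n_tracks Number of tracks (0 gives an empty tibble).
#' @param f_immobile Probability a track is immobile.
#' @param D_immobile True diffusion coefficient of the immobile species
#'   (um^2/s); 0 for chromosome-bound molecules.
#' @param D_mobile True diffusion coefficient of the mobile species (um^2/s).
#' @param loc_error_sigma Localization error sd (um).
#' @param dt Frame interval (s).
#' @param track_length Localizations per track: a single integer >= 5 or a
#'   function of `n` returning `n` integer lengths >= 5.
#' @param seed Optional integer seed.
#' @return Tibble with columns `track_id`, `frame`, `x`, `y`, `species`.
#' @examples
#' trk <- simulate_tracks(10, f_immobile = 1, D_mobile = 0.36, seed = 1)
#' @export
simulate_tracks <- function(n_tracks, f_immobile, D_immobile = 0,
                            D_mobile = 0.36, loc_error_sigma = 0.035,
                            dt = 0.015, track_length = 5L, seed = NULL) {
  if (n_tracks == 0) {
    return(tibble::tibble(
      track_id = integer(0), frame = integer(0),
      x = numeric(0), y = numeric(0), species = character(0)
    ))
  }
  if (D_mobile <= 0) abort("D_mobile must be positive")
  if (f_immobile < 0 || f_immobile > 1) abort("f_immobile must lie in [0, 1]")
  with_seed(seed, {
    lens <- if (is.function(track_length)) {
      as.integer(track_length(n_tracks))
    } else {
      rep(as.integer(track_length), n_tracks)
    }
    if (any(lens < 5L)) abort("track lengths must be >= 5 localizations")
    imm <- runif(n_tracks) < f_immobile
    D <- if_else(imm, D_immobile, D_mobile)
    if (base::length(unique(lens)) == 1L) {
      L <- lens[1]
      step_sd <- sqrt(2 * D * dt)
      cum <- function() {
        s <- matrix(rnorm(n_tracks * (L - 1), 0, rep(step_sd, L - 1)),
                    nrow = n_tracks)
        # lower-triangular accumulation: positions from steps
        cbind(0, s %*% upper.tri(diag(L - 1), diag = TRUE))
      }
      px <- cum() + matrix(rnorm(n_tracks * L, 0, loc_error_sigma), n_tracks)
      py <- cum() + matrix(rnorm(n_tracks * L, 0, loc_error_sigma), n_tracks)
      out <- tibble::tibble(
        track_id = rep(seq_len(n_tracks), each = L),
        frame = rep(seq_len(L), times = n_tracks),
        x = as.vector(t(px)), y = as.vector(t(py)),
        species = rep(if_else(imm, "immobile", "mobile"), each = L)
      )
    } else {
      total <- sum(lens)
      tid <- rep(seq_len(n_tracks), times = lens)
      first <- !duplicated(tid)
      sdv <- sqrt(2 * D[tid] * dt)
      dx <- rnorm(total, 0, sdv)
      dy <- rnorm(total, 0, sdv)
      dx[first] <- 0
      dy[first] <- 0
      out <- tibble::tibble(
        track_id = tid,
        frame = stats::ave(rep(1L, total), tid, FUN = seq_along),
        x = stats::ave(dx, tid, FUN = cumsum) + rnorm(total, 0, loc_error_sigma),
        y = stats::ave(dy, tid, FUN = cumsum) + rnorm(total, 0, loc_error_sigma),
        species = if_else(imm[tid], "immobile", "mobile")
      )
    }
    out
  })
}

#' Render localization frames as a synthetic image stack
#'
#' Each emitter is rendered as an integrated 2D Gaussian point-spread function
#' on a pixel grid, with Poisson shot noise on signal plus uniform background.
#' Pixel (i, j) covers x in `(j-1)*pixel .. j*pixel` and y in
#' `(i-1)*pixel .. i*pixel` (row index = y).
#'
#' @param locs Tibble with columns `x`, `y` (um) and optionally `frame`
#'   (default: all in frame 1).
#' @param fov_um Field of view `c(x, y)` extent in um.
#' @param pixel Pixel size (um).
#' @param psf_sigma PSF Gaussian sd (um).
#' @param photons Expected photons per emitter.
#' @param background Expected background counts per pixel.
#' @param noise Add Poisson noise?
#' @param seed Optional integer seed for the shot noise.
#' @return A numeric array `[rows, cols, frames]` with the ground-truth
#'   localization table attached as attribute `"truth"`.
#' @export
render_frames <- function(locs, fov_um = c(10, 10), pixel = 0.1,
                          psf_sigma = 0.13, photons = 1000, background = 0,
                          noise = TRUE, seed = NULL) {
  if (pixel <= 0) abort("pixel size must be positive")
  if (!"frame" %in% names(locs)) locs$frame <- 1L
  if (any(locs$x < 0 | locs$x > fov_um[1] | locs$y < 0 | locs$y > fov_um[2])) {
    abort("all emitter positions must lie within the field of view")
  }
  nx <- ceiling(fov_um[1] / pixel)
  ny <- ceiling(fov_um[2] / pixel)
  frames <- sort(unique(locs$frame))
  xe <- seq(0, nx) * pixel
  ye <- seq(0, ny) * pixel
  stack <- array(0, dim = c(ny, nx, base::length(frames)))
  for (k in seq_along(frames)) {
    sub <- locs[locs$frame == frames[k], ]
    img <- matrix(background, ny, nx)
    for (i in seq_len(nrow(sub))) {
      fx <- diff(stats::pnorm(xe, sub$x[i], psf_sigma))
      fy <- diff(stats::pnorm(ye, sub$y[i], psf_sigma))
      img <- img + photons * (fy %o% fx)
    }
    stack[, , k] <- img
  }
  if (noise) {
    stack <- with_seed(seed, array(rpois(base::length(stack), stack), dim = dim(stack)))
  }
  attr(stack, "truth") <- tibble::as_tibble(locs)
  attr(stack, "pixel") <- pixel
  stack
}

#' Write an image stack to TIFF
#'
#' @param stack Array as returned by [render_frames()].
#' @param path Output file.
#' @param scale Intensity divisor mapping counts into \[0, 1\] for TIFF storage.
#' @export
write_frames_tiff <- function(stack, path, scale = max(stack)) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF stacks")
  }
  imgs <- purrr::map(seq_len(dim(stack)[3]), function(k) stack[, , k] / scale)
  tiff::writeTIFF(imgs, path)
  invisible(path)
}
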