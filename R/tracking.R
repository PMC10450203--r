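#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour linking: localizations in each frame are linked to
#' the closest open track end within `search_radius`, closest pairs first;
#' each localization joins at most one track and unlinked localizations start
#' new tracks. A track absent from a single frame (fluorophore blinking) is
#' bridged: its end remains available for one further frame, so the
#' localizations on either side of the empty frame are connected. Two-frame
#' gaps terminate the track. Ties in distance are broken by localization
#' index, then by track id.
#'
#' @param locs Localization tibble with columns `frame`, `x`, `y` (um), sorted
#'   or not.
#' @param search_radius Maximum link distance (um). The default corresponds to
#'   about five diffusion standard deviations of a mobile molecule at
#'   0.36 um^2/s over one 15 ms frame.
#' @param max_gap Maximum number of missing frames bridged within a track.
#' @return The input tibble (sorted by frame) with a `track_id` column.
#' @examples
#' locs <- simulate_tracks(3, f_immobile = 0, D_mobile = 0.1, seed = 1)
#' linked <- link_tracks(locs[, c("frame", "x", "y")])
#' @export
link_tracks <- function(locs, search_radius = 0.48, max_gap = 1) {
  if (search_radius <= 0) abort("search_radius must be positive")
  locs <- dplyr::arrange(tibble::as_tibble(locs), .data$frame)
  n <- nrow(locs)
  track_id <- integer(n)
  if (n == 0) {
    locs$track_id <- track_id
    return(locs)
  }
  # open track ends: id, last frame, last position
  end_id <- integer(0)
  end_frame <- numeric(0)
  end_x <- numeric(0)
  end_y <- numeric(0)
  next_id <- 1L
  for (f in sort(unique(locs$frame))) {
    idx <- which(locs$frame == f)
    live <- which(f - end_frame >= 1 & f - end_frame <= max_gap + 1)
    assigned_loc <- rep(FALSE, base::length(idx))
    used_end <- rep(FALSE, base::length(live))
    if (base::length(live) > 0 && base::length(idx) > 0) {
      d <- outer(seq_along(idx), seq_along(live), function(a, b) {
        sqrt((locs$x[idx[a]] - end_x[live[b]])^2 +
               (locs$y[idx[a]] - end_y[live[b]])^2)
      })
      repeat {
        d_ok <- d
        d_ok[assigned_loc, ] <- Inf
        d_ok[, used_end] <- Inf
        m <- min(d_ok)
        if (!is.finite(m) || m > search_radius) break
        hit <- which(d_ok == m, arr.ind = TRUE)
        a <- hit[1, 1]
        b <- hit[1, 2]
        i <- idx[a]
        e <- live[b]
        track_id[i] <- end_id[e]
        end_frame[e] <- f
        end_x[e] <- locs$x[i]
        end_y[e] <- locs$y[i]
        assigned_loc[a] <- TRUE
        used_end[b] <- TRUE
      }
    }
    for (a in which(!assigned_loc)) {
      i <- idx[a]
      track_id[i] <- next_id
      end_id <- c(end_id, next_id)
      end_frame <- c(end_frame, f)
      end_x <- c(end_x, locs$x[i])
      end_y <- c(end_y, locs$y[i])
      next_id <- next_id + 1L
    }
    # drop ends that can no longer be linked (keeps the search small)
    stale <- f - end_frame > max_gap + 1
    if (any(stale)) {
      end_id <- end_id[!stale]
      end_frame <- end_frame[!stale]
      end_x <- end_x[!stale]
      end_y <- end_y[!stale]
    }
  }
  locs$track_id <- track_id
  locs
}

#' Apparent diffusion coefficient per track
#'
#' D* is the mean squared displacement over the first `n_steps` single-frame
#' displacement intervals of a track, divided by `4 * dt`:
#' `D* = sum(dx^2 + dy^2) / (4 * n_steps * dt)`. Only consecutive-frame steps
#' count: displacements across a bridged blink gap span two frame intervals
#' and are excluded. Tracks with fewer than `n_steps` usable steps are
#' excluded (returned with `D_star = NA` and counted in the `"excluded"`
#' attribute). Fixing `n_steps = 4` makes the sampling distribution of D* a
#' gamma with shape 4 and mean equal to the apparent diffusion coefficient.
#'
#' @param tracks Tibble with columns `track_id`, `frame`, `x`, `y`.
#' @param dt Frame interval (s).
#' @param n_steps Number of single-frame steps used (default 4).
#' @return Tibble with one row per track: `track_id`, `n_steps`, `D_star`
#'   (um^2/s; NA when too few usable steps).
#' @examples
#' trk <- simulate_tracks(5, f_immobile = 0, D_mobile = 0.36, seed = 1)
#' apparent_D(trk)
#' @export
apparent_D <- function(tracks, dt = 0.015, n_steps = 4L) {
  tracks <- dplyr::arrange(tibble::as_tibble(tracks), .data$track_id,
                           .data$frame)
  ns_cap <- as.integer(n_steps)
  # fast path: no blink gaps anywhere (typical for simulated tracks)
  nr <- nrow(tracks)
  if (nr > 1) {
    tid <- tracks$track_id
    same <- tid[-1] == tid[-nr]
    dfr <- diff(tracks$frame)
    if (all(dfr[same] == 1)) {
      runs <- rle(as.vector(tid))
      sq <- (diff(tracks$x)^2 + diff(tracks$y)^2)[same]
      step_rank <- sequence(runs$lengths - 1L)
      step_tid <- rep(seq_along(runs$values), runs$lengths - 1L)
      keep <- step_rank <= ns_cap
      sums <- rowsum(sq[keep], step_tid[keep])
      counts <- rowsum(rep(1L, sum(keep)), step_tid[keep])
      ns <- integer(base::length(runs$values))
      ns[as.integer(rownames(counts))] <- counts[, 1]
      dsum <- rep(NA_real_, base::length(runs$values))
      dsum[as.integer(rownames(sums))] <- sums[, 1]
      dstar <- if_else(ns >= ns_cap, dsum / (4 * ns_cap * dt), NA_real_)
      res <- tibble::tibble(track_id = runs$values, n_steps = ns,
                            D_star = dstar)
      attr(res, "excluded") <- sum(is.na(res$D_star))
      return(res)
    }
  }
  res <- tracks %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::summarise(
      n_steps = min(sum(diff(.data$frame) == 1), ns_cap),
      D_star = {
        use <- head(which(diff(.data$frame) == 1), ns_cap)
        if (base::length(use) < ns_cap) NA_real_ else {
          sum(diff(.data$x)[use]^2 + diff(.data$y)[use]^2) /
            (4 * ns_cap * dt)
        }
      },
      .groups = "drop"
    )
  attr(res, "excluded") <- sum(is.na(res$D_star))
  res
}

#' First localization of each track with its D*
#'
#' Clustering and heatmap analyses use one spatial sample per trajectory to
#' avoid over-weighting long tracks; this helper extracts the first
#' localization of each track and joins the track's apparent diffusion
#' coefficient.
#'
#' @param tracks Tibble with `track_id`, `frame`, `x`, `y` (and optionally
#'   other columns carried along).
#' @param dt Frame interval (s) for [apparent_D()].
#' @return One row per track with `x`, `y` of the first localization and
#'   `D_star`.
#' @export
track_positions <- function(tracks, dt = 0.015) {
  firsts <- tracks %>%
    dplyr::arrange(.data$track_id, .data$frame) %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()
  dplyr::left_join(firsts, apparent_D(tracks, dt = dt)[, c("track_id", "D_star")],
                   by = "track_id")
}
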