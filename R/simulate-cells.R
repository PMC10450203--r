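#' Exponential cluster-size model
#'
#' Cluster sizes follow a truncated-exponential law fitted to experimental
#' cluster-size histograms as `y = a * exp(-b * x)`. Sampling uses the inverse
#' transform `X = -(1/b) * log(1 - b*u/a)` with `u` uniform on (0, 1); draws
#' with `b*u/a >= 1` are rejected and redrawn, and sizes are rounded and
#' clamped to >= 1. With `a = b` the law is a plain exponential with mean
#' `1/b` molecules.
#'
#' @param a Amplitude (> 0).
#' @param b Decay rate per molecule (> 0).
#' @return An object of class `cluster_size_model`.
#' @export
cluster_size_model <- function(a, b) {
  if (!(is.numeric(a) && is.numeric(b) && a > 0 && b > 0)) {
    abort("cluster_size_model requires a > 0 and b > 0")
  }
  structure(list(a = a, b = b), class = "cluster_size_model")
}

#' Sample integer cluster sizes from the exponential law
#'
#' @param model A [cluster_size_model()].
#' @param n Number of sizes to draw.
#' @param seed Optional integer seed.
#' @return Integer vector of `n` sizes, each >= 1.
#' @examples
#' sample_cluster_sizes(cluster_size_model(0.1, 0.1), 5, seed = 1)
#' @export
sample_cluster_sizes <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "cluster_size_model"))
  if (!is.numeric(n) || n < 1) abort("n must be a positive count")
  a <- model$a
  b <- model$b
  # acceptance probability of the rejection step: P(b*u/a < 1) = min(1, a/b)
  if (min(1, a / b) < 0.01) {
    abort("cluster size model has rejection acceptance < 1% (b too large relative to a)")
  }
  with_seed(seed, {
    out <- numeric(0)
    while (base::length(out) < n) {
      u <- runif(max(2L * (n - base::length(out)), 64L))
      u <- u[b * u / a < 1]
      out <- c(out, -(1 / b) * log(1 - b * u / a))
    }
    pmax(1L, as.integer(round(out[1:n])))
  })
}

#' Place rrn operon transcription sites on the nucleoid surface
#'
#' Each operon's long-axis coordinate is set by a linear genomic-distance map:
#' the origin of replication sits at the pole-proximal nucleoid tip and the
#' terminus at mid-cell, so an operon at `offset_kb` from oriC on a replication
#' arm of `arm_length_kb` lies at distance `(offset_kb/arm_length_kb) *
#' nucleoid_a` from the tip. This defines a ring of candidate positions around
#' the nucleoid periphery at that coordinate; azimuthal angles are proposed
#' uniformly until all pairwise separations are at least `min_sep`. All sites
#' of one nucleoid share the ori-proximal pole (drawn at random per call).
#'
#' @param cell A [cell_geometry()].
#' @param offsets_kb Genomic distances of the operons from oriC (kb).
#' @param arm_length_kb Replication arm length (kb); default half the 4.64 Mb
#'   genome.
#' @param min_sep Minimum pairwise 3D separation between sites (um).
#' @param seed Optional integer seed.
#' @param max_proposals Proposals allowed per operon before declaring the
#'   packing infeasible.
#' @return Tibble with one row per operon: `offset_kb`, `x`, `y`, `z`.
#' @export
place_rrn_sites <- function(cell, offsets_kb, arm_length_kb = 2320,
                            min_sep = 0.070, seed = NULL,
                            max_proposals = 1e4) {
  stopifnot(inherits(cell, "cell_geometry"))
  if (any(offsets_kb < 0 | offsets_kb > arm_length_kb)) {
    abort("operon offsets must lie in [0, arm_length_kb]")
  }
  if (min_sep < 0) abort("min_sep must be >= 0")
  a <- cell$nucleoid_a
  b <- cell$nucleoid_b
  with_seed(seed, {
    side <- sample(c(-1, 1), 1)
    xs <- side * a * (1 - offsets_kb / arm_length_kb)
    rho <- b * sqrt(pmax(0, 1 - (xs / a)^2))
    ys <- zs <- numeric(base::length(xs))
    for (i in seq_along(xs)) {
      placed <- FALSE
      for (trial in seq_len(max_proposals)) {
        theta <- runif(1, 0, 2 * pi)
        yi <- rho[i] * cos(theta)
        zi <- rho[i] * sin(theta)
        if (i == 1) {
          ok <- TRUE
        } else {
          j <- seq_len(i - 1)
          ok <- all((xs[j] - xs[i])^2 + (ys[j] - yi)^2 + (zs[j] - zi)^2 >=
            min_sep^2)
        }
        if (ok) {
          ys[i] <- yi
          zs[i] <- zi
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place operon %d with min separation %.3f um after %d proposals",
          i, min_sep, max_proposals
        ))
      }
    }
    tibble::tibble(offset_kb = offsets_kb, x = xs, y = ys, z = zs)
  })
}

#' Monte-Carlo cell simulation configuration
#'
#' Bundles the parameters of the four-population cell model: `n_molecules`
#' RNAPs split into an immobile fraction (molecules bound at rrn operon sites
#' or in small clusters spread through the nucleoid) and a mobile fraction
#' (molecules uniform in the nucleoid, with a sub-fraction diverted to
#' localization noise uniform in the whole cell volume).
#'
#' Strain presets follow the study design: `"WT"` uses 1800 molecules and all
#' seven operons, `"D5"` 1800 molecules with rrnC and rrnB remaining (42 and
#' 265 kb from oriC), `"D6"` 1200 molecules with only rrnE (306 kb).
#'
#' @param strain `"WT"`, `"D5"` or `"D6"`; sets `n_molecules` and
#'   `rrn_offsets_kb` unless given explicitly.
#' @param n_molecules Total molecules per cell.
#' @param f_immobile Immobile fraction of all molecules.
#' @param f_rrn_of_immobile Fraction of immobile molecules bound at rrn sites
#'   (remainder goes to small clusters).
#' @param noise_fraction Fraction of the mobile population diverted to
#'   whole-cell noise.
#' @param rrn_offsets_kb Operon offsets from oriC (kb).
#' @param arm_length_kb Replication arm length (kb).
#' @param min_operon_sep Minimum separation between operon sites (um).
#' @param cluster_sigma Isotropic Gaussian radial spread of cluster members
#'   (um).
#' @param cluster_size_model A [cluster_size_model()] for small-cluster sizes.
#' @param cell A [cell_geometry()].
#' @param seed Optional integer seed stored in the config.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- simulation_config("D5", seed = 1)
#' @export
simulation_config <- function(strain = c("WT", "D5", "D6"),
                              n_molecules = NULL,
                              f_immobile = 0.48,
                              f_rrn_of_immobile = 0.60,
                              noise_fraction = 0.10,
                              rrn_offsets_kb = NULL,
                              arm_length_kb = 2320,
                              min_operon_sep = 0.070,
                              cluster_sigma = 0.040,
                              cluster_size_model = rnaptrack::cluster_size_model(0.1, 0.1),
                              cell = cell_geometry(3.0, 1.0),
                              seed = NULL) {
  strain <- match.arg(strain)
  offs <- rrn_operon_offsets()
  if (is.null(rrn_offsets_kb)) {
    rrn_offsets_kb <- switch(strain,
      WT = offs,
      D5 = offs[c("rrnC", "rrnB")],
      D6 = offs["rrnE"]
    )
  }
  if (is.null(n_molecules)) {
    n_molecules <- switch(strain, WT = 1800L, D5 = 1800L, D6 = 1200L)
  }
  fr <- c(f_immobile, f_rrn_of_immobile, noise_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  stopifnot(inherits(cell, "cell_geometry"),
            inherits(cluster_size_model, "cluster_size_model"))
  structure(
    list(
      strain = strain, n_molecules = as.integer(n_molecules),
      f_immobile = f_immobile, f_rrn_of_immobile = f_rrn_of_immobile,
      noise_fraction = noise_fraction,
      rrn_offsets_kb = rrn_offsets_kb, arm_length_kb = arm_length_kb,
      min_operon_sep = min_operon_sep, cluster_sigma = cluster_sigma,
      cluster_size_model = cluster_size_model, cell = cell, seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> strain %s: %d molecules, %d operons, f_imm %.2f, f_rrn %.2f\n",
    x$strain, x$n_molecules, base::length(x$rrn_offsets_kb),
    x$f_immobile, x$f_rrn_of_immobile
  ))
  invisible(x)
}

#' Read or write a simulation config as YAML
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  y <- config
  y$cell <- list(
    length_um = config$cell$length, width_um = config$cell$width,
    pole_gap_um = config$cell$pole_gap,
    nucleoid_shrink = config$cell$nucleoid_shrink
  )
  y$cluster_size_model <- list(a = config$cluster_size_model$a,
                               b = config$cluster_size_model$b)
  yaml::write_yaml(unclass(y), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  simulation_config(
    strain = y$strain, n_molecules = y$n_molecules,
    f_immobile = y$f_immobile, f_rrn_of_immobile = y$f_rrn_of_immobile,
    noise_fraction = y$noise_fraction,
    rrn_offsets_kb = setNames(as.numeric(unlist(y$rrn_offsets_kb)),
                              names(unlist(y$rrn_offsets_kb))),
    arm_length_kb = y$arm_length_kb, min_operon_sep = y$min_operon_sep,
    cluster_sigma = y$cluster_sigma,
    cluster_size_model = cluster_size_model(y$cluster_size_model$a,
                                            y$cluster_size_model$b),
    cell = cell_geometry(y$cell$length_um, y$cell$width_um,
                         y$cell$pole_gap_um,
                         as.numeric(unlist(y$cell$nucleoid_shrink))),
    seed = y$seed
  )
}

# Gaussian cluster members around a 3D centre, regenerated until all lie
# inside the cell volume.
cluster_members <- function(center, size, sigma, cell) {
  m <- matrix(rnorm(3 * size, mean = rep(center, each = size), sd = sigma),
              ncol = 3)
  bad <- which(!in_cell_3d(m[, 1], m[, 2], m[, 3], cell))
  while (base::length(bad) > 0) {
    m[bad, ] <- matrix(
      rnorm(3 * base::length(bad), mean = rep(center, each = base::length(bad)),
            sd = sigma),
      ncol = 3
    )
    mb <- m[bad, , drop = FALSE]
    bad <- bad[!in_cell_3d(mb[, 1], mb[, 2], mb[, 3], cell)]
  }
  m
}

#' Simulate one cell of the four-population RNAP model
#'
#' Draws `n_molecules` 3D positions split into four labelled populations --
#' `rrn` (bound at operon sites on the nucleoid periphery), `small_cluster`
#' (bound in small clusters through the nucleoid), `mobile` (uniform in the
#' nucleoid) and `noise` (uniform in the whole cell volume) -- then projects
#' to 2D by dropping the z coordinate. Cluster members are isotropic Gaussians
#' around their centres, regenerated until inside the cell volume. Population
#' counts are exact: `round(f_immobile * n)` immobile molecules, of which
#' `round(f_rrn_of_immobile * n_immobile)` are rrn-bound; of the mobile
#' remainder, `round(noise_fraction * n_mobile)` become noise.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed; overrides `config$seed`.
#' @return Tibble with columns `x`, `y` (um), `population` (one of `rrn`,
#'   `small_cluster`, `mobile`, `noise`) and `species` (`immobile`/`mobile`).
#'   The operon site table is attached as attribute `"rrn_sites"`.
#' @examples
#' locs <- simulate_cell(simulation_config("D6"), seed = 2)
#' table(locs$population)
#' @export
simulate_cell <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (is.null(seed)) config$seed else seed
  n <- config$n_molecules
  n_imm <- round(config$f_immobile * n)
  n_rrn <- round(config$f_rrn_of_immobile * n_imm)
  n_small <- n_imm - n_rrn
  n_mobile_all <- n - n_imm
  n_noise <- round(config$noise_fraction * n_mobile_all)
  n_mob <- n_mobile_all - n_noise
  cell <- config$cell
  with_seed(seed, {
    sites <- place_rrn_sites(cell, config$rrn_offsets_kb,
      arm_length_kb = config$arm_length_kb,
      min_sep = config$min_operon_sep
    )
    parts <- list()
    # rrn-bound molecules allocated uniformly among operon sites
    if (n_rrn > 0) {
      alloc <- as.vector(stats::rmultinom(1, n_rrn,
                                          rep(1, nrow(sites)) / nrow(sites)))
      rrn_pts <- purrr::map2(seq_len(nrow(sites)), alloc, function(i, k) {
        if (k == 0) return(NULL)
        cluster_members(c(sites$x[i], sites$y[i], sites$z[i]), k,
                        config$cluster_sigma, cell)
      })
      m <- do.call(rbind, rrn_pts)
      parts$rrn <- tibble::tibble(x = m[, 1], y = m[, 2], population = "rrn")
    }
    # small clusters: sizes from the exponential law, centres uniform in the
    # nucleoid, last cluster trimmed so counts are exact
    if (n_small > 0) {
      sizes <- integer(0)
      while (sum(sizes) < n_small) {
        sizes <- c(sizes, sample_cluster_sizes(config$cluster_size_model, 16L))
      }
      k <- which(cumsum(sizes) >= n_small)[1]
      sizes <- sizes[seq_len(k)]
      sizes[k] <- sizes[k] - (sum(sizes) - n_small)
      sizes <- sizes[sizes > 0]
      centers <- sample_uniform(cell, base::length(sizes), region = "nucleoid")
      m <- do.call(rbind, purrr::map(seq_along(sizes), function(i) {
        cluster_members(c(centers$x[i], centers$y[i], centers$z[i]),
                        sizes[i], config$cluster_sigma, cell)
      }))
      parts$small <- tibble::tibble(x = m[, 1], y = m[, 2],
                                    population = "small_cluster")
    }
    if (n_mob > 0) {
      p <- sample_uniform(cell, n_mob, region = "nucleoid", project = TRUE)
      parts$mob <- tibble::tibble(x = p$x, y = p$y, population = "mobile")
    }
    if (n_noise > 0) {
      p <- sample_uniform(cell, n_noise, region = "cell", project = TRUE)
      parts$noise <- tibble::tibble(x = p$x, y = p$y, population = "noise")
    }
    out <- dplyr::bind_rows(parts)
    out$species <- if_else(out$population %in% c("rrn", "small_cluster"),
                           "immobile", "mobile")
    attr(out, "rrn_sites") <- sites
    out
  })
}

#' Write or read a localization table as CSV
#'
#' Columns follow the package convention: `cell_id`, `frame`, `x_um`, `y_um`,
#' plus any label columns present.
#'
#' @param locs Localization tibble.
#' @param path File path.
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
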