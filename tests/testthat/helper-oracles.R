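# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths.

# Brute-force DBSCAN: neighbourhood enumeration + connected components over
# core points (igraph). Border points are reported with the *set* of clusters
# they are reachable from, since their assignment is ambiguous in DBSCAN.
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  comp <- rep(NA_integer_, n)
  core_idx <- which(core)
  if (length(core_idx) > 0) {
    edges <- do.call(rbind, lapply(core_idx, function(i) {
      js <- intersect(nb[[i]], core_idx)
      if (length(js) == 0) return(NULL)
      cbind(i, js)
    }))
    g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                     directed = FALSE)
    memb <- igraph::components(g)$membership
    comp[as.integer(names(memb))] <- as.integer(memb)
  }
  border_sets <- lapply(seq_len(n), function(i) {
    if (core[i]) return(integer(0))
    sort(unique(comp[intersect(nb[[i]], core_idx)]))
  })
  list(core = core, core_comp = comp, border_sets = border_sets)
}

# Canonical form of a partition restricted to a point subset: cluster labels
# renumbered by first appearance, so partitions compare independent of ids.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# Check a cluster_rnap() result against the brute-force oracle.
expect_dbscan_matches_oracle <- function(res, eps, min_pts) {
  or <- brute_dbscan(res$x, res$y, eps, min_pts)
  expect_identical(res$role == "core", unname(or$core))
  core_i <- which(or$core)
  expect_identical(
    canonical_partition(res$cluster[core_i]),
    canonical_partition(or$core_comp[core_i])
  )
  # map package cluster ids to oracle component ids via the core points
  id_map <- tapply(or$core_comp[core_i], res$cluster[core_i],
                   function(v) unique(v))
  for (i in which(!or$core)) {
    if (is.na(res$cluster[i])) {
      expect_length(or$border_sets[[i]], 0)
    } else {
      expect_true(id_map[[as.character(res$cluster[i])]] %in%
                    or$border_sets[[i]])
    }
  }
  invisible(TRUE)
}

# Independent pair-correlation estimate: base-R dist() + findInterval binning
# with its own uniform null (rejection sampling written out long-hand).
brute_pair_correlation <- function(pts, cell, bin_width, r_max, n_null) {
  n_bins <- round(r_max / bin_width)
  edges <- seq(0, r_max, by = bin_width)
  hist_of <- function(px, py) {
    dd <- as.vector(dist(cbind(px, py)))
    tabulate(findInterval(dd[dd < r_max], edges), nbins = n_bins)
  }
  obs <- hist_of(pts$x, pts$y)
  hw <- cell$width / 2
  hc <- cell$length / 2 - hw
  null_acc <- numeric(n_bins)
  for (k in seq_len(n_null)) {
    xs <- ys <- numeric(0)
    while (length(xs) < nrow(pts)) {
      x <- runif(4 * nrow(pts), -cell$length / 2, cell$length / 2)
      y <- runif(4 * nrow(pts), -hw, hw)
      z <- runif(4 * nrow(pts), -hw, hw)
      r2 <- y^2 + z^2
      ok <- (abs(x) <= hc & r2 <= hw^2) |
        (abs(x) > hc & (abs(x) - hc)^2 + r2 <= hw^2)
      xs <- c(xs, x[ok])
      ys <- c(ys, y[ok])
    }
    null_acc <- null_acc + hist_of(xs[seq_len(nrow(pts))],
                                   ys[seq_len(nrow(pts))])
  }
  null_mean <- null_acc / n_null
  ifelse(null_mean > 0, obs / null_mean, NA_real_)
}

# Numerical area of the union of discs intersected with a 2D spherocylinder
# outline, relative to the outline area, by grid integration.
disc_union_area_fraction <- function(foci, radius, L, W, h = 0.002) {
  xs <- seq(-L / 2, L / 2, by = h)
  ys <- seq(-W / 2, W / 2, by = h)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  hw <- W / 2
  hc <- L / 2 - hw
  inside <- abs(gy) <= hw &
    (abs(gx) <= hc | (pmax(abs(gx) - hc, 0))^2 + gy^2 <= hw^2)
  near <- rep(FALSE, length(gx))
  for (i in seq_len(nrow(foci))) {
    near <- near | ((gx - foci$x[i])^2 + (gy - foci$y[i])^2 <= radius^2)
  }
  sum(inside & near) / sum(inside)
}

# Numerical inversion of the truncated-exponential cluster-size CDF,
# independent of the closed-form transform.
brute_cluster_sizes <- function(a, b, n) {
  cdf <- function(x) (a / b) * (1 - exp(-b * x))
  x_hi <- -log(1e-12) / b
  out <- numeric(0)
  while (length(out) < n) {
    u <- runif(2 * (n - length(out)) + 16)
    u <- u[u < cdf(x_hi)]
    xs <- vapply(u, function(ui) {
      uniroot(function(x) cdf(x) - ui, c(0, x_hi), tol = 1e-10)$root
    }, numeric(1))
    out <- c(out, xs)
  }
  pmax(1L, as.integer(round(out[seq_len(n)])))
}
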