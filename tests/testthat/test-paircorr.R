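test_that("uniform points self-normalize to a flat g(r)", {
  cell <- cell_geometry(3, 1)
  gr_list <- lapply(1:10, function(i) {
    pts <- sample_uniform(cell, 500, region = "cell", project = TRUE,
                          seed = 100 + i)
    pair_correlation_cell(pts, cell, r_max = 0.6, n_null_draws = 10,
                          seed = 500 + i)
  })
  m <- mean_pair_correlation(gr_list)
  band <- m$g[m$r >= 0.05 & m$r <= 0.5]
  expect_lt(abs(mean(band, na.rm = TRUE) - 1), 0.1)
})

test_that("a tight cluster produces strong short-range correlation", {
  cell <- cell_geometry(3, 1)
  set.seed(102)
  pts <- tibble::tibble(x = rnorm(300, 0, 0.04), y = rnorm(300, 0, 0.02))
  gr <- pair_correlation_cell(pts, cell, r_max = 1.0, n_null_draws = 10,
                              seed = 1)
  expect_gt(mean(gr$g[gr$r < 0.1], na.rm = TRUE), 5)
  expect_lt(mean(gr$g[gr$r > 0.5], na.rm = TRUE), 1)
})

test_that("g(r) matches an independent brute-force implementation", {
  cell <- cell_geometry(3, 1)
  set.seed(103)
  clustered <- tibble::tibble(x = rnorm(600, 0.5, 0.03),
                              y = rnorm(600, 0, 0.02))
  uniform <- sample_uniform(cell, 2400, region = "cell", project = TRUE,
                            seed = 104)
  pts <- dplyr::bind_rows(clustered, uniform)
  gr <- pair_correlation_cell(pts, cell, bin_width = 0.01, r_max = 0.5,
                              n_null_draws = 30, seed = 105)
  set.seed(106)
  g_ref <- brute_pair_correlation(pts, cell, bin_width = 0.01, r_max = 0.5,
                                  n_null = 60)
  ok <- !is.na(gr$g) & !is.na(g_ref) & g_ref > 0 & gr$n_pairs > 500
  expect_true(any(ok))
  expect_lt(max(abs(gr$g[ok] / g_ref[ok] - 1)), 0.03)
})

test_that("g(r) is invariant under rigid motions of points with the frame", {
  cell <- cell_geometry(3, 1)
  pts <- sample_uniform(cell, 400, region = "nucleoid", project = TRUE,
                        seed = 107)
  g1 <- pair_correlation_cell(pts, cell, r_max = 0.5, n_null_draws = 5,
                              seed = 9)
  flipped <- tibble::tibble(x = -pts$x, y = -pts$y) # 180 degree rotation
  g2 <- pair_correlation_cell(flipped, cell, r_max = 0.5, n_null_draws = 5,
                              seed = 9)
  expect_equal(g1$n_pairs, g2$n_pairs)
  expect_equal(g1$g, g2$g)
})

test_that("mean pair correlation averages per-bin and checks binning", {
  mk <- function(g) {
    rnaptrack:::new_pair_correlation(c(0.005, 0.015), g, c(10, 10), 0.01,
                                     100, 5)
  }
  m <- mean_pair_correlation(list(mk(c(0.8, 1)), mk(c(1.2, 1))))
  expect_equal(m$g, c(1, 1))
  expect_identical(mean_pair_correlation(list(mk(c(1, 1))))$g, c(1, 1))

  bad <- rnaptrack:::new_pair_correlation(c(0.01, 0.03), c(1, 1), c(1, 1),
                                          0.02, 100, 5)
  expect_error(mean_pair_correlation(list(mk(c(1, 1)), bad)), "binning")

  # NA bins are excluded per bin
  m2 <- mean_pair_correlation(list(mk(c(NA, 1)), mk(c(1.4, 1))))
  expect_equal(m2$g, c(1.4, 1))
})

test_that("pair correlation rejects degenerate input and truncates r_max", {
  cell <- cell_geometry(3, 1)
  expect_error(
    pair_correlation_cell(tibble::tibble(x = 1, y = 0), cell),
    "at least 2"
  )
  pts <- sample_uniform(cell, 50, region = "cell", project = TRUE, seed = 1)
  expect_warning(
    pair_correlation_cell(pts, cell, r_max = 5, n_null_draws = 2, seed = 1),
    "truncating"
  )
})

test_that("co-localization fractions hit their analytic limits", {
  cell <- cell_geometry(3, 1)
  foci <- tibble::tibble(x = c(-1, 0.5), y = 0)
  on_foci <- foci[rep(1:2, 25), ]
  expect_equal(coloc_fraction(on_foci, foci, cell)$fraction, 1)

  far <- tibble::tibble(x = 1.2, y = 0.1)
  expect_equal(coloc_fraction(far, tibble::tibble(x = -1.2, y = 0),
                              cell)$fraction, 0)

  expect_error(coloc_fraction(far, far[0, ], cell), "at least one focus")
})

test_that("the uniform-nucleoid null fraction matches direct area integration", {
  cell <- cell_geometry(3, 1)
  foci <- foci_on_axis(cell, c(0.15, 0.15, 0.30), c(-1, 1, -1))
  got <- coloc_fraction(tibble::tibble(x = 0, y = 0), foci, cell,
                        null = TRUE, n_null_points = 4e4, n_null_draws = 4,
                        seed = 11)$fraction
  want <- disc_union_area_fraction(foci, 0.2, L = 0.75 * 3, W = 0.75 * 1)
  expect_lt(abs(got - want), 0.01)
})

test_that("cross pair correlation of uniform points is flat", {
  cell <- cell_geometry(3, 1)
  shrunk <- cell_geometry(2.25, 0.75, pole_gap = 0)
  pts <- rnaptrack:::sample_uniform_area(shrunk, 3000, seed = 12)
  foci <- foci_on_axis(cell, c(0.15, 0.3), c(-1, 1))
  gx <- cross_pair_correlation(pts, foci, cell, r_max = 0.8,
                               n_null_draws = 20, seed = 13)
  band <- gx$g[gx$r > 0.05 & gx$r < 0.6]
  expect_lt(abs(mean(band, na.rm = TRUE) - 1), 0.05)
})

test_that("doubling the null draws barely changes g(r)", {
  cell <- cell_geometry(3, 1)
  pts <- sample_uniform(cell, 2000, region = "cell", project = TRUE,
                        seed = 14)
  g20 <- pair_correlation_cell(pts, cell, bin_width = 0.025, r_max = 0.5,
                               n_null_draws = 20, seed = 15)
  g40 <- pair_correlation_cell(pts, cell, bin_width = 0.025, r_max = 0.5,
                               n_null_draws = 40, seed = 16)
  ok <- g20$r >= 0.05 & !is.na(g20$g) & !is.na(g40$g)
  expect_lt(max(abs(g40$g[ok] / g20$g[ok] - 1)), 0.01)
})
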