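test_that("cluster-size sampling follows the inverse-transform law", {
  # with a = 1, b = 0.05 the transform is bounded by -20*log(0.95) < 1.5,
  # so every rounded, clamped size is exactly 1
  s <- sample_cluster_sizes(cluster_size_model(1, 0.05), 500, seed = 1)
  expect_true(all(s == 1L))

  # distribution matches an independent numerical inversion of the same CDF,
  # including the rejection branch (b > a)
  a <- 0.10
  b <- 0.15
  s1 <- sample_cluster_sizes(cluster_size_model(a, b), 2e4, seed = 2)
  set.seed(1002)
  s2 <- brute_cluster_sizes(a, b, 2e4)
  ks <- suppressWarnings(stats::ks.test(s1, s2)$statistic)
  expect_lt(unname(ks), 0.015)
  expect_true(all(s1 >= 1))

  expect_error(sample_cluster_sizes(cluster_size_model(1, 200), 10),
               "acceptance")
  expect_error(cluster_size_model(-1, 1), "a > 0")
})

test_that("rrn sites sit on the nucleoid surface with genomic ordering and separation", {
  cell <- cell_geometry(3, 1)
  a <- cell$nucleoid_a
  b <- cell$nucleoid_b
  offs <- rrn_operon_offsets()

  # single operon: deterministic long-axis coordinate on the surface
  for (s in 1:20) {
    one <- place_rrn_sites(cell, 306, seed = s)
    expect_equal(abs(one$x), a * (1 - 306 / 2320), tolerance = 1e-12)
    expect_equal((one$x / a)^2 + (one$y / b)^2 + (one$z / b)^2, 1,
                 tolerance = 1e-9)
  }

  # seven operons: minimum pairwise separation respected in every draw
  for (s in 1:100) {
    sites <- place_rrn_sites(cell, offs, seed = s)
    d <- dist(cbind(sites$x, sites$y, sites$z))
    expect_gte(min(d), 0.070)
  }

  # monotone genomic-distance map: closer to oriC means closer to the pole
  two <- place_rrn_sites(cell, c(42, 265), seed = 3)
  expect_gt(abs(two$x[1]), abs(two$x[2]))

  # infeasible packing: two operons at the same offset on a degenerate ring
  expect_error(
    place_rrn_sites(cell, c(0, 0), min_sep = 0.07, seed = 1,
                    max_proposals = 200),
    "could not place"
  )
})

test_that("simulate_cell conserves population counts and containment", {
  cfg <- simulation_config("WT", seed = 5)
  locs <- simulate_cell(cfg)
  expect_equal(nrow(locs), 1800)
  expect_equal(sum(locs$species == "immobile"), 864)
  expect_equal(sum(locs$species == "mobile"), 936)
  expect_true(all(rnaptrack:::in_cell_2d(locs$x, locs$y, cfg$cell,
                                         tol = 1e-9)))

  # counts conserved exactly across configs
  for (strain in c("D5", "D6")) {
    cfg2 <- simulation_config(strain)
    l2 <- simulate_cell(cfg2, seed = 8)
    expect_equal(nrow(l2), cfg2$n_molecules)
  }

  # with no noise, every non-noise population stays nucleoid-associated:
  # mobile points obey the projected spheroid inequality
  cfg0 <- simulation_config("D5", noise_fraction = 0)
  l0 <- simulate_cell(cfg0, seed = 9)
  expect_equal(sum(l0$population == "noise"), 0)
  mob <- l0[l0$population == "mobile", ]
  expect_true(all((mob$x / cfg0$cell$nucleoid_a)^2 +
                    (mob$y / cfg0$cell$nucleoid_b)^2 <= 1 + 1e-12))
})

test_that("exterior fraction of immobile molecules grows with the rrn-bound share", {
  fracs <- vapply(c(0.30, 0.55, 0.80), function(fr) {
    cfg <- simulation_config("D5", f_rrn_of_immobile = fr)
    lf <- unlist(lapply(1:30, function(i) {
      l <- simulate_cell(cfg, seed = 1000 + i)
      imm <- l[l$species == "immobile", ]
      np <- normalize_position(imm, cfg$cell, tol = 1e-6)
      np$l_folded
    }))
    mean(lf <= 0.25)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("track simulator reproduces the analytic apparent-D relation", {
  dt <- 0.015
  sig <- 0.035
  # immobile molecules: apparent D* equals sigma^2/dt
  trk <- simulate_tracks(5000, f_immobile = 1, D_immobile = 0,
                         loc_error_sigma = sig, dt = dt, seed = 31)
  d <- apparent_D(trk, dt = dt)$D_star
  target <- sig^2 / dt
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - target), 3 * se)
  expect_lt(abs(mean(d) - 0.0817), 0.003)

  # mobile molecules: apparent D* = D_true + sigma^2/dt, near the 0.36 scale
  trk2 <- simulate_tracks(5000, f_immobile = 0, D_mobile = 0.28,
                          loc_error_sigma = sig, dt = dt, seed = 32)
  d2 <- apparent_D(trk2, dt = dt)$D_star
  expect_lt(abs(mean(d2) - (0.28 + target)), 3 * sd(d2) / sqrt(length(d2)))

  expect_equal(nrow(simulate_tracks(0, 0.5)), 0)
  expect_error(simulate_tracks(5, 0.5, D_mobile = -1), "positive")

  # species labels are constant within a track
  spl <- tapply(trk$species, trk$track_id, function(v) length(unique(v)))
  expect_true(all(spl == 1))
})

test_that("rendered frames place photons at emitter positions deterministically", {
  one <- render_frames(data.frame(x = 5, y = 5), photons = 1000,
                       noise = FALSE)
  img <- one[, , 1]
  peak <- which(img == max(img), arr.ind = TRUE)
  # emitter at 5 um with 0.1 um pixels straddles pixels 50/51
  expect_true(peak[1, 1] %in% c(50, 51) && peak[1, 2] %in% c(50, 51))

  two <- render_frames(data.frame(x = c(3, 5), y = c(5, 5)), photons = 1000,
                       noise = FALSE)[, , 1]
  prof <- two[50, ]
  local_max <- which(diff(sign(diff(prof))) == -2) + 1
  expect_gte(length(local_max), 2)

  s1 <- render_frames(data.frame(x = runif(20, 1, 9), y = runif(20, 1, 9)),
                      photons = 500, background = 5, seed = 3)
  s2 <- render_frames(attr(s1, "truth"), photons = 500, background = 5,
                      seed = 3)
  expect_identical(as.vector(s1), as.vector(s2))

  expect_error(render_frames(data.frame(x = 5, y = 5), pixel = 0),
               "pixel")
  expect_error(render_frames(data.frame(x = 50, y = 5)), "field of view")
})

test_that("simulation config validates and round-trips through YAML", {
  expect_error(simulation_config("WT", f_immobile = 1.2), "fractions")
  cfg <- simulation_config("D5", seed = 4, cluster_sigma = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_molecules, cfg$n_molecules)
  expect_equal(back$cluster_sigma, 0.05)
  expect_equal(unname(back$rrn_offsets_kb), unname(cfg$rrn_offsets_kb))
  expect_equal(back$cell$length, cfg$cell$length)
})
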