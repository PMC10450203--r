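test_that("noiseless emitters are localized to sub-pixel accuracy", {
  stk <- render_frames(data.frame(x = 5.00, y = 5.00), photons = 1000,
                       noise = FALSE)
  locs <- detect_and_fit(stk[, , 1])
  expect_equal(nrow(locs), 1)
  expect_lt(abs(locs$x - 5.00), 1e-3)
  expect_lt(abs(locs$y - 5.00), 1e-3)
  expect_true(all(locs$sigma_x > 0 & locs$sigma_y > 0))

  # off-grid position, still sub-pixel
  stk2 <- render_frames(data.frame(x = 4.537, y = 5.213), photons = 1000,
                        noise = FALSE)
  l2 <- detect_and_fit(stk2[, , 1])
  expect_lt(abs(l2$x - 4.537), 2e-3)
  expect_lt(abs(l2$y - 5.213), 2e-3)

  expect_error(detect_and_fit(matrix(c(1, NA), 1)), "finite")
  expect_error(detect_and_fit(matrix(1, 5, 5), bandpass = c(3, 1)),
               "sigma_small")
})

test_that("localization precision and false-positive rate behave under noise", {
  # Monte-Carlo localization precision at 1000 photons over background 10
  est <- vapply(1:50, function(s) {
    stk <- render_frames(data.frame(x = 5, y = 5), photons = 1000,
                         background = 10, seed = s)
    locs <- detect_and_fit(stk[, , 1])
    d2 <- (locs$x - 5)^2 + (locs$y - 5)^2
    locs$x[which.min(d2)]
  }, numeric(1))
  expect_lt(sd(est), 0.04)

  # blank noise-only frames: no detections in at least 95% of seeds
  empty <- vapply(1:100, function(s) {
    img <- rnaptrack:::with_seed(200 + s,
      matrix(rpois(60 * 60, 10), 60, 60))
    nrow(detect_and_fit(img, threshold_k = 5))
  }, numeric(1))
  expect_gte(mean(empty == 0), 0.95)
})

test_that("detection is translation-equivariant and monotone in threshold", {
  set.seed(77)
  truth <- data.frame(x = c(2.2, 5.1, 7.6), y = c(3.3, 6.4, 2.8))
  stk <- render_frames(truth, photons = 800, background = 5, seed = 7)
  img <- stk[, , 1]
  locs <- detect_and_fit(img)

  # shift by 10 whole pixels in x (1 um): all fits shift by exactly that
  shifted <- matrix(5, nrow(img), ncol(img))
  shifted[, 11:ncol(img)] <- img[, 1:(ncol(img) - 10)]
  locs_s <- detect_and_fit(shifted)
  common <- min(nrow(locs), nrow(locs_s))
  o1 <- order(locs$x)[seq_len(common)]
  o2 <- order(locs_s$x)[seq_len(common)]
  expect_equal(locs_s$x[o2], locs$x[o1] + 1.0, tolerance = 1e-6)
  expect_equal(locs_s$y[o2], locs$y[o1], tolerance = 1e-6)

  counts <- vapply(c(2, 4, 8, 20), function(k) {
    nrow(detect_and_fit(img, threshold_k = k))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("focus detection recovers planted diffraction-limited spots", {
  truth <- data.frame(x = c(2.0, 4.0, 6.5), y = c(2.5, 5.0, 3.5))
  # 20 identical noiseless frames: averaging is the identity
  stack <- render_frames(truth[rep(1:3, 20), ] |>
                           transform(frame = rep(1:20, each = 3)),
                         photons = 800, noise = FALSE)
  foci <- detect_foci(stack)
  expect_equal(nrow(foci), 3)
  ord <- order(foci$x)
  expect_lt(max(abs(foci$x[ord] - truth$x)), 1e-3)
  expect_lt(max(abs(foci$y[ord] - truth$y)), 1e-3)

  # Poisson-noisy stack, spots >= 500 nm apart: all within 50 nm of truth
  stack_n <- render_frames(truth[rep(1:3, 20), ] |>
                             transform(frame = rep(1:20, each = 3)),
                           photons = 300, background = 10, seed = 9)
  fn <- detect_foci(stack_n)
  expect_equal(nrow(fn), 3)
  ordn <- order(fn$x)
  expect_lt(max(sqrt((fn$x[ordn] - truth$x)^2 + (fn$y[ordn] - truth$y)^2)),
            0.050)

  # planted-count recovery across simulated cells: mean foci per cell
  n_found <- vapply(1:20, function(s) {
    fx <- runif(3, 1.5, 8.5)
    fy <- runif(3, 1.5, 8.5)
    while (min(dist(cbind(fx, fy))) < 0.8) {
      fx <- runif(3, 1.5, 8.5)
      fy <- runif(3, 1.5, 8.5)
    }
    tr <- data.frame(x = rep(fx, 20), y = rep(fy, 20),
                     frame = rep(1:20, each = 3))
    st <- render_frames(tr, photons = 300, background = 10, seed = 400 + s)
    nrow(detect_foci(st))
  }, numeric(1))
  expect_lt(abs(mean(n_found) - 3.0), 0.1)
})

test_that("repeat localizations in flanking frames merge into one record", {
  locs <- tibble::tibble(
    frame = c(1, 2, 3, 2, 5),
    x = c(1.000, 1.020, 1.010, 3.000, 1.000),
    y = c(1.000, 0.990, 1.005, 3.000, 1.000)
  )
  merged <- merge_repeat_localizations(locs, radius = 0.1)
  # the frame 1-3 run collapses to its first appearance; the distant point
  # and the re-activation after a gap survive
  expect_equal(nrow(merged), 3)
  expect_equal(attr(merged, "merged"), 2)
  expect_setequal(merged$frame, c(1, 2, 5))
  expect_true(3.0 %in% merged$x)
})
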