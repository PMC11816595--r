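test_that("patch grids enumerate row-major half-open blocks", {
  g224 <- segment_patches(c(224L, 224L), 2)
  expect_equal(g224$n_patches, 12544L)
  expect_equal(c(g224$rows, g224$cols), c(112L, 112L))

  g4 <- segment_patches(c(4L, 4L), 2)
  expect_equal(g4$n_patches, 4L)
  px <- patch_pixels(g4, 3)
  expect_equal(px$rows, c(3L, 4L))   # 0-based patch 3 covers pixels (2..3, 2..3)
  expect_equal(px$cols, c(3L, 4L))

  g64 <- segment_patches(c(6L, 4L), 2)
  expect_equal(g64$n_patches, 6L)
  expect_equal(c(g64$rows, g64$cols), c(3L, 2L))

  expect_error(segment_patches(c(5L, 4L), 2), "5x4")
  expect_error(patch_pixels(g4, 4), "out of range")

  # patches tile the image exactly once
  g <- segment_patches(c(8L, 6L), 2)
  seen <- matrix(0L, 8, 6)
  for (k in seq_len(g$n_patches) - 1L) {
    px <- patch_pixels(g, k)
    seen[px$rows, px$cols] <- seen[px$rows, px$cols] + 1L
  }
  expect_true(all(seen == 1L))
})

test_that("zero-strength filters leave the image untouched", {
  s <- flat_sample(0.5)
  grid <- segment_patches(s, 2)
  for (kind in c("gaussian_noise", "brightness", "blur")) {
    f <- distortion_filter(kind, noise_sd = 0, brightness = 0, blur_sd = 0,
                           seed = 1)
    st <- apply_distortion(perturbation_state(s, grid, f), 5L)
    expect_identical(st$current, s$pixels)
    expect_equal(st$counts[6], 1L)   # bookkeeping still advances
  }
})

test_that("brightness distortions clip and update D by hand arithmetic", {
  s <- flat_sample(0.8)
  grid <- segment_patches(s, 2)
  f <- distortion_filter("brightness", brightness = 0.5, seed = 1)
  st <- apply_distortion(perturbation_state(s, grid, f), 0L)
  px <- patch_pixels(grid, 0)
  expect_true(all(st$current[px$rows, px$cols, 1] == 1))   # 0.8 + 0.5 clipped
  # 4 pixels each moved 0.2: D = 0.2 * sqrt(4)
  expect_equal(state_distance(st), 0.2 * 2, tolerance = 1e-12)
  off <- st$current; off[px$rows, px$cols, 1] <- 0.8
  expect_identical(off, s$pixels)    # locality: nothing outside the patch
})

test_that("add/remove sequences replay to the original bit-exactly", {
  set.seed(12)
  s <- image_sample(array(stats::runif(64), c(8, 8, 1)), 0L)
  grid <- segment_patches(s, 2)
  f <- distortion_filter("gaussian_noise", noise_sd = 0.2, seed = 3)
  st0 <- perturbation_state(s, grid, f)

  st <- apply_distortion(st0, 7L)
  expect_identical(remove_distortion(st, 7L)$current, s$pixels)

  # LIFO: removing one of two stacked distortions recovers the middle state
  st1 <- apply_distortion(st0, 7L)
  st2 <- apply_distortion(st1, 7L)
  expect_identical(remove_distortion(st2, 7L)$current, st1$current)

  # matched random adds and removes cancel exactly
  st <- st0
  order_add <- sample(0:15, 10, replace = TRUE)
  for (k in order_add) st <- apply_distortion(st, k)
  for (k in rev(order_add)) st <- remove_distortion(st, k)
  expect_identical(st$current, s$pixels)
  expect_lte(state_distance(st), 1e-9)
  expect_error(remove_distortion(st, 0L), "none applied")
})

test_that("any operation sequence respects clipping, locality and D", {
  set.seed(13)
  s <- image_sample(array(stats::runif(64), c(8, 8, 1)), 0L)
  grid <- segment_patches(s, 2)
  for (f in list(distortion_filter("gaussian_noise", noise_sd = 5, seed = 2),
                 distortion_filter("brightness", brightness = -3, seed = 2),
                 distortion_filter("blur", blur_sd = 2, seed = 2))) {
    st <- perturbation_state(s, grid, f)
    for (i in 1:30) {
      dist <- distorted_patches(st)
      if (length(dist) > 0 && stats::runif(1) < 0.3) {
        st <- remove_distortion(st, dist[sample.int(length(dist), 1)])
      } else {
        st <- apply_distortion(st, sample.int(16, 1) - 1L)
      }
      expect_true(all(st$current >= 0 & st$current <= 1))
      # untouched patches remain pixel-identical to the original
      for (k in setdiff(0:15, distorted_patches(st))) {
        px <- patch_pixels(grid, k)
        expect_identical(st$current[px$rows, px$cols, ],
                         st$original[px$rows, px$cols, ])
      }
      expect_equal(state_distance(st),
                   sqrt(sum((st$current - st$original)^2)),
                   tolerance = 1e-6)
    }
  }
})

test_that("filter strength validation enforces the minimal-distortion bound", {
  s <- flat_sample(0.5, H = 16, W = 16)
  grid <- segment_patches(s, 2)
  expect_true(validate_filter_strength(
    distortion_filter("gaussian_noise", noise_sd = 0.1, seed = 1), s, grid))
  expect_error(validate_filter_strength(
    distortion_filter("brightness", brightness = 1, seed = 1), s, grid),
    "not minimal")
})

test_that("sensitivity maps satisfy their support and query contracts", {
  s <- flat_sample(0.5)
  grid <- segment_patches(s, 2)
  f <- distortion_filter("gaussian_noise", noise_sd = 0.1, seed = 4)

  # constant classifier: all sensitivities vanish
  bb_const <- as_blackbox(function(img) c(0.7, 0.3))
  st <- apply_distortion(perturbation_state(s, grid, f), 3L)
  sm <- compute_sensitivity(bb_const, st, gt_label = 0L, p_gt_current = 0.7)
  expect_true(all(sm$p_add == 0))
  expect_equal(sum(!is.na(sm$p_remove)), 1L)   # only the distorted patch
  expect_false(is.na(sm$p_remove[4]))
  expect_true(all(abs(sm$p_add) <= 1, na.rm = TRUE))

  # exact query budget: one call per patch plus one per distorted patch
  counter <- as_blackbox(function(img) c(0.5, 0.5))
  invisible(compute_sensitivity(counter, st, 0L, p_gt_current = 0.5))
  expect_equal(query_count(counter), grid$n_patches + 1L)
})

test_that("sensitivity ranking matches the analytic linear-model oracle", {
  set.seed(14)
  w <- matrix(stats::rnorm(64, sd = 0.4), 8, 8)
  bbl <- as_blackbox(linear_pixel_classifier(w))
  s <- flat_sample(0.5, label = 1L)
  grid <- segment_patches(s, 2)
  f <- distortion_filter("brightness", brightness = 0.05, seed = 5)
  st <- perturbation_state(s, grid, f)
  p1 <- stats::plogis(sum(w * 0.5))
  sm <- compute_sensitivity(bbl, st, gt_label = 1L, p_gt_current = p1)
  # brute-force oracle: brightness +c adds c * (sum of patch weights) to the
  # logit; P_GT for class 1 increases monotonically with that sum, so the
  # drop in P_GT ranks patches in reverse order of their weight sums
  wsum <- vapply(seq_len(grid$n_patches) - 1L, function(k) {
    px <- patch_pixels(grid, k)
    sum(w[px$rows, px$cols])
  }, numeric(1))
  expect_equal(order(sm$p_add), order(-wsum))
})
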