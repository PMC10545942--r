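test_that("median background handles identical and odd-count stacks exactly", {
  f <- matrix(runif(20 * 20), 20, 20)
  bg <- median_background(list(f, f, f, f, f))
  expect_equal(bg$pixels, f)
  expect_equal(bg$update_weight, 0)

  stack <- list(matrix(0.1, 2, 2), matrix(0.9, 2, 2), matrix(0.1, 2, 2))
  expect_equal(median_background(stack)$pixels, matrix(0.1, 2, 2))
  expect_error(median_background(list()), "at least one")
  expect_error(median_background(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "identical dimensions")
})

test_that("median background equals a brute-force per-pixel sort", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(2:9, 1)
    frames <- lapply(seq_len(n), function(i) matrix(runif(6 * 5), 6, 5))
    expect_equal(median_background(frames)$pixels, oracle_median_stack(frames))
  }
})

test_that("median background recovers the true background under a moving animal", {
  spec <- arena_spec(64, 64, "bright_on_dark", background_level = 0.2,
                    noise_sigma = 0.01)
  sim <- make_arena(spec, list(animal_spec(1, target_area = 60, speed = 3)),
                    n_frames = 101, seed = 10)
  bg <- median_background(sim$frames)
  expect_lt(max(abs(bg$pixels - 0.2)), 2 / 255)
})

test_that("background update blends geometrically toward the frame", {
  f0 <- matrix(0, 8, 8)
  target <- matrix(1, 8, 8)
  model <- median_background(list(f0))
  expect_equal(update_background(model, target, 0)$pixels, f0)
  expect_equal(update_background(model, target, 1)$pixels, target)
  m <- model
  err <- max(abs(m$pixels - target))
  for (i in 1:5) {
    m <- update_background(m, target, 0.1)
    new_err <- max(abs(m$pixels - target))
    expect_equal(new_err, err * 0.9, tolerance = 1e-12)
    err <- new_err
  }
  expect_error(update_background(model, matrix(0, 3, 3), 0.5), "dimensions")
})

test_that("subtraction is absolute difference and polarity-symmetric", {
  bg <- matrix(0.5, 4, 4)
  model <- median_background(list(bg))
  expect_equal(subtract_background(bg, model), matrix(0, 4, 4))
  f <- matrix(0.2, 4, 4)
  expect_equal(subtract_background(f, model), matrix(0.3, 4, 4))
  dark <- bg; dark[2, 2] <- 0.5 - 0.3
  bright <- bg; bright[2, 2] <- 0.5 + 0.3
  expect_equal(subtract_background(dark, model), subtract_background(bright, model))
})

test_that("masking keeps positive-mask pixels and is idempotent", {
  img <- matrix(runif(16), 4, 4)
  expect_equal(apply_mask(img, matrix(1, 4, 4)), img)
  expect_equal(apply_mask(img, matrix(0, 4, 4)), matrix(0, 4, 4))
  half <- matrix(rep(c(1, 0), each = 8), 4, 4)
  out <- apply_mask(img, half)
  expect_true(all(out[half == 0] == 0))
  expect_equal(out[half > 0], img[half > 0])
  expect_equal(apply_mask(out, half), out)
})

test_that("thresholding is strict and monotone in the threshold", {
  expect_false(binarize(matrix(0.05), 0.08)[1, 1])
  expect_true(binarize(matrix(0.15), 0.08)[1, 1])
  expect_false(any(binarize(matrix(runif(100), 10, 10), 1)))
  expect_false(binarize(matrix(0.08), 0.08)[1, 1])  # strict >
  set.seed(42)
  for (rep in 1:100) {
    g <- matrix(runif(64), 8, 8)
    thr <- sort(runif(5))
    counts <- vapply(thr, function(t) sum(binarize(g, t)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("cluster labeling gates by area and uses 8-connectivity", {
  img <- matrix(FALSE, 30, 40)
  img[5:10, 5:14] <- TRUE            # 60 px blob
  img[20:21, 30:34] <- TRUE          # 10 px speck
  params <- segmentation_params(0.1, min_area = 30, max_area = 120)
  cl <- label_clusters(img, params, frame_index = 1, time_s = 0)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$area, 60L)
  expect_equal(cl$frame, 1L)

  # diagonal contact joins components (8-connectivity)
  diagonal <- matrix(FALSE, 6, 6)
  diagonal[2, 2] <- TRUE
  diagonal[3, 3] <- TRUE
  cl2 <- label_clusters(diagonal, segmentation_params(0.1, 1, Inf))
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$area, 2L)

  expect_equal(nrow(label_clusters(matrix(FALSE, 5, 5), params)), 0)
})

test_that("two touching blobs above max_area are rejected as one component", {
  img <- matrix(FALSE, 20, 40)
  img[6:10, 5:17] <- TRUE            # 65 px
  img[6:10, 18:30] <- TRUE           # 65 px, touching: one 130-px component
  expect_equal(length(oracle_flood_components(img)), 1)
  cl <- label_clusters(img, segmentation_params(0.1, 30, 120))
  expect_equal(nrow(cl), 0)
})

test_that("labeling agrees with a brute-force flood fill on random images", {
  set.seed(43)
  for (rep in 1:50) {
    img <- matrix(runif(15 * 12) < 0.3, 12, 15)
    comps <- oracle_flood_components(img)
    cl <- label_clusters(img, segmentation_params(0.1, 1, Inf))
    expect_equal(nrow(cl), length(comps))
    expect_setequal(cl$area, lengths(comps))
  }
})

test_that("cluster measurement matches its definitions on canonical shapes", {
  single <- measure_cluster(cbind(x = 4, y = 7))
  expect_equal(single$x, 4)
  expect_equal(single$y, 7)
  expect_equal(single$area, 1L)
  expect_equal(single$length, 1)

  bar <- measure_cluster(cbind(x = 0:4, y = rep(2, 5)))
  expect_equal(bar$area, 5L)
  expect_equal(bar$length, 5)
  expect_equal(bar$orientation, 0)

  expect_error(measure_cluster(cbind(x = numeric(0), y = numeric(0))), "Empty")
})

test_that("measured orientation and length recover a rasterised ellipse", {
  for (angle in c(0, 0.4, 1.1, 2.4)) {
    # sub-pixel centre: a lattice-aligned centre maximises rasterisation bias
    px <- ellipse_pixels(20.3, 20.7, a = 4.5, b = 1.5, theta = angle,
                         width = 40, height = 40)
    m <- measure_cluster(cbind(px$x, px$y))
    ang_err <- min(abs(m$orientation - angle %% pi),
                   pi - abs(m$orientation - angle %% pi))
    expect_lt(ang_err, 0.05)
    expect_lt(abs(m$length - 9), 1)
    # brute-force projection oracle at the measured angle
    proj <- px$x * cos(m$orientation) + px$y * sin(m$orientation)
    expect_equal(m$length, diff(range(proj)) + 1)
  }
})

test_that("measurement agrees with exhaustive projection on random pixel sets", {
  set.seed(44)
  for (rep in 1:50) {
    n <- sample(2:30, 1)
    px <- cbind(x = sample(0:15, n, replace = TRUE),
                y = sample(0:15, n, replace = TRUE))
    px <- unique(px)
    m <- measure_cluster(px)
    expect_equal(m$x, mean(px[, 1]))
    expect_equal(m$y, mean(px[, 2]))
    expect_equal(m$area, nrow(px))
    # the reported axis maximises projected variance (principal axis)
    angles <- seq(0, pi, length.out = 361)
    vars <- vapply(angles, function(a) {
      var(px[, 1] * cos(a) + px[, 2] * sin(a)) * (nrow(px) - 1) / nrow(px)
    }, numeric(1))
    v_m <- var(px[, 1] * cos(m$orientation) + px[, 2] * sin(m$orientation)) *
      (nrow(px) - 1) / nrow(px)
    expect_gte(v_m + 1e-9, max(vars) * 0.999)
  }
})

test_that("segmentation recovers disjoint animals exactly on noise-free frames", {
  spec <- arena_spec(200, 200, "dark_on_light", noise_sigma = 0)
  animals <- lapply(1:4, function(i) animal_spec(i, target_area = 60, speed = 2))
  sim <- make_arena(spec, animals, n_frames = 15, seed = 12)
  bg <- matrix(spec$background_level, 200, 200)
  for (f in 1:15) {
    d <- subtract_background(frame_at(sim$frames, f), bg)
    cl <- label_clusters(binarize(d, 0.15), segmentation_params(0.15, 10, 200), f)
    gt <- dplyr::filter(sim$ground_truth, frame == f)
    expect_equal(nrow(cl), sum(gt$visible))
    m <- match_min_cost(outer(seq_len(nrow(gt)), seq_len(nrow(cl)), function(i, j) {
      sqrt((gt$x[i] - cl$x[j])^2 + (gt$y[i] - cl$y[j])^2)
    }))
    expect_true(all(sqrt((gt$x - cl$x[m])^2 + (gt$y - cl$y[m])^2) <= 0.5))
    expect_true(all(abs(cl$area[m] - gt$area) / gt$area <= 0.05))
  }
})
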