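mk_track <- function(xs, ys, areas, lens, frames = seq_along(xs),
                     merged = rep(FALSE, length(xs)), id = 1L) {
  list(id = id, xs = xs, ys = ys, areas = areas, lens = lens, frames = frames,
       merged_flags = merged, mean_area = mean(areas[!merged]),
       mean_length = mean(lens[!merged]), last_frame = frames[length(frames)],
       merged = merged[length(merged)])
}

mk_cluster <- function(x, y, area, length, frame = NA_integer_, label = 1L) {
  tibble::tibble(frame = frame, label = label, x = x, y = y,
                 area = as.integer(area), length = length, orientation = 0,
                 x0 = 0L, y0 = 0L, x1 = 1L, y1 = 1L, time_s = frame / 30)
}

test_that("assignment cost is zero at the prediction and gates on distance", {
  p <- tracker_params(max_move = 10)
  tr <- mk_track(xs = c(0, 2), ys = c(0, 0), areas = c(60, 60), lens = c(12, 12))
  # predicted position: (4, 0)
  perfect <- mk_cluster(4, 0, 60, 12, frame = 3)
  expect_equal(assignment_cost(tr, perfect, p), 0)

  far <- mk_cluster(4 + 20, 0, 60, 12, frame = 3)  # distance 2 x max_move, gap 1
  expect_identical(assignment_cost(tr, far, p), Inf)

  # default weights: d = max_move/2 and area off by 50% -> cost 1.0
  half <- mk_cluster(4, 5, 90, 12, frame = 3)
  expect_equal(assignment_cost(tr, half, p), 1.0)
})

test_that("step matching equals exhaustive minimum-cost search", {
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(1:5, 1)
    m <- sample(1:5, 1)
    cost <- matrix(runif(n * m, 0, 10), n, m)
    cost[matrix(runif(n * m) < 0.35, n, m)] <- Inf
    sol <- match_min_cost(cost)
    got <- matching_card_cost(cost, sol)
    want <- oracle_best_matching(cost)
    expect_equal(got$cardinality, want$cardinality)
    expect_equal(got$cost, want$cost, tolerance = 1e-9)
  }
})

test_that("a matched track resets its inactivity and an unreachable cluster births", {
  p <- tracker_params(max_move = 10, min_active = 1, max_inactive = 3)
  st <- new_tracker(p)
  st <- tracker_step(st, mk_cluster(50, 50, 60, 12, frame = 1))
  st <- tracker_step(st, mk_cluster(52, 50, 60, 12, frame = 2))
  tr <- st$tracks[[1]]
  expect_equal(tr$status, "active")
  expect_equal(tr$inactive_count, 0L)
  expect_equal(length(tr$xs), 2)

  # a cluster far beyond the gate: new track, existing track goes inactive
  st <- tracker_step(st, mk_cluster(150, 150, 60, 12, frame = 3, label = 1L))
  expect_equal(length(st$tracks), 2)
  expect_equal(st$tracks[[1]]$inactive_count, 1L)
  expect_equal(st$last_assignment$births, 1L)
  expect_equal(st$last_assignment$misses, 1L)
})

test_that("track lifecycle boundaries are exact", {
  # unmatched for exactly max_inactive frames survives; one more archives
  p <- tracker_params(max_move = 10, min_active = 1, max_inactive = 2)
  st <- new_tracker(p)
  st <- tracker_step(st, mk_cluster(50, 50, 60, 12, frame = 1))
  empty <- label_clusters(matrix(FALSE, 4, 4), segmentation_params(0.1, 1, Inf))
  st <- tracker_step(st, empty)   # inactive_count 1
  st <- tracker_step(st, empty)   # inactive_count 2 == max_inactive: survives
  expect_equal(st$tracks[[1]]$status, "inactive")
  expect_equal(st$tracks[[1]]$inactive_count, 2L)
  st <- tracker_step(st, empty)   # 3 > max_inactive: archived
  expect_equal(st$tracks[[1]]$status, "archived")

  # min_active boundary: provisional until exactly min_active consecutive matches
  p2 <- tracker_params(max_move = 10, min_active = 3, max_inactive = 2)
  st2 <- new_tracker(p2)
  st2 <- tracker_step(st2, mk_cluster(10, 10, 60, 12, frame = 1))
  expect_equal(st2$tracks[[1]]$status, "provisional")
  st2 <- tracker_step(st2, mk_cluster(11, 10, 60, 12, frame = 2))
  expect_equal(st2$tracks[[1]]$status, "provisional")
  st2 <- tracker_step(st2, mk_cluster(12, 10, 60, 12, frame = 3))
  expect_equal(st2$tracks[[1]]$status, "active")
  # the provisional prefix is emitted once activated
  tt <- track_table(st2)
  expect_equal(tt$frame, 1:3)
  expect_equal(tt$status, c("provisional", "provisional", "active"))
})

test_that("tracks that never activate are suppressed from the table", {
  p <- tracker_params(max_move = 10, min_active = 3, max_inactive = 2)
  st <- new_tracker(p)
  st <- tracker_step(st, mk_cluster(10, 10, 60, 12, frame = 1))
  empty <- label_clusters(matrix(FALSE, 4, 4), segmentation_params(0.1, 1, Inf))
  st <- tracker_step(st, empty)
  expect_equal(nrow(track_table(st)), 0)
})

test_that("split resolution uses frozen mean features to retain identity", {
  p <- tracker_params(max_move = 20)
  small <- mk_track(xs = c(100, 100), ys = c(100, 100), areas = c(60, 60),
                    lens = c(12, 12), merged = c(FALSE, TRUE), id = 1L)
  big <- mk_track(xs = c(100, 100), ys = c(100, 100), areas = c(120, 120),
                  lens = c(18, 18), merged = c(FALSE, TRUE), id = 2L)
  small$mean_area <- 60; small$mean_length <- 12
  big$mean_area <- 120; big$mean_length <- 18
  clusters <- dplyr::bind_rows(
    mk_cluster(95, 100, 58, 12, frame = 3, label = 1L),
    mk_cluster(105, 100, 125, 18, frame = 3, label = 2L))
  res <- resolve_split(list(small, big), clusters, p)
  expect_equal(res$label[res$track_id == 2], 2L)   # larger track takes 125 px
  expect_equal(res$label[res$track_id == 1], 1L)

  # degenerate features: assignment falls back to distance
  a <- mk_track(xs = c(90, 92), ys = c(100, 100), areas = c(60, 60),
                lens = c(12, 12), id = 3L)
  b <- mk_track(xs = c(110, 108), ys = c(100, 100), areas = c(60, 60),
                lens = c(12, 12), id = 4L)
  cl2 <- dplyr::bind_rows(
    mk_cluster(96, 100, 60, 12, frame = 3, label = 1L),
    mk_cluster(104, 100, 60, 12, frame = 3, label = 2L))
  res2 <- resolve_split(list(a, b), cl2, p)
  expect_equal(res2$label[res2$track_id == 3], 1L)
  expect_equal(res2$label[res2$track_id == 4], 2L)
})

test_that("three-way splits equal the brute-force permutation optimum", {
  set.seed(52)
  p <- tracker_params(max_move = 50)
  for (rep in 1:50) {
    tracks <- lapply(1:3, function(i) {
      mk_track(xs = runif(1, 40, 60), ys = runif(1, 40, 60),
               areas = sample(40:140, 1), lens = runif(1, 10, 25), id = i)
    })
    clusters <- dplyr::bind_rows(lapply(1:3, function(j) {
      mk_cluster(runif(1, 40, 60), runif(1, 40, 60), sample(40:140, 1),
                 runif(1, 10, 25), frame = 2, label = j)
    }))
    cost <- matrix(Inf, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      cost[i, j] <- assignment_cost(tracks[[i]], clusters[j, ], p)
    }
    res <- resolve_split(tracks, clusters, p)
    got <- sum(res$cost)
    want <- oracle_best_matching(cost)
    expect_equal(nrow(res), want$cardinality)
    expect_equal(got, want$cost, tolerance = 1e-9)
  }
})

test_that("clusters are conserved through every tracker step", {
  spec <- arena_spec(160, 160, "bright_on_dark", noise_sigma = 0.01)
  animals <- lapply(1:3, function(i) animal_spec(i, target_area = 60, speed = 2))
  sim <- make_arena(spec, animals, n_frames = 60, seed = 13)
  tt <- track_animals(sim$frames, segmentation_params(0.15, 20, 120),
                      tracker_params(max_move = 8, min_active = 3,
                                     max_inactive = 10))
  for (a in attr(tt, "log")) {
    accounted <- nrow(a$matches) + length(unique(a$merges$label)) +
      length(a$births) + length(a$dropped)
    expect_equal(a$n_clusters, accounted)
  }
})

test_that("disjoint animals are tracked with full identity preservation", {
  spec <- arena_spec(240, 240, "bright_on_dark", noise_sigma = 0.01)
  animals <- lapply(1:4, function(i) animal_spec(i, target_area = 60, speed = 2))
  sim <- make_arena(spec, animals, n_frames = 100, seed = 14)
  tt <- track_animals(sim$frames, segmentation_params(0.15, 20, 120),
                      tracker_params(max_move = 8, min_active = 3,
                                     max_inactive = 10))
  expect_equal(length(unique(tt$track_id)), 4)
  expect_equal(identity_preservation(tt, sim$ground_truth, max_move = 8), 100)
})

test_that("tracking a video with no animals yields an empty table", {
  spec <- arena_spec(64, 64, "bright_on_dark", noise_sigma = 0.005)
  sim <- make_arena(spec, list(), n_frames = 20, seed = 15)
  tt <- track_animals(sim$frames, segmentation_params(0.15, 10, 120),
                      tracker_params(max_move = 8))
  expect_equal(nrow(tt), 0)
})

test_that("tracking is deterministic for fixed inputs", {
  spec <- arena_spec(120, 120, "bright_on_dark", noise_sigma = 0.01)
  animals <- lapply(1:2, function(i) animal_spec(i, target_area = 50, speed = 2))
  sim <- make_arena(spec, animals, n_frames = 40, seed = 16)
  seg <- segmentation_params(0.15, 15, 110)
  trk <- tracker_params(max_move = 8, min_active = 3, max_inactive = 5)
  t1 <- track_animals(sim$frames, seg, trk)
  t2 <- track_animals(sim$frames, seg, trk)
  attributes(t1) <- attributes(t1)[c("names", "class", "row.names")]
  attributes(t2) <- attributes(t2)[c("names", "class", "row.names")]
  expect_identical(t1, t2)
})

test_that("identity survives a two-animal collision with distinct sizes", {
  scn <- collision_scenario(seed = 3)
  expect_equal(length(unique(scn$tracks$track_id)), 2)
  expect_equal(post_split_identity(scn), 100)
})
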