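#' Tracker parameters
#'
#' @param max_move Maximum acceptable movement per frame, in pixels. A
#'   cluster farther than `max_move * gap` from a track's predicted position
#'   (where `gap` is the number of frames since the track was last observed)
#'   can never be assigned to it.
#' @param min_active Minimum number of consecutive matched frames before a
#'   provisional track is recognised as active (noise suppression).
#' @param max_inactive Maximum number of frames a track may remain unmatched;
#'   one more frame archives it.
#' @param feature_weight_area,feature_weight_length,distance_weight
#'   Non-negative weights of the assignment cost terms; not all zero.
#' @param merge_area Cluster area (pixels) above which an unmatched cluster
#'   is treated as a merge of several animals rather than a new track. The
#'   pipeline sets this from the segmentation `max_area`.
#' @return A `tracker_params` object.
#' @export
tracker_params <- function(max_move, min_active = 3L, max_inactive = 5L,
                           feature_weight_area = 1, feature_weight_length = 1,
                           distance_weight = 1, merge_area = Inf) {
  stopifnot_scalar_num(max_move, "max_move")
  if (max_move <= 0) abort("`max_move` must be positive.")
  if (min_active < 1) abort("`min_active` must be >= 1.")
  if (max_inactive < 0) abort("`max_inactive` must be >= 0.")
  w <- c(feature_weight_area, feature_weight_length, distance_weight)
  if (any(w < 0) || all(w == 0)) {
    abort("Cost weights must be >= 0 and not all zero.")
  }
  structure(list(max_move = max_move, min_active = as.integer(min_active),
                 max_inactive = as.integer(max_inactive),
                 feature_weight_area = feature_weight_area,
                 feature_weight_length = feature_weight_length,
                 distance_weight = distance_weight, merge_area = merge_area),
            class = "tracker_params")
}

# ---- minimum-cost one-to-one matching -------------------------------------

# Jonker-Volgenant style shortest-augmenting-path assignment for a square
# finite cost matrix; returns, for each row, the assigned column. O(n^3).
solve_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}

# Min-cost matching over feasible pairs of a (possibly rectangular) cost
# matrix that may contain Inf (infeasible). Among matchings of maximum
# cardinality the total cost is minimised. Returns an integer vector: for
# each row the matched column, or NA.
match_min_cost <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  finite <- cost[is.finite(cost)]
  if (length(finite) == 0) return(rep(NA_integer_, n))
  big <- sum(finite) + 1
  s <- n + m
  M <- matrix(3 * big, s, s)
  M[seq_len(n), seq_len(m)] <- pmin(cost, 3 * big)
  for (i in seq_len(n)) M[i, m + i] <- big          # row unmatched
  for (j in seq_len(m)) M[n + j, j] <- big          # column unmatched
  # dummy-dummy block free, so a zero-cost perfect completion always exists
  M[(n + 1):s, (m + 1):s] <- 0
  sol <- solve_assignment(M)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && is.finite(cost[i, j])) out[i] <- j
  }
  out
}

# ---- track state ----------------------------------------------------------

new_track <- function(id, cluster, frame, time_s, status = "provisional") {
  list(id = id, status = status,
       frames = frame, times = time_s, xs = cluster$x, ys = cluster$y,
       areas = cluster$area, lens = cluster$length,
       merged_flags = FALSE, statuses = status,
       mean_area = cluster$area, mean_length = cluster$length, n_feat = 1L,
       active_count = 1L, inactive_count = 0L, merged = FALSE,
       last_frame = frame)
}

# constant-velocity prediction: last position plus the last per-frame
# displacement, extrapolated over `gap` frames; falls back to the last
# position for single-observation tracks
track_predict <- function(tr, gap = 1) {
  k <- length(tr$xs)
  # displacements touching a merged observation measure the blob-centroid
  # jump, not animal motion; fall back to the last position there
  if (k >= 2 && !tr$merged_flags[k] && !tr$merged_flags[k - 1]) {
    df <- tr$frames[k] - tr$frames[k - 1]
    vx <- (tr$xs[k] - tr$xs[k - 1]) / df
    vy <- (tr$ys[k] - tr$ys[k - 1]) / df
    c(tr$xs[k] + gap * vx, tr$ys[k] + gap * vy)
  } else {
    c(tr$xs[k], tr$ys[k])
  }
}

track_cost <- function(tr, cl, params, frame) {
  gap <- frame - tr$last_frame
  pred <- track_predict(tr, gap)
  d <- sqrt((pred[1] - cl$x)^2 + (pred[2] - cl$y)^2)
  # while merged (or against a merge-sized cluster) the blob centroid is not
  # the animal's position: widen the gate by the blob's semi-length so the
  # centroid jump at merge formation and split stays feasible
  slack <- 0
  if (isTRUE(tr$merged)) slack <- slack + tail(tr$lens, 1) / 2
  if (cl$area > params$merge_area) slack <- slack + cl$length / 2
  if (d > params$max_move * gap + slack) return(Inf)
  params$distance_weight * (d / params$max_move) +
    params$feature_weight_area * abs(cl$area - tr$mean_area) / tr$mean_area +
    params$feature_weight_length * abs(cl$length - tr$mean_length) / tr$mean_length
}

#' Assignment cost between a track and a cluster
#'
#' The gating-and-cost function of the identity model. A cluster is
#' infeasible for a track when its centroid lies farther than
#' `max_move * gap` from the track's predicted position (last position plus
#' last displacement — a one-step constant-velocity prediction). Otherwise
#' the cost combines normalised distance with relative deviations from the
#' track's temporal mean area and primary-axis length:
#' `distance_weight * d / max_move +
#'  feature_weight_area * |area - mean_area| / mean_area +
#'  feature_weight_length * |length - mean_length| / mean_length`.
#'
#' @param track A track as found in a tracker state (see [new_tracker()]),
#'   or a list with numeric fields `xs`, `ys`, `mean_area`, `mean_length`,
#'   `last_frame`.
#' @param cluster One cluster row (list or one-row tibble with `x`, `y`,
#'   `area`, `length`, and optionally `frame`).
#' @param params [tracker_params()].
#' @return The cost (non-negative scalar), or `Inf` when infeasible.
#' @export
assignment_cost <- function(track, cluster, params) {
  if (length(track$xs) < 1) abort("Track has no observations.")
  frame <- if (!is.null(cluster$frame) && !is.na(cluster$frame[1])) {
    cluster$frame[1]
  } else {
    track$last_frame + 1L
  }
  track_cost(track, as.list(cluster), params, frame)
}

#' Create an empty tracker state
#'
#' The tracker is advanced one frame at a time with [tracker_step()]; at any
#' point [track_table()] extracts the history of all tracks that reached
#' active status.
#'
#' @param params [tracker_params()].
#' @return A `tracker` state object.
#' @export
new_tracker <- function(params) {
  if (!inherits(params, "tracker_params")) abort("`params` must be tracker_params.")
  structure(list(params = params, tracks = list(), next_id = 1L,
                 last_frame = -Inf, log = list()),
            class = "tracker")
}

#' Advance the tracker by one frame
#'
#' Implements the per-frame association step:
#' 1. feasible track-to-cluster costs are computed with [assignment_cost()];
#' 2. a globally minimum-total-cost one-to-one matching is solved over the
#'    feasible pairs (optimal, not greedy);
#' 3. clusters larger than `merge_area`, and clusters that are the unique
#'    feasible target of at least two otherwise-unmatched tracks, are treated
#'    as merges: all those tracks attach to the cluster, are flagged merged,
#'    and their running means freeze so the collision blob cannot corrupt the
#'    identity features;
#' 4. remaining unmatched clusters start new provisional tracks;
#' 5. unmatched tracks keep their last position, increment their inactivity
#'    count, and are archived once it exceeds `max_inactive` (provisional
#'    tracks are discarded on their first miss);
#' 6. provisional tracks matched `min_active` consecutive frames become
#'    active;
#' 7. matched tracks update history and running means; a previously merged
#'    track that wins a one-to-one match has its merged flag cleared (the
#'    split resolution).
#'
#' @param state A `tracker` state.
#' @param clusters Cluster tibble for one frame (from [label_clusters()]);
#'   all rows must share the same `frame`, later than any frame already
#'   processed.
#' @return The updated `tracker` state; the per-frame [assignment] record is
#'   available as `state$last_assignment` and appended to `state$log`.
#' @export
tracker_step <- function(state, clusters) {
  if (!inherits(state, "tracker")) abort("`state` must be a tracker.")
  params <- state$params
  nc <- nrow(clusters)
  if (nc > 0) {
    fr <- unique(clusters$frame)
    if (length(fr) != 1) abort("Clusters must all come from the same frame.")
    frame <- fr
    time_s <- clusters$time_s[1]
  } else {
    frame <- if (is.finite(state$last_frame)) state$last_frame + 1L else 1L
    time_s <- NA_real_
  }
  if (frame <= state$last_frame) {
    abort("Clusters must be from a frame later than all track observations.")
  }

  open_idx <- which(vapply(state$tracks, function(t) t$status != "archived",
                           logical(1)))
  nt <- length(open_idx)
  cl_list <- if (nc > 0) lapply(seq_len(nc), function(j) as.list(clusters[j, ])) else list()
  oversize <- if (nc > 0) clusters$area > params$merge_area else logical(0)

  # full feasibility/cost matrix (tracks x clusters)
  cost <- matrix(Inf, nt, nc)
  if (nt > 0 && nc > 0) {
    for (a in seq_len(nt)) {
      tr <- state$tracks[[open_idx[a]]]
      for (j in seq_len(nc)) {
        cost[a, j] <- track_cost(tr, cl_list[[j]], params, frame)
      }
    }
  }

  # one-to-one matching over normal-size clusters
  normal <- which(!oversize)
  match_of_track <- rep(NA_integer_, nt)
  if (nt > 0 && length(normal) > 0) {
    sub <- cost[, normal, drop = FALSE]
    sol <- match_min_cost(sub)
    match_of_track <- ifelse(is.na(sol), NA_integer_, normal[sol])
  }

  matched_cl <- stats::na.omit(match_of_track)
  unmatched_tracks <- which(is.na(match_of_track))

  # merge resolution
  merge_members <- vector("list", nc)  # track indices (into open_idx) per cluster
  if (nt > 0 && nc > 0) {
    # (a) oversize clusters attract every feasible unmatched track
    for (j in which(oversize)) {
      feas <- unmatched_tracks[is.finite(cost[unmatched_tracks, j])]
      if (length(feas) > 0) merge_members[[j]] <- feas
    }
    # (b) a cluster that is the unique feasible target of >= 2 otherwise-
    # unmatched tracks becomes a merge; if it was matched one-to-one, the
    # matched track joins the merge (its means freeze too)
    for (j in seq_len(nc)) {
      if (oversize[j]) next
      um <- setdiff(unmatched_tracks, unlist(merge_members))
      uniq <- um[vapply(um, function(a) {
        feas <- which(is.finite(cost[a, ]))
        length(feas) == 1 && feas == j
      }, logical(1))]
      owner <- which(match_of_track == j)
      if (length(uniq) + length(owner) >= 2 && length(uniq) >= 1) {
        merge_members[[j]] <- c(owner, uniq)
        if (length(owner) > 0) match_of_track[owner] <- NA_integer_
      }
    }
  }
  merged_tracks_now <- unlist(merge_members)
  unmatched_tracks <- setdiff(which(is.na(match_of_track)), merged_tracks_now)

  merge_target_cl <- which(lengths(merge_members) > 0)
  birth_cl <- setdiff(which(!oversize), c(stats::na.omit(match_of_track),
                                          merge_target_cl))
  dropped_cl <- setdiff(which(oversize), merge_target_cl)

  # ---- apply updates ----
  tracks <- state$tracks
  append_obs <- function(tr, cl, merged_flag) {
    tr$frames <- c(tr$frames, frame)
    tr$times <- c(tr$times, time_s)
    tr$xs <- c(tr$xs, cl$x)
    tr$ys <- c(tr$ys, cl$y)
    tr$areas <- c(tr$areas, cl$area)
    tr$lens <- c(tr$lens, cl$length)
    tr$merged_flags <- c(tr$merged_flags, merged_flag)
    tr$last_frame <- frame
    tr$inactive_count <- 0L
    tr$active_count <- tr$active_count + 1L
    if (!merged_flag) {
      tr$mean_area <- (tr$mean_area * tr$n_feat + cl$area) / (tr$n_feat + 1L)
      tr$mean_length <- (tr$mean_length * tr$n_feat + cl$length) / (tr$n_feat + 1L)
      tr$n_feat <- tr$n_feat + 1L
    }
    tr
  }

  for (a in seq_len(nt)) {
    ti <- open_idx[a]
    j <- match_of_track[a]
    if (!is.na(j)) {
      tr <- append_obs(tracks[[ti]], cl_list[[j]], FALSE)
      tr$merged <- FALSE
      if (tr$status == "provisional" && tr$active_count >= params$min_active) {
        tr$status <- "active"
      } else if (tr$status == "inactive") {
        tr$status <- "active"
      }
      tr$statuses <- c(tr$statuses, tr$status)
      tracks[[ti]] <- tr
    } else if (a %in% merged_tracks_now) {
      j2 <- which(vapply(merge_members, function(mm) a %in% mm, logical(1)))[1]
      tr <- append_obs(tracks[[ti]], cl_list[[j2]], TRUE)
      tr$merged <- TRUE
      if (tr$status == "inactive") tr$status <- "active"
      tr$statuses <- c(tr$statuses, tr$status)
      tracks[[ti]] <- tr
    } else {
      tr <- tracks[[ti]]
      if (tr$status == "provisional") {
        tr$status <- "archived"   # never activated: discarded as noise
        tr$never_active <- TRUE
      } else {
        tr$inactive_count <- tr$inactive_count + 1L
        tr$active_count <- 0L
        tr$status <- if (tr$inactive_count > params$max_inactive) "archived"
                     else "inactive"
      }
      tracks[[ti]] <- tr
    }
  }

  birth_ids <- integer(0)
  for (j in birth_cl) {
    id <- state$next_id
    status0 <- if (params$min_active <= 1L) "active" else "provisional"
    tracks[[length(tracks) + 1]] <- new_track(id, cl_list[[j]], frame, time_s,
                                              status = status0)
    birth_ids <- c(birth_ids, id)
    state$next_id <- id + 1L
  }

  ids_of <- function(aidx) {
    vapply(aidx, function(a) tracks[[open_idx[a]]]$id, integer(1))
  }
  assignment <- list(
    frame = frame,
    matches = tibble(track_id = ids_of(which(!is.na(match_of_track))),
                     label = clusters$label[stats::na.omit(match_of_track)] %||% integer(0)),
    merges = if (length(merge_target_cl) > 0) {
      dplyr::bind_rows(lapply(merge_target_cl, function(j) {
        tibble(label = clusters$label[j], track_id = ids_of(merge_members[[j]]))
      }))
    } else tibble(label = integer(), track_id = integer()),
    births = if (length(birth_cl)) clusters$label[birth_cl] else integer(0),
    misses = ids_of(unmatched_tracks),
    dropped = if (length(dropped_cl)) clusters$label[dropped_cl] else integer(0),
    n_clusters = nc
  )
  class(assignment) <- "assignment"

  state$tracks <- tracks
  state$last_frame <- frame
  state$last_assignment <- assignment
  state$log[[length(state$log) + 1]] <- assignment
  state
}

#' Resolve a merge split by feature-based matching
#'
#' When a merged blob separates into several clusters, the tracks that were
#' attached to it are re-assigned by minimum-total-cost matching using
#' [assignment_cost()] with their frozen temporal mean area and length — the
#' time-independent characteristics that retain identity through collisions.
#' [tracker_step()] performs this automatically; this function exposes the
#' matching on its own.
#'
#' @param merged_tracks List of tracks (as in a tracker state) currently
#'   attached to one merged cluster.
#' @param new_clusters Cluster tibble of the candidate post-split clusters.
#' @param params [tracker_params()].
#' @return A tibble with columns `track_id`, `label`, `cost` (matched pairs
#'   only; unmatched tracks stay merged).
#' @export
resolve_split <- function(merged_tracks, new_clusters, params) {
  nt <- length(merged_tracks)
  nc <- nrow(new_clusters)
  cost <- matrix(Inf, nt, nc)
  for (a in seq_len(nt)) {
    for (j in seq_len(nc)) {
      cost[a, j] <- assignment_cost(merged_tracks[[a]], new_clusters[j, ], params)
    }
  }
  sol <- match_min_cost(cost)
  keep <- which(!is.na(sol))
  tibble(
    track_id = vapply(keep, function(a) merged_tracks[[a]]$id, integer(1)),
    label = new_clusters$label[sol[keep]],
    cost = cost[cbind(keep, sol[keep])]
  )
}

#' Extract the track table from a tracker state
#'
#' Returns the full history (including the provisional prefix) of every track
#' that ever reached active status. Tracks that never activated are treated
#' as noise and omitted.
#'
#' @param state A `tracker` state.
#' @return A tibble with columns `frame`, `time_s`, `track_id`, `x`, `y`,
#'   `area`, `length`, `merged`, `status`, sorted by frame then track id.
#' @export
track_table <- function(state) {
  keep <- Filter(function(t) "active" %in% t$statuses, state$tracks)
  if (length(keep) == 0) return(empty_track_table())
  out <- dplyr::bind_rows(lapply(keep, function(t) {
    tibble(frame = as.integer(t$frames), time_s = t$times, track_id = t$id,
           x = t$xs, y = t$ys, area = as.integer(t$areas), length = t$lens,
           merged = t$merged_flags, status = t$statuses)
  }))
  dplyr::arrange(out, .data$frame, .data$track_id)
}

empty_track_table <- function() {
  tibble(frame = integer(), time_s = numeric(), track_id = integer(),
         x = numeric(), y = numeric(), area = integer(), length = numeric(),
         merged = logical(), status = character())
}

#' Track animals across a frame sequence
#'
#' The full offline tracking pipeline on one video: build the median
#' background, then per frame subtract, (optionally) mask, threshold, extract
#' size-gated clusters, and associate them to persistent identities with
#' [tracker_step()]. Clusters larger than the segmentation `max_area` are not
#' discarded here but passed to the tracker as merge candidates, so collision
#' blobs keep their constituent identities attached.
#'
#' @param frames A [frame_seq()] (or list of matrices).
#' @param seg [segmentation_params()]; its `threshold` must be set.
#' @param trk [tracker_params()]; `merge_area` defaults to `seg$max_area`.
#' @param mask Optional mask matrix (positive = keep).
#' @param background Optional precomputed `background_model`; computed with
#'   [median_background()] when `NULL`.
#' @param bg_samples Passed to [median_background()].
#' @return A track-table tibble (see [track_table()]), with the tracker
#'   state attached as attribute `"tracker"` and per-frame assignment log as
#'   attribute `"log"`.
#' @export
track_animals <- function(frames, seg, trk, mask = NULL, background = NULL,
                          bg_samples = 101) {
  if (is.list(frames) && !inherits(frames, "frame_seq")) frames <- frame_seq(frames)
  if (length(frames) < 1) abort("Need at least one frame.")
  if (is.null(seg$threshold)) abort("`seg$threshold` must be set (see run_pipeline for auto-estimation).")
  if (is.infinite(trk$merge_area) && is.finite(seg$max_area)) {
    trk$merge_area <- seg$max_area
  }
  if (is.null(background)) background <- median_background(frames, bg_samples)
  # tracker sees clusters above min_area with no upper gate; the upper gate
  # becomes the tracker's merge_area
  seg_open <- segmentation_params(threshold = seg$threshold,
                                  min_area = seg$min_area, max_area = Inf)
  state <- new_tracker(trk)
  times <- frame_times(frames)
  for (i in seq_len(length(frames))) {
    diff <- subtract_background(frame_at(frames, i), background)
    if (!is.null(mask)) diff <- apply_mask(diff, mask)
    bin <- binarize(diff, seg$threshold)
    clusters <- label_clusters(bin, seg_open, frame_index = i, time_s = times[i])
    state <- tracker_step(state, clusters)
  }
  out <- track_table(state)
  attr(out, "tracker") <- state
  attr(out, "log") <- state$log
  out
}
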