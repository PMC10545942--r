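#' Path displacement within a time window
#'
#' Total path length: the sum of Euclidean step lengths between consecutive
#' trajectory samples whose times fall in `[t0, t1]`. Raw (unsmoothed)
#' positions are used.
#'
#' @param traj Trajectory tibble with columns `time_s`, `x`, `y` (one track),
#'   times strictly increasing.
#' @param t0,t1 Window in seconds (`t0 < t1`); at least 2 samples must fall
#'   inside.
#' @return Displacement in pixels.
#' @export
path_displacement <- function(traj, t0, t1) {
  if (t0 >= t1) abort("Require t0 < t1.")
  w <- traj$time_s >= t0 & traj$time_s <= t1
  if (sum(w) < 2) abort("Fewer than 2 trajectory samples in the window.")
  x <- traj$x[w]
  y <- traj$y[w]
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Mean crawl velocity within a time window
#'
#' `path_displacement(traj, t0, t1) / (t1 - t0)`.
#'
#' @inheritParams path_displacement
#' @return Velocity in pixels/second.
#' @export
mean_velocity <- function(traj, t0, t1) {
  path_displacement(traj, t0, t1) / (t1 - t0)
}

#' Segment a trajectory's time span into stimulus epochs
#'
#' Splits the span into maximal constant-state intervals of the stimulus
#' record (e.g. the alternating 20 s ON / 20 s OFF periods of a blinking
#' protocol), intersected with the trajectory's own time span. Epochs tile
#' the span exactly: no gaps, no overlaps.
#'
#' @param traj Trajectory tibble (`time_s`, ...) or a numeric `c(t0, t1)`
#'   span.
#' @param timeline A stimulus timeline (`time_s`, `value`) or parsed state
#'   log (`host_time_s`, `value`); must cover the trajectory span.
#' @return A tibble with columns `epoch_index`, `state` (`"off"`/`"on"`),
#'   `value`, `t_start`, `t_end`.
#' @export
segment_epochs <- function(traj, timeline) {
  span <- if (is.numeric(traj)) range(traj) else range(traj$time_s)
  tcol <- if ("time_s" %in% names(timeline)) "time_s" else "host_time_s"
  if (nrow(timeline) == 0) abort("Empty stimulus record.")
  t <- timeline[[tcol]]
  v <- timeline$value
  o <- order(t)
  t <- t[o]
  v <- v[o]
  if (span[1] < t[1] - 1e-9) {
    abort("Stimulus record does not cover the start of the trajectory.")
  }
  # collapse consecutive equal values into maximal constant-state events
  keep <- c(TRUE, diff(v) != 0)
  t <- t[keep]
  v <- v[keep]
  # interval boundaries clipped to the trajectory span
  starts <- pmax(t, span[1])
  ends <- c(t[-1], Inf)
  ends <- pmin(ends, span[2])
  inside <- starts < ends
  starts <- starts[inside]
  ends <- ends[inside]
  vv <- v[inside]
  if (length(starts) == 0) {
    # span collapses inside a single state
    k <- findInterval(span[1], t)
    starts <- span[1]
    ends <- span[2]
    vv <- v[max(k, 1)]
  }
  tibble(epoch_index = seq_along(starts),
         state = ifelse(vv > 0, "on", "off"),
         value = vv, t_start = starts, t_end = ends)
}

#' Per-track, per-epoch displacement and velocity
#'
#' Computes [path_displacement()] and [mean_velocity()] for every track in a
#' track table within every stimulus epoch. Epochs in which a track has
#' fewer than 2 samples are dropped.
#'
#' @param track_table Track table (`frame`, `time_s`, `track_id`, `x`, `y`, ...).
#' @param timeline Stimulus timeline or state log covering the recording.
#' @return A tibble: `track_id`, `epoch_index`, `state`, `t_start`, `t_end`,
#'   `displacement`, `mean_velocity`.
#' @export
epoch_stats <- function(track_table, timeline) {
  if (nrow(track_table) == 0) {
    return(tibble(track_id = integer(), epoch_index = integer(),
                  state = character(), t_start = numeric(), t_end = numeric(),
                  displacement = numeric(), mean_velocity = numeric()))
  }
  epochs <- segment_epochs(range(track_table$time_s), timeline)
  out <- list()
  for (tid in unique(track_table$track_id)) {
    traj <- dplyr::filter(track_table, .data$track_id == tid)
    for (k in seq_len(nrow(epochs))) {
      e <- epochs[k, ]
      w <- traj$time_s >= e$t_start & traj$time_s <= e$t_end
      if (sum(w) < 2) next
      d <- path_displacement(traj, e$t_start, e$t_end)
      out[[length(out) + 1]] <- tibble(
        track_id = tid, epoch_index = e$epoch_index, state = e$state,
        t_start = e$t_start, t_end = e$t_end, displacement = d,
        mean_velocity = d / (e$t_end - e$t_start)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on per-animal paired differences
#' (`values_on - values_off`), the comparison used for off-vs-on stimulus
#' epochs. Zero differences are dropped; ties receive mid-ranks. For up to
#' 12 non-zero differences the p-value is exact, computed by enumerating all
#' sign patterns; above that a normal approximation with tie-corrected
#' variance (`Var W = sum(r_i^2)/4`) is used, without continuity correction.
#' When all differences are zero, `p = 1` by convention.
#'
#' @param values_off,values_on Paired numeric vectors of equal length
#'   (n >= 1).
#' @return A `paired_wilcoxon` object: `n_pairs` (input pairs), `n_used`
#'   (non-zero differences), `statistic` (W, the rank sum over positive
#'   differences), `p_value`, `method`.
#' @examples
#' paired_wilcoxon(c(1, 2, 3, 4, 5, 6), c(2, 3, 5, 6, 8, 10))
#' @export
paired_wilcoxon <- function(values_off, values_on) {
  if (length(values_off) != length(values_on)) {
    abort("`values_off` and `values_on` must have equal length.")
  }
  n_pairs <- length(values_off)
  if (n_pairs < 1) abort("Need at least one pair.")
  d <- values_on - values_off
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(structure(list(n_pairs = n_pairs, n_used = 0L, statistic = 0,
                          p_value = 1, method = "all differences zero"),
                     class = "paired_wilcoxon"))
  }
  r <- rank(abs(d))  # mid-ranks for ties
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (m <= 12) {
    # exact: all 2^m equally likely sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    W_all <- as.vector(signs %*% r)
    p <- mean(abs(W_all - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation, tie-corrected"
  }
  structure(list(n_pairs = n_pairs, n_used = m, statistic = W, p_value = p,
                 method = method),
            class = "paired_wilcoxon")
}

#' @export
print.paired_wilcoxon <- function(x, ...) {
  cat(sprintf("Paired Wilcoxon signed-rank: W = %g, p = %.5g (%s; %d pairs, %d used)\n",
              x$statistic, x$p_value, x$method, x$n_pairs, x$n_used))
  invisible(x)
}

#' Identity-preservation score against ground truth
#'
#' Quantifies how well a tracker kept identities on a video with known
#' ground truth. Tracks are mapped to animals once, by minimum-distance
#' matching on the first frame both tables cover; the score is the
#' percentage of visible, non-merged ground-truth records whose nearest
#' emitted track position (within `max_move`) is the mapped track.
#'
#' @param track_table Track table (`frame`, `track_id`, `x`, `y`, ...).
#' @param ground_truth Ground-truth tibble from [make_arena()].
#' @param max_move Match radius in pixels (a record with no track within it
#'   counts as lost).
#' @return Percentage in \[0, 100\] (0 when there are no tracks).
#' @export
identity_preservation <- function(track_table, ground_truth, max_move) {
  gt <- dplyr::filter(ground_truth, .data$visible & !.data$merged)
  if (nrow(gt) == 0) abort("No visible, non-merged ground-truth records.")
  if (nrow(track_table) == 0) return(0)
  common <- intersect(unique(track_table$frame), unique(gt$frame))
  if (length(common) == 0) return(0)
  f0 <- min(common)
  g0 <- dplyr::filter(gt, .data$frame == f0)
  t0 <- dplyr::filter(track_table, .data$frame == f0)
  # one-time animal -> track mapping by minimum-distance matching
  cost <- outer(seq_len(nrow(g0)), seq_len(nrow(t0)),
                function(i, j) sqrt((g0$x[i] - t0$x[j])^2 + (g0$y[i] - t0$y[j])^2))
  sol <- match_min_cost(matrix(cost, nrow(g0), nrow(t0)))
  mapping <- setNames(rep(NA_integer_, nrow(g0)), g0$animal_id)
  mapping[!is.na(sol)] <- t0$track_id[sol[!is.na(sol)]]

  correct <- 0L
  total <- 0L
  tt_by_frame <- split(track_table, track_table$frame)
  for (f in sort(unique(gt$frame))) {
    gf <- gt[gt$frame == f, ]
    tf <- tt_by_frame[[as.character(f)]]
    total <- total + nrow(gf)
    if (is.null(tf) || nrow(tf) == 0) next
    for (i in seq_len(nrow(gf))) {
      dists <- sqrt((tf$x - gf$x[i])^2 + (tf$y - gf$y[i])^2)
      j <- which.min(dists)
      mapped <- mapping[as.character(gf$animal_id[i])]
      if (dists[j] <= max_move && !is.na(mapped) && tf$track_id[j] == mapped) {
        correct <- correct + 1L
      }
    }
  }
  100 * correct / total
}
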