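# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# per-pixel median of a list of matrices by explicit sort
oracle_median_stack <- function(frames) {
  d <- dim(frames[[1]])
  out <- matrix(NA_real_, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      v <- sort(vapply(frames, function(f) f[r, c], numeric(1)))
      n <- length(v)
      out[r, c] <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    }
  }
  out
}

# 8-connected components by queue-based flood fill on the full grid
oracle_flood_components <- function(binary) {
  h <- nrow(binary)
  w <- ncol(binary)
  seen <- matrix(FALSE, h, w)
  comps <- list()
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (binary[r0, c0] && !seen[r0, c0]) {
      queue <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      px <- integer(0)
      while (length(queue) > 0) {
        p <- queue[[1]]
        queue <- queue[-1]
        px <- c(px, (p[2] - 1L) * h + p[1])
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr
          cc <- p[2] + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              binary[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
      comps[[length(comps) + 1]] <- sort(px)
    }
  }
  comps
}

# maximum-cardinality, minimum-total-cost matching by exhaustive recursion
# over all feasible injective assignments (rows -> columns, Inf = infeasible)
oracle_best_matching <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  best_card <- -1L
  best_cost <- Inf
  rec <- function(i, used, card, acc) {
    if (i > n) {
      if (card > best_card || (card == best_card && acc < best_cost)) {
        best_card <<- card
        best_cost <<- acc
      }
      return()
    }
    rec(i + 1L, used, card, acc)
    for (j in seq_len(m)) {
      if (!(j %in% used) && is.finite(cost[i, j])) {
        rec(i + 1L, c(used, j), card + 1L, acc + cost[i, j])
      }
    }
  }
  rec(1L, integer(0), 0L, 0)
  list(cardinality = best_card, cost = best_cost)
}

matching_card_cost <- function(cost, sol) {
  keep <- which(!is.na(sol))
  list(cardinality = length(keep),
       cost = if (length(keep) > 0) sum(cost[cbind(keep, sol[keep])]) else 0)
}

# exact two-sided signed-rank p-value by enumeration of all sign patterns
oracle_wilcoxon_p <- function(off, on) {
  d <- on - off
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  W_all <- as.vector(signs %*% r)
  mean(abs(W_all - mu) >= abs(W - mu) - 1e-9)
}

# normal-equations solve for a quadratic least-squares fit
oracle_quadratic_coefs <- function(x, y) {
  X <- cbind(1, x, x^2)
  solve(t(X) %*% X, t(X) %*% y)[, 1]  # (c, b, a)
}

# standard two-animal collision scenario shared by tests and acceptance
collision_scenario <- function(seed, n_frames = 110) {
  spec <- arena_spec(200, 200, "bright_on_dark", noise_sigma = 0.01)
  animals <- list(
    animal_spec(1, target_area = 60, speed = 2, start_x = 60, start_y = 100),
    animal_spec(2, target_area = 120, speed = 2, start_x = 140, start_y = 100))
  ev <- collision_event(1, 2, frame_start = 40, frame_end = 70)
  sim <- make_arena(spec, animals, n_frames = n_frames,
                    collisions = list(ev), seed = seed)
  seg <- segmentation_params(threshold = 0.15, min_area = 25, max_area = 150)
  trk <- tracker_params(max_move = 8, min_active = 3, max_inactive = 40)
  tt <- track_animals(sim$frames, seg, trk)
  list(sim = sim, tracks = tt, seg = seg, trk = trk, event_end = 70)
}

# identity restricted to pre-event and post-event frames: did the split
# restore the correct identities?
post_split_identity <- function(scn, buffer = 5) {
  keep <- function(df) {
    dplyr::filter(df, frame <= 5 | frame > scn$event_end + buffer)
  }
  identity_preservation(keep(scn$tracks), keep(scn$sim$ground_truth),
                        max_move = 8)
}
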