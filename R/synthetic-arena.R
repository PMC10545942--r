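#' Arena specification for synthetic videos
#'
#' Describes the recording regime the generator emulates. Two polarities are
#' supported: `"dark_on_light"` (ambient lighting, dark animals on a light
#' background — typical for adult flies) and `"bright_on_dark"` (IR darkfield
#' illumination, bright animals on a dark background — typical for nearly
#' transparent larvae and fish).
#'
#' @param width,height Arena size in pixels (>= 32).
#' @param polarity `"dark_on_light"` or `"bright_on_dark"`.
#' @param background_level Background intensity in \[0, 1\].
#' @param noise_sigma Per-pixel Gaussian noise standard deviation in \[0, 1\].
#' @param fps Frame rate (frames/second).
#' @return An `arena_spec` object.
#' @export
arena_spec <- function(width, height, polarity = c("dark_on_light", "bright_on_dark"),
                       background_level = NULL, noise_sigma = 0.01, fps = 30) {
  polarity <- match.arg(polarity)
  if (is.null(background_level)) {
    background_level <- if (polarity == "dark_on_light") 0.85 else 0.1
  }
  if (width < 32 || height < 32) abort("Arena must be at least 32 x 32 px.")
  if (background_level < 0 || background_level > 1) {
    abort("`background_level` must be in [0, 1].")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (fps <= 0) abort("`fps` must be positive.")
  structure(list(width = as.integer(width), height = as.integer(height),
                 polarity = polarity, background_level = background_level,
                 noise_sigma = noise_sigma, fps = fps),
            class = "arena_spec")
}

#' Animal specification for synthetic videos
#'
#' Each animal renders as a rotated ellipse of approximately `target_area`
#' pixels whose intensity differs from the background by `contrast` (sign set
#' by the arena polarity). Motion is a persistent random walk: each frame the
#' heading is perturbed by Gaussian noise scaled by `1 - heading_persistence`
#' and the animal advances `speed` pixels along it, reflecting at the arena
#' borders.
#'
#' @param animal_id Integer identity, unique within one arena.
#' @param target_area Blob area in pixels (>= 4). ~60 px matches a
#'   low-resolution larva recording; ~500 px a high-resolution fish.
#' @param axis_ratio Major/minor axis ratio (>= 1).
#' @param contrast Intensity offset from background, in (0, 1\].
#' @param speed Pixels per frame (>= 0).
#' @param heading_persistence In \[0, 1\]; 1 = straight-line motion.
#' @param start_x,start_y Optional fixed start position (0-based pixel
#'   coordinates, x = column, y = row); random when `NULL`.
#' @return An `animal_spec` object.
#' @export
animal_spec <- function(animal_id, target_area = 60, axis_ratio = 3,
                        contrast = 0.4, speed = 2, heading_persistence = 0.8,
                        start_x = NULL, start_y = NULL) {
  if (target_area < 4) abort("`target_area` must be >= 4 pixels.")
  if (axis_ratio < 1) abort("`axis_ratio` must be >= 1.")
  if (contrast <= 0 || contrast > 1) abort("`contrast` must be in (0, 1].")
  if (speed < 0) abort("`speed` must be >= 0.")
  if (heading_persistence < 0 || heading_persistence > 1) {
    abort("`heading_persistence` must be in [0, 1].")
  }
  structure(list(animal_id = as.integer(animal_id),
                 target_area = as.integer(target_area),
                 axis_ratio = axis_ratio, contrast = contrast, speed = speed,
                 heading_persistence = heading_persistence,
                 start_x = start_x, start_y = start_y),
            class = "animal_spec")
}

#' Scheduled collision between two animals
#'
#' During frames `frame_start..frame_end` the two animals are steered onto a
#' pass-through crossing: each moves linearly toward the shared midpoint of
#' their entry positions, overlaps the other there mid-window, and continues
#' to the other's entry position, after which both resume their random walks.
#' This produces a reproducible merge-and-split for identity-retention tests.
#'
#' @param animal_a,animal_b Animal ids.
#' @param frame_start,frame_end Frame window (1-based, `frame_start < frame_end`).
#' @return A `collision_event` object.
#' @export
collision_event <- function(animal_a, animal_b, frame_start, frame_end) {
  if (frame_start >= frame_end) abort("`frame_start` must be < `frame_end`.")
  structure(list(animal_a = as.integer(animal_a), animal_b = as.integer(animal_b),
                 frame_start = as.integer(frame_start),
                 frame_end = as.integer(frame_end)),
            class = "collision_event")
}

# ellipse semi-axes for a target area and axis ratio: area = pi * a * b
ellipse_axes <- function(target_area, axis_ratio) {
  a <- sqrt(target_area * axis_ratio / pi)
  b <- a / axis_ratio
  list(a = a, b = b)
}

# pixel centres (0-based x = col, y = row) inside a rotated ellipse at (cx, cy)
ellipse_pixels <- function(cx, cy, a, b, theta, width, height) {
  r <- ceiling(a) + 1
  xs <- max(0, floor(cx - r)):min(width - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(height - 1, ceiling(cy + r))
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  dx <- px - cx
  dy <- py - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  list(x = px[keep], y = py[keep])
}

# projected extent of pixel centres along the axis at angle theta, plus 1
projected_length <- function(x, y, theta) {
  p <- x * cos(theta) + y * sin(theta)
  diff(range(p)) + 1
}

#' Generate a synthetic arena video with ground truth
#'
#' Simulates animals as elliptical blobs on a noisy uniform background and
#' returns both the rendered frames (lazily, drawn on demand) and one exact
#' ground-truth record per (frame, animal) — the oracle against which
#' segmentation and tracking are validated. The same seed always yields
#' bit-identical frames and records.
#'
#' Blob intensity differs from the background by each animal's `contrast`;
#' with `dark_on_light` polarity blobs are darker, with `bright_on_dark`
#' brighter. Outside scheduled collisions, trajectories are kept disjoint:
#' a step that would bring two blobs into contact is rejected and the animals
#' turn around instead.
#'
#' @param spec An [arena_spec()].
#' @param animals List of [animal_spec()] (may be empty).
#' @param n_frames Number of frames (>= 1).
#' @param collisions List of [collision_event()].
#' @param seed Integer seed; the generator uses a private RNG stream.
#' @return A list with elements `frames` (a [frame_seq()]) and
#'   `ground_truth` (a tibble with columns `frame`, `animal_id`, `x`, `y`,
#'   `area`, `length`, `visible`, `merged`; coordinates 0-based, x = column).
#' @examples
#' sim <- make_arena(arena_spec(64, 64), list(animal_spec(1, speed = 1)),
#'                   n_frames = 10, seed = 42)
#' sim$ground_truth
#' @export
make_arena <- function(spec, animals, n_frames, collisions = list(), seed = 1) {
  if (!inherits(spec, "arena_spec")) abort("`spec` must be an arena_spec.")
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  if (inherits(animals, "animal_spec")) animals <- list(animals)
  if (inherits(collisions, "collision_event")) collisions <- list(collisions)
  n_animals <- length(animals)
  ids <- vapply(animals, function(a) a$animal_id, integer(1))
  if (anyDuplicated(ids)) abort("Animal ids must be unique.")
  for (ev in collisions) {
    if (!all(c(ev$animal_a, ev$animal_b) %in% ids)) {
      abort("Collision event references an unknown animal id.")
    }
    if (ev$frame_end > n_frames) abort("Collision event extends past the video.")
  }

  axes <- lapply(animals, function(a) ellipse_axes(a$target_area, a$axis_ratio))
  amax <- vapply(axes, function(e) e$a, numeric(1))
  margin <- amax + 1
  if (n_animals > 0 &&
      (any(2 * margin >= spec$width) || any(2 * margin >= spec$height))) {
    abort("`target_area` too large for the arena.")
  }

  state <- with_private_seed(seed, {
    simulate_trajectories(spec, animals, n_frames, collisions, margin)
  })
  pos <- state$pos        # n_frames x n_animals x 2 (x, y)
  headings <- state$headings

  # ground truth from the exact blob masks used for rendering
  truth <- list()
  blob_cache <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    blobs <- vector("list", n_animals)
    keys <- vector("list", n_animals)
    for (j in seq_len(n_animals)) {
      e <- axes[[j]]
      b <- ellipse_pixels(pos[f, j, 1], pos[f, j, 2], e$a, e$b,
                          headings[f, j], spec$width, spec$height)
      blobs[[j]] <- b
      keys[[j]] <- b$y * spec$width + b$x
    }
    merged <- rep(FALSE, n_animals)
    if (n_animals > 1) {
      for (j in seq_len(n_animals - 1)) {
        for (k in (j + 1):n_animals) {
          if (length(keys[[j]]) && length(keys[[k]]) &&
              any(keys[[j]] %in% keys[[k]])) {
            merged[j] <- TRUE
            merged[k] <- TRUE
          }
        }
      }
    }
    blob_cache[[f]] <- blobs
    if (n_animals > 0) {
      truth[[f]] <- tibble(
        frame = f,
        animal_id = ids,
        x = pos[f, , 1],
        y = pos[f, , 2],
        area = vapply(blobs, function(b) length(b$x), integer(1)),
        length = vapply(seq_len(n_animals), function(j) {
          if (length(blobs[[j]]$x) == 0) return(0)
          projected_length(blobs[[j]]$x, blobs[[j]]$y, headings[f, j])
        }, numeric(1)),
        visible = vapply(blobs, function(b) length(b$x) > 0, logical(1)),
        merged = merged
      )
    }
  }
  truth <- if (n_animals > 0) dplyr::bind_rows(truth) else empty_ground_truth()

  sign <- if (spec$polarity == "dark_on_light") -1 else 1
  contrasts <- vapply(animals, function(a) a$contrast, numeric(1))
  render <- function(i) {
    m <- matrix(spec$background_level, spec$height, spec$width)
    for (j in seq_len(n_animals)) {
      b <- blob_cache[[i]][[j]]
      if (length(b$x)) {
        m[cbind(b$y + 1L, b$x + 1L)] <- spec$background_level + sign * contrasts[j]
      }
    }
    if (spec$noise_sigma > 0) {
      noise <- with_private_seed(frame_seed(seed, i), {
        rnorm(length(m), 0, spec$noise_sigma)
      })
      m <- m + noise
    }
    m[m < 0] <- 0
    m[m > 1] <- 1
    m
  }

  frames <- new_frame_seq(n = n_frames, height = spec$height, width = spec$width,
                          fps = spec$fps,
                          time_s = (seq_len(n_frames) - 1) / spec$fps,
                          get = render)
  list(frames = frames, ground_truth = truth)
}

empty_ground_truth <- function() {
  tibble(frame = integer(), animal_id = integer(), x = numeric(), y = numeric(),
         area = integer(), length = numeric(), visible = logical(),
         merged = logical())
}

# sequential random-walk simulation; collision windows override positions
simulate_trajectories <- function(spec, animals, n_frames, collisions, margin) {
  n <- length(animals)
  pos <- array(NA_real_, c(n_frames, max(n, 1L), 2L))
  headings <- matrix(0, n_frames, max(n, 1L))
  if (n == 0) return(list(pos = pos, headings = headings))

  ids <- vapply(animals, function(a) a$animal_id, integer(1))
  speed <- vapply(animals, function(a) a$speed, numeric(1))
  persistence <- vapply(animals, function(a) a$heading_persistence, numeric(1))
  minsep <- outer(margin, margin, "+")  # bounding-circle separation

  # initial placement: user-specified or rejection-sampled, pairwise disjoint
  cur <- matrix(NA_real_, n, 2)
  fixed <- vapply(animals, function(a) !is.null(a$start_x), logical(1))
  for (j in which(fixed)) {
    cur[j, ] <- c(animals[[j]]$start_x, animals[[j]]$start_y)
    if (cur[j, 1] < 0 || cur[j, 1] >= spec$width ||
        cur[j, 2] < 0 || cur[j, 2] >= spec$height) {
      abort("Animal start position outside the arena.")
    }
  }
  if (any(fixed)) {
    idx <- which(fixed)
    for (a in idx) for (b in idx) {
      if (a < b && sqrt(sum((cur[a, ] - cur[b, ])^2)) < minsep[a, b]) {
        abort("Animals have overlapping initial positions outside a scheduled collision.")
      }
    }
  }
  for (j in which(!fixed)) {
    for (try in 1:1000) {
      cand <- c(runif(1, margin[j], spec$width - 1 - margin[j]),
                runif(1, margin[j], spec$height - 1 - margin[j]))
      others <- which(!is.na(cur[, 1]))
      ok <- all(vapply(others, function(k) {
        sqrt(sum((cand - cur[k, ])^2)) >= minsep[j, k]
      }, logical(1)))
      if (ok) break
      if (try == 1000) abort("Could not place animals without overlap; arena too crowded.")
    }
    cur[j, ] <- cand
  }
  hd <- runif(n, 0, 2 * pi)

  # per-frame collision bookkeeping
  in_event <- function(f) {
    out <- list()
    for (ev in collisions) {
      if (f >= ev$frame_start && f <= ev$frame_end) out[[length(out) + 1]] <- ev
    }
    out
  }
  ev_anchor <- list()  # per event: entry positions at frame_start

  pos[1, , ] <- cur
  headings[1, ] <- hd
  for (f in 2:max(n_frames, 2)) {
    if (f > n_frames) break
    hd <- hd + rnorm(n, 0, (1 - persistence) * pi)
    prop <- cur + speed * cbind(cos(hd), sin(hd))
    # border reflection (keeps the whole blob inside)
    for (j in seq_len(n)) {
      lo <- margin[j]
      hix <- spec$width - 1 - margin[j]
      hiy <- spec$height - 1 - margin[j]
      if (prop[j, 1] < lo) { prop[j, 1] <- 2 * lo - prop[j, 1]; hd[j] <- pi - hd[j] }
      if (prop[j, 1] > hix) { prop[j, 1] <- 2 * hix - prop[j, 1]; hd[j] <- pi - hd[j] }
      if (prop[j, 2] < lo) { prop[j, 2] <- 2 * lo - prop[j, 2]; hd[j] <- -hd[j] }
      if (prop[j, 2] > hiy) { prop[j, 2] <- 2 * hiy - prop[j, 2]; hd[j] <- -hd[j] }
      prop[j, 1] <- min(max(prop[j, 1], lo), hix)
      prop[j, 2] <- min(max(prop[j, 2], lo), hiy)
    }
    # collision steering overrides the walk
    colliding <- integer(0)
    for (ev in in_event(f)) {
      key <- paste(ev$animal_a, ev$animal_b, ev$frame_start, sep = "_")
      ja <- match(ev$animal_a, ids)
      jb <- match(ev$animal_b, ids)
      if (is.null(ev_anchor[[key]])) {
        # entry positions: where the animals are when the event begins
        ev_anchor[[key]] <- list(a = cur[ja, ], b = cur[jb, ], f0 = f - 1L)
      }
      anch <- ev_anchor[[key]]
      u <- min(1, (f - anch$f0) / (ev$frame_end - anch$f0))
      prop[ja, ] <- anch$a + u * (anch$b - anch$a)
      prop[jb, ] <- anch$b + u * (anch$a - anch$b)
      # keep headings aligned with steered motion
      hd[ja] <- atan2(anch$b[2] - anch$a[2], anch$b[1] - anch$a[1])
      hd[jb] <- atan2(anch$a[2] - anch$b[2], anch$a[1] - anch$b[1])
      colliding <- c(colliding, ja, jb)
    }
    # disjointness outside collisions: reject steps that bring blobs into
    # contact; the rejected animal keeps its position and turns around
    if (n > 1) {
      for (j in seq_len(n - 1)) {
        for (k in (j + 1):n) {
          both_colliding <- j %in% colliding && k %in% colliding
          if (both_colliding) next
          d <- sqrt(sum((prop[j, ] - prop[k, ])^2))
          if (d < minsep[j, k]) {
            for (m in c(j, k)) {
              if (!(m %in% colliding)) {
                prop[m, ] <- cur[m, ]
                hd[m] <- hd[m] + pi
              }
            }
          }
        }
      }
    }
    cur <- prop
    pos[f, , ] <- cur
    headings[f, ] <- hd
  }
  list(pos = pos, headings = headings)
}

#' Write or read ground-truth records as CSV
#'
#' Lossless round-trip: doubles are printed with 17 significant digits so
#' `read_ground_truth(write_ground_truth(x))` reproduces `x` exactly.
#'
#' @param records Ground-truth tibble from [make_arena()].
#' @param path Output file; when `NULL` the CSV text is returned as a
#'   character scalar.
#' @return `write_ground_truth`: the CSV text (invisibly when written to a
#'   file); `read_ground_truth`: a ground-truth tibble.
#' @export
write_ground_truth <- function(records, path = NULL) {
  if (nrow(records) == 0) abort("`records` must be non-empty.")
  header <- "frame,animal_id,x,y,area,length,visible,merged"
  rows <- sprintf("%d,%d,%s,%s,%d,%s,%s,%s",
                  records$frame, records$animal_id,
                  num17(records$x), num17(records$y),
                  records$area, num17(records$length),
                  ifelse(records$visible, "TRUE", "FALSE"),
                  ifelse(records$merged, "TRUE", "FALSE"))
  txt <- paste(c(header, rows), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

num17 <- function(x) sprintf("%.17g", x)

#' @rdname write_ground_truth
#' @param text_or_path CSV text (containing a newline) or a file path.
#' @export
read_ground_truth <- function(text_or_path) {
  df <- read_csv_strict(text_or_path,
                        c("frame", "animal_id", "x", "y", "area", "length",
                          "visible", "merged"))
  tibble(frame = as.integer(df$frame), animal_id = as.integer(df$animal_id),
         x = as.numeric(df$x), y = as.numeric(df$y),
         area = as.integer(df$area), length = as.numeric(df$length),
         visible = as.logical(df$visible), merged = as.logical(df$merged))
}

# minimal strict CSV reader: comma, '.', header required, no quoting needed
read_csv_strict <- function(text_or_path, required_cols) {
  lines <- if (length(text_or_path) == 1L && grepl("\n", text_or_path)) {
    strsplit(text_or_path, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(text_or_path)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("Empty CSV input.")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  missing <- setdiff(required_cols, header)
  if (length(missing) > 0) {
    abort(sprintf("CSV is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (length(lines) == 1) {
    df <- as.data.frame(matrix(character(0), 0, length(header)))
    names(df) <- header
    return(df)
  }
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad) > 0) {
    abort(sprintf("Malformed CSV row at line %d.", bad[1] + 1L))
  }
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- header
  df
}
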