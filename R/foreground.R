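#' Segmentation parameters
#'
#' @param threshold Foreground threshold on the background difference, a
#'   decimal fraction in \[0, 1\] (for typical arena recordings values below
#'   0.1 work well; higher-contrast footage tolerates higher, more stringent
#'   thresholds). `NULL` requests automatic estimation in [run_pipeline()].
#' @param min_area,max_area Cluster area gate in pixels; connected components
#'   outside `[min_area, max_area]` are discarded.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(threshold = NULL, min_area = 1, max_area = Inf) {
  if (!is.null(threshold)) {
    stopifnot_scalar_num(threshold, "threshold")
    if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  }
  if (min_area <= 0 || min_area > max_area) {
    abort("Require 0 < min_area <= max_area.")
  }
  structure(list(threshold = threshold, min_area = min_area,
                 max_area = max_area),
            class = "segmentation_params")
}

#' Median background model
#'
#' Estimates the static background as the per-pixel median over a sample of
#' frames. Provided every moving animal covers each pixel in fewer than half
#' of the sampled frames, the median sees mostly background at every pixel
#' and the animals vanish from the model. For even sample counts the median
#' is the mean of the two central order statistics; sampling prefers an odd
#' count.
#'
#' @param frames A [frame_seq()] or a list of numeric matrices.
#' @param max_samples Upper bound on the number of frames entering the
#'   median; frames are taken at a regular stride to stay within it.
#' @return A `background_model` with fields `pixels` (the background image)
#'   and `update_weight` (0 until [update_background()] is used).
#' @export
median_background <- function(frames, max_samples = 101) {
  if (inherits(frames, "frame_seq")) {
    n <- length(frames)
    if (n == 0) abort("Need at least one frame.")
    stride <- ceiling(n / max_samples)
    idx <- seq(1, n, by = stride)
    if (length(idx) > 1 && length(idx) %% 2 == 0) idx <- idx[-length(idx)]
    frames <- lapply(idx, function(i) frame_at(frames, i))
  }
  if (!is.list(frames) || length(frames) == 0) abort("Need at least one frame.")
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) abort("All frames must have identical dimensions.")
  stack <- matrix(unlist(frames, use.names = FALSE), nrow = prod(d))
  med <- matrixStats::rowMedians(stack)
  structure(list(pixels = matrix(med, d[1], d[2]), update_weight = 0),
            class = "background_model")
}

#' Dynamic background update
#'
#' Blends the current frame into the background model:
#' `new = (1 - weight) * old + weight * frame`. With a small weight the model
#' slowly adapts to lighting changes while moving animals barely imprint.
#'
#' @param model A `background_model`.
#' @param frame A numeric matrix, same shape as the model.
#' @param weight Blend weight in \[0, 1\].
#' @return The updated `background_model` (with `update_weight` recorded).
#' @export
update_background <- function(model, frame, weight) {
  if (!inherits(model, "background_model")) abort("`model` must be a background_model.")
  stopifnot_scalar_num(weight, "weight")
  if (weight < 0 || weight > 1) abort("`weight` must be in [0, 1].")
  if (!identical(dim(model$pixels), dim(frame))) {
    abort("Frame and background dimensions differ.")
  }
  model$pixels <- (1 - weight) * model$pixels + weight * frame
  model$update_weight <- weight
  model
}

#' Background subtraction
#'
#' Per-pixel absolute difference between a frame and the background model.
#' The absolute value makes one code path serve both recording polarities:
#' dark animals on a light background and bright animals on a dark one
#' produce identical difference images at equal contrast.
#'
#' @param frame A numeric matrix in \[0, 1\].
#' @param model A `background_model` (or a background matrix).
#' @return A numeric matrix of differences in \[0, 1\].
#' @export
subtract_background <- function(frame, model) {
  bg <- if (inherits(model, "background_model")) model$pixels else model
  if (!identical(dim(frame), dim(bg))) abort("Frame and background dimensions differ.")
  abs(frame - bg)
}

#' Apply a region-of-interest mask
#'
#' Pixels where the mask is positive are kept; pixels where it is zero are
#' set to zero (removed from consideration). Masks are easily drawn in any
#' image editor and loaded with [read_frames()] machinery.
#'
#' @param image A numeric matrix.
#' @param mask A numeric/logical matrix of the same shape; positive = keep.
#' @return The masked image.
#' @export
apply_mask <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) abort("Image and mask dimensions differ.")
  image * (mask > 0)
}

#' Threshold a difference image
#'
#' A pixel is foreground iff its difference value strictly exceeds the
#' threshold.
#'
#' @param diff A numeric matrix (background difference).
#' @param threshold Fraction in \[0, 1\].
#' @return A logical matrix.
#' @export
binarize <- function(diff, threshold) {
  stopifnot_scalar_num(threshold, "threshold")
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  diff > threshold
}

# 8-connected labeling of a sparse binary image via union-find over the
# foreground pixel list; returns a list of integer pixel-index vectors
# (column-major), one per component, ordered by top-most then left-most
# first pixel.
label_components_sparse <- function(binary) {
  h <- nrow(binary)
  w <- ncol(binary)
  idx <- which(binary)
  m <- length(idx)
  if (m == 0) return(list())
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  parent <- seq_len(m)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  # 4 of the 8 neighbour offsets suffice (the rest are symmetric)
  offsets <- list(c(-1L, 0L), c(-1L, -1L), c(-1L, 1L), c(0L, -1L))
  for (off in offsets) {
    nr <- r + off[1]
    nc <- c + off[2]
    valid <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc - 1L) * h + nr
    pos <- rep(NA_integer_, m)
    pos[valid] <- match(nidx[valid], idx)
    for (i in which(!is.na(pos))) {
      ra <- find(i)
      rb <- find(pos[i])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  comps <- split(seq_len(m), roots)
  # order by top-most, then left-most first pixel (row-major scan order)
  first_key <- vapply(comps, function(ii) {
    min((r[ii] - 1) * w + (c[ii] - 1))
  }, numeric(1))
  comps <- comps[order(first_key)]
  lapply(comps, function(ii) idx[ii])
}

#' Extract size-gated clusters from a binary image
#'
#' Finds 8-connected foreground components, discards those with area below
#' `min_area` or above `max_area`, and measures shape features for each
#' survivor via [measure_cluster()]. Labels are assigned in scan order
#' (top-most, then left-most first pixel), so output is deterministic.
#'
#' @param binary A logical matrix (from [binarize()]).
#' @param params A [segmentation_params()] (its `threshold` is not used here).
#' @param frame_index,time_s Metadata copied onto each cluster row.
#' @return A tibble with one row per cluster: `frame`, `label`, `x`, `y`,
#'   `area`, `length`, `orientation`, `x0`, `y0`, `x1`, `y1` (half-open
#'   bounding box), `time_s`.
#' @export
label_clusters <- function(binary, params, frame_index = NA_integer_,
                           time_s = NA_real_) {
  if (!inherits(params, "segmentation_params")) {
    abort("`params` must be segmentation_params.")
  }
  comps <- label_components_sparse(binary)
  areas <- lengths(comps)
  keep <- areas >= params$min_area & areas <= params$max_area
  comps <- comps[keep]
  if (length(comps) == 0) return(empty_cluster_table())
  h <- nrow(binary)
  rows <- lapply(seq_along(comps), function(k) {
    idx <- comps[[k]]
    x <- ((idx - 1L) %/% h)      # 0-based column
    y <- ((idx - 1L) %% h)       # 0-based row
    f <- measure_pixels(x, y)
    tibble(frame = frame_index, label = k, x = f$x, y = f$y, area = f$area,
           length = f$length, orientation = f$orientation,
           x0 = f$bbox[1], y0 = f$bbox[2], x1 = f$bbox[3], y1 = f$bbox[4],
           time_s = time_s)
  })
  dplyr::bind_rows(rows)
}

empty_cluster_table <- function() {
  tibble(frame = integer(), label = integer(), x = numeric(), y = numeric(),
         area = integer(), length = numeric(), orientation = numeric(),
         x0 = integer(), y0 = integer(), x1 = integer(), y1 = integer(),
         time_s = numeric())
}

# shape features from 0-based pixel-centre coordinates
measure_pixels <- function(x, y) {
  n <- length(x)
  cx <- mean(x)
  cy <- mean(y)
  if (n == 1) {
    theta <- 0
    len <- 1
  } else {
    dx <- x - cx
    dy <- y - cy
    sxx <- mean(dx * dx)
    syy <- mean(dy * dy)
    sxy <- mean(dx * dy)
    if (abs(sxy) < 1e-12 && abs(sxx - syy) < 1e-12) {
      theta <- 0  # isotropic pixel set: primary axis undefined, use 0
    } else {
      # principal axis of the second-moment matrix
      theta <- 0.5 * atan2(2 * sxy, sxx - syy)
    }
    if (theta < 0) theta <- theta + pi
    if (theta >= pi) theta <- theta - pi
    len <- projected_length(x, y, theta)
  }
  list(x = cx, y = cy, area = as.integer(n), length = len, orientation = theta,
       bbox = c(min(x), min(y), max(x) + 1L, max(y) + 1L))
}

#' Measure shape features of a pixel set
#'
#' Computes the features the tracker's identity model is built on: the
#' centroid (mean of pixel centres), area (pixel count), the primary-axis
#' orientation (principal axis of the pixel-coordinate second-moment
#' matrix, in \[0, pi)), and the length across the primary axis
#' (peak-to-peak extent of pixel centres projected onto that axis, plus 1,
#' so a single pixel has length 1).
#'
#' @param pixels A two-column matrix or data frame of 0-based pixel
#'   coordinates (x = column, y = row).
#' @return A list with `x`, `y`, `area`, `length`, `orientation`, `bbox`
#'   (half-open `c(x0, y0, x1, y1)`).
#' @examples
#' measure_cluster(cbind(x = 0:4, y = rep(2, 5)))  # horizontal bar
#' @export
measure_cluster <- function(pixels) {
  pixels <- as.data.frame(pixels)
  if (nrow(pixels) == 0) abort("Empty pixel set.")
  names(pixels)[1:2] <- c("x", "y")
  measure_pixels(as.numeric(pixels$x), as.numeric(pixels$y))
}
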