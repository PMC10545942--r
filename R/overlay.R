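# 3x5 bitmap glyphs for digits, used to stamp track ids onto overlay frames
digit_glyphs <- local({
  rows <- c(
    "111101101101111",  # 0
    "010110010010111",  # 1
    "111001111100111",  # 2
    "111001111001111",  # 3
    "101101111001001",  # 4
    "111100111001111",  # 5
    "111100111101111",  # 6
    "111001001001001",  # 7
    "111101111101111",  # 8
    "111101111001111"   # 9
  )
  lapply(rows, function(s) {
    matrix(as.integer(strsplit(s, "")[[1]]) == 1L, nrow = 5, ncol = 3,
           byrow = TRUE)
  })
})

stamp_digits <- function(img, text, row, col, colour) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  for (ch in strsplit(text, "")[[1]]) {
    d <- suppressWarnings(as.integer(ch))
    if (!is.na(d)) {
      g <- digit_glyphs[[d + 1L]]
      for (r in 1:5) for (cc in 1:3) {
        if (g[r, cc]) {
          rr <- row + r - 1L
          c2 <- col + cc - 1L
          if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w) {
            img[rr, c2, ] <- colour
          }
        }
      }
    }
    col <- col + 4L
  }
  img
}

draw_line <- function(img, x0, y0, x1, y1, colour) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1L)
  xs <- round(seq(x0, x1, length.out = n)) + 1L
  ys <- round(seq(y0, y1, length.out = n)) + 1L
  ok <- xs >= 1 & xs <= dim(img)[2] & ys >= 1 & ys <= dim(img)[1]
  for (ch in 1:3) img[cbind(ys[ok], xs[ok], ch)] <- colour[ch]
  img
}

draw_cross <- function(img, x, y, colour, arm = 2L) {
  h <- dim(img)[1]
  w <- dim(img)[2]
  r <- round(y) + 1L
  c <- round(x) + 1L
  rr <- pmax(1L, pmin(h, r + (-arm:arm)))
  cc <- pmax(1L, pmin(w, c + (-arm:arm)))
  for (ch in 1:3) {
    img[cbind(rr, rep(c, length(rr)), ch)] <- colour[ch]
    img[cbind(rep(r, length(cc)), cc, ch)] <- colour[ch]
  }
  img
}

#' Render tracking overlays
#'
#' Annotates each frame with track centroids, trailing paths and track ids.
#' When per-frame stimulus states are supplied, trail segments are coloured
#' by the state under which they were recorded (red while the stimulus is
#' on, green while it is off) — the standard way to visualise light-coupled
#' behaviour directly on the tracks.
#'
#' @param frames A [frame_seq()] or list of matrices.
#' @param track_table Track table covering (a subset of) the frames.
#' @param states Optional numeric vector of per-frame stimulus values (from
#'   [frame_states()]).
#' @param trail Number of past positions drawn behind each track.
#' @return A list of `height x width x 3` RGB arrays in \[0, 1\].
#' @export
render_overlay <- function(frames, track_table, states = NULL, trail = 30L) {
  if (is.list(frames) && !inherits(frames, "frame_seq")) frames <- frame_seq(frames)
  on_col <- c(1, 0.15, 0.15)
  off_col <- c(0.15, 1, 0.3)
  id_col <- c(1, 1, 0.2)
  by_track <- if (nrow(track_table) > 0) split(track_table, track_table$track_id) else list()
  out <- vector("list", length(frames))
  for (i in seq_len(length(frames))) {
    g <- frame_at(frames, i)
    img <- array(g, c(dim(g), 3L))
    for (tt in by_track) {
      rows <- which(tt$frame <= i & tt$frame > i - 1L)
      if (length(rows) == 0) next
      hist <- tt[tt$frame <= i, ]
      hist <- tail(hist, trail)
      if (nrow(hist) >= 2) {
        for (k in 2:nrow(hist)) {
          col <- if (!is.null(states) && states[hist$frame[k]] > 0) on_col else off_col
          img <- draw_line(img, hist$x[k - 1], hist$y[k - 1],
                           hist$x[k], hist$y[k], col)
        }
      }
      cur <- tt[tt$frame == i, ]
      if (nrow(cur) == 1) {
        col <- if (!is.null(states) && states[i] > 0) on_col else off_col
        img <- draw_cross(img, cur$x, cur$y, col)
        img <- stamp_digits(img, as.character(cur$track_id),
                            row = round(cur$y) - 7L, col = round(cur$x) + 4L,
                            colour = id_col)
      }
    }
    out[[i]] <- img
  }
  out
}

write_overlay_frames <- function(overlays, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  width <- max(4L, nchar(length(overlays)))
  for (i in seq_along(overlays)) {
    png::writePNG(pmin(pmax(overlays[[i]], 0), 1),
                  file.path(dir, sprintf("overlay_%0*d.png", width, i)))
  }
  invisible(dir)
}
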