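#' Frame sequences
#'
#' A `frame_seq` is the package's container for a grayscale video: an ordered
#' set of frames, each a numeric matrix with intensities in \[0, 1\],
#' together with per-frame timestamps. Frames are fetched through an accessor
#' function, so a sequence can be backed by an in-memory list, by image files
#' on disk, or by a renderer that draws frames on demand (as the synthetic
#' arena generator does) — large videos never need to be held in memory at
#' once.
#'
#' @param frames A list of numeric matrices, all the same dimension, values
#'   in \[0, 1\].
#' @param fps Frames per second used to derive timestamps (`(i - 1) / fps`).
#' @param time_s Optional explicit timestamps (seconds), one per frame.
#' @return A `frame_seq` object.
#' @examples
#' fs <- frame_seq(list(matrix(0, 4, 4), matrix(1, 4, 4)), fps = 2)
#' length(fs)
#' frame_at(fs, 2)[1, 1]
#' @export
frame_seq <- function(frames, fps = 30, time_s = NULL) {
  if (!is.list(frames)) abort("`frames` must be a list of matrices.")
  if (length(frames) > 0) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), d),
                 logical(1))
    if (!all(ok)) abort("All frames must be matrices of identical dimensions.")
  } else {
    d <- c(0L, 0L)
  }
  new_frame_seq(
    n = length(frames), height = d[1], width = d[2], fps = fps,
    time_s = time_s %||% (seq_len(length(frames)) - 1) / fps,
    get = function(i) frames[[i]]
  )
}

new_frame_seq <- function(n, height, width, fps, time_s, get) {
  if (fps <= 0) abort("`fps` must be positive.")
  structure(
    list(n = as.integer(n), height = as.integer(height),
         width = as.integer(width), fps = fps, time_s = time_s, get = get),
    class = "frame_seq"
  )
}

#' @export
length.frame_seq <- function(x) x$n

#' @export
dim.frame_seq <- function(x) c(x$height, x$width)

#' @export
print.frame_seq <- function(x, ...) {
  cat(sprintf("<frame_seq: %d frames, %d x %d px, %.3g fps>\n",
              x$n, x$width, x$height, x$fps))
  invisible(x)
}

#' Fetch one frame from a frame sequence
#'
#' @param fs A [frame_seq()].
#' @param i Frame index (1-based).
#' @return A numeric matrix with values in \[0, 1\].
#' @export
frame_at <- function(fs, i) {
  if (!inherits(fs, "frame_seq")) abort("`fs` must be a frame_seq.")
  if (i < 1 || i > fs$n) abort(sprintf("Frame index %d out of range 1..%d.", i, fs$n))
  fs$get(i)
}

#' Per-frame timestamps of a frame sequence
#' @inheritParams frame_at
#' @return Numeric vector of times in seconds.
#' @export
frame_times <- function(fs) fs$time_s

#' Read a grayscale frame sequence from numbered image files
#'
#' Reads a directory of numbered PNG or TIFF images (lossless formats) as a
#' [frame_seq()]. Files are ordered by name; colour images are converted to
#' grayscale with the Rec. 601 luma weights; intensities are normalised to
#' \[0, 1\] regardless of source bit depth. Frames are loaded lazily, one
#' file per access.
#'
#' @param path Directory containing the image files, or a character vector of
#'   file paths.
#' @param fps Frames per second used for timestamps.
#' @return A [frame_seq()].
#' @export
read_frames <- function(path, fps = 30) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                        ignore.case = TRUE)
    files <- files[order(basename(files))]
  } else {
    files <- path
  }
  if (length(files) == 0L) abort(sprintf("No PNG/TIFF frames found at '%s'.", path[1]))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) abort(sprintf("Frame file not found: '%s'.", missing[1]))
  first <- read_image_gray(files[[1]])
  d <- dim(first)
  get <- function(i) {
    m <- read_image_gray(files[[i]])
    if (!identical(dim(m), d)) {
      abort(sprintf("Frame '%s' has dimensions %dx%d; expected %dx%d.",
                    basename(files[[i]]), dim(m)[1], dim(m)[2], d[1], d[2]))
    }
    m
  }
  new_frame_seq(n = length(files), height = d[1], width = d[2], fps = fps,
                time_s = (seq_along(files) - 1) / fps, get = get)
}

read_image_gray <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png = png::readPNG(file),
    tif = ,
    tiff = tiff::readTIFF(file),
    abort(sprintf("Unsupported image format '%s' (PNG/TIFF only).", ext))
  )
  if (length(dim(img)) == 3L) {
    # colour (or colour+alpha): Rec. 601 luma on the first three channels
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  img
}

#' Write a frame sequence as numbered PNG files
#'
#' Frames are quantised to 8-bit grayscale PNG (lossless). File names are
#' zero-padded so lexicographic order equals frame order.
#'
#' @inheritParams frame_at
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of file paths written.
#' @export
write_frames <- function(fs, dir, prefix = "frame") {
  if (!inherits(fs, "frame_seq")) abort("`fs` must be a frame_seq.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  width <- max(4L, nchar(as.character(fs$n)))
  paths <- character(fs$n)
  for (i in seq_len(fs$n)) {
    f <- pmin(pmax(frame_at(fs, i), 0), 1)
    paths[i] <- file.path(dir, sprintf("%s_%0*d.png", prefix, width, i))
    png::writePNG(f, paths[i])
  }
  invisible(paths)
}

#' Materialise a frame sequence as an in-memory list
#' @inheritParams frame_at
#' @return A list of matrices.
#' @export
as_frame_list <- function(fs) lapply(seq_len(fs$n), function(i) frame_at(fs, i))
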