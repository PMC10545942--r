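#' Pipeline configuration
#'
#' Bundles everything one tracking run needs. Any parameter left `NULL` that
#' the pipeline can estimate (currently the segmentation threshold) is
#' estimated from the data and logged as such, so the run log always records
#' each parameter's value and provenance (user vs estimated).
#'
#' @param input A [frame_seq()], a directory of numbered PNG/TIFF frames, or
#'   a vector of frame file paths.
#' @param output_dir Directory for outputs (created if needed); `NULL` for
#'   in-memory results only.
#' @param seg [segmentation_params()] (threshold may be `NULL` = estimate).
#' @param trk [tracker_params()].
#' @param mask Optional mask: a matrix or a path to a mask image (positive =
#'   keep).
#' @param stimulus_log Optional state-log CSV path or parsed log tibble.
#' @param drift Optional [drift_model()] applied to the stimulus log.
#' @param fps Frame rate used when reading frames from disk.
#' @param bg_samples Number of frames sampled for the median background.
#' @param overlay Write annotated overlay frames to `output_dir/overlay/`.
#' @param seed Seed recorded in the run log (the offline pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input, output_dir = NULL,
                            seg = segmentation_params(),
                            trk = tracker_params(max_move = 10),
                            mask = NULL, stimulus_log = NULL, drift = NULL,
                            fps = 30, bg_samples = 101, overlay = FALSE,
                            seed = 1L) {
  structure(list(input = input, output_dir = output_dir, seg = seg, trk = trk,
                 mask = mask, stimulus_log = stimulus_log, drift = drift,
                 fps = fps, bg_samples = bg_samples, overlay = overlay,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value config mirroring [pipeline_config()] arguments; nested
#' keys `seg:` and `trk:` hold the segmentation and tracker parameters.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' does not exist.", path))
  y <- yaml::read_yaml(path)
  seg <- do.call(segmentation_params, y$seg %||% list())
  trk <- do.call(tracker_params, y$trk %||% list(max_move = 10))
  pipeline_config(
    input = y$input, output_dir = y$output_dir,
    seg = seg, trk = trk, mask = y$mask, stimulus_log = y$stimulus_log,
    fps = y$fps %||% 30, bg_samples = y$bg_samples %||% 101,
    overlay = isTRUE(y$overlay), seed = y$seed %||% 1L
  )
}

# Otsu's threshold on a difference-image sample (256 bins); used as the
# estimation fallback when no threshold is configured, clamped to <= cap
# because arena recordings sit in the low-threshold regime.
otsu_threshold <- function(values, cap = 0.1) {
  h <- tabulate(pmin(pmax(floor(values * 255), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  thr <- (which.max(sigma_b) - 1) / 255
  min(thr, cap)
}

#' Run the end-to-end tracking pipeline
#'
#' Executes read -> median background -> subtract -> (mask) -> threshold ->
#' cluster -> track, then, when a stimulus log is supplied, aligns per-frame
#' stimulus states and computes per-epoch displacement and velocity
#' statistics. Results are returned in memory and, when `output_dir` is set,
#' written as `tracks.csv`, `epoch_stats.csv`, `run_log.yaml` and optional
#' overlay frames. Any stage error aborts with a stage-named message and
#' removes partial outputs.
#'
#' The run log records every parameter with its provenance and per-frame
#' stage counts; cluster conservation (`found = matched + merged + births +
#' dropped`) holds on every frame.
#'
#' @param config A [pipeline_config()].
#' @return A list with `tracks` (track table), `epoch_stats` (or `NULL`),
#'   `states` (per-frame stimulus values, or `NULL`), `background`,
#'   `run_log` (a list), and `paths` (files written).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  paths <- character(0)
  out_dir <- config$output_dir
  cleanup <- function() {
    if (length(paths) > 0) unlink(paths, recursive = TRUE, force = TRUE)
  }
  stage <- "input"
  tryCatch({
    frames <- config$input
    if (is.character(frames)) {
      if (length(frames) == 1 && !dir.exists(frames) && !file.exists(frames)) {
        abort(sprintf("Input path '%s' does not exist.", frames))
      }
      frames <- read_frames(frames, fps = config$fps)
    } else if (is.list(frames) && !inherits(frames, "frame_seq")) {
      frames <- frame_seq(frames, fps = config$fps)
    }

    mask <- config$mask
    if (is.character(mask)) mask <- read_image_gray(mask)

    stage <- "background"
    background <- median_background(frames, config$bg_samples)

    stage <- "threshold"
    seg <- config$seg
    threshold_provenance <- "user"
    if (is.null(seg$threshold)) {
      # estimate from the difference histogram of a frame sample
      n <- length(frames)
      idx <- unique(round(seq(1, n, length.out = min(9, n))))
      diffs <- unlist(lapply(idx, function(i) {
        d <- subtract_background(frame_at(frames, i), background)
        if (!is.null(mask)) d <- apply_mask(d, mask)
        as.vector(d)
      }))
      seg$threshold <- otsu_threshold(diffs)
      threshold_provenance <- "estimated"
    }

    stage <- "tracking"
    tracks <- track_animals(frames, seg, config$trk, mask = mask,
                            background = background)
    log <- attr(tracks, "log")

    stage <- "stimulus"
    states <- NULL
    stats_tbl <- NULL
    if (!is.null(config$stimulus_log)) {
      records <- config$stimulus_log
      if (is.character(records)) records <- parse_state_log(records)
      states <- frame_states(frame_times(frames), records, config$drift)
      stage <- "metrics"
      timeline <- tibble(time_s = frame_times(frames), value = states)
      if (nrow(tracks) > 0) stats_tbl <- epoch_stats(tracks, timeline)
    }

    stage <- "output"
    run_log <- list(
      parameters = list(
        threshold = seg$threshold, threshold_provenance = threshold_provenance,
        min_area = seg$min_area, max_area = seg$max_area,
        max_move = config$trk$max_move, min_active = config$trk$min_active,
        max_inactive = config$trk$max_inactive,
        merge_area = if (is.finite(config$trk$merge_area)) config$trk$merge_area
                     else seg$max_area,
        bg_samples = config$bg_samples, fps = config$fps, seed = config$seed
      ),
      counts = list(
        frames = length(frames),
        clusters_found = sum(vapply(log, function(a) a$n_clusters, numeric(1))),
        matched = sum(vapply(log, function(a) nrow(a$matches), numeric(1))),
        merged_into = sum(vapply(log, function(a) length(unique(a$merges$label)), numeric(1))),
        births = sum(vapply(log, function(a) length(a$births), numeric(1))),
        dropped = sum(vapply(log, function(a) length(a$dropped), numeric(1))),
        tracks_active = length(unique(tracks$track_id)),
        tracks_archived = sum(vapply(attr(tracks, "tracker")$tracks,
                                     function(t) t$status == "archived", logical(1)))
      ),
      per_frame = lapply(log, function(a) {
        list(frame = a$frame, found = a$n_clusters, matched = nrow(a$matches),
             merged = length(unique(a$merges$label)), births = length(a$births),
             dropped = length(a$dropped))
      })
    )

    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      p_tracks <- file.path(out_dir, "tracks.csv")
      paths <- c(paths, p_tracks)
      write_tracks_csv(tracks, p_tracks)
      if (!is.null(stats_tbl)) {
        p_stats <- file.path(out_dir, "epoch_stats.csv")
        paths <- c(paths, p_stats)
        write_epoch_stats_csv(stats_tbl, p_stats)
      }
      p_log <- file.path(out_dir, "run_log.yaml")
      paths <- c(paths, p_log)
      yaml::write_yaml(run_log, p_log)
      if (isTRUE(config$overlay)) {
        ov_dir <- file.path(out_dir, "overlay")
        paths <- c(paths, ov_dir)
        ov <- render_overlay(frames, tracks, states = states)
        write_overlay_frames(ov, ov_dir)
      }
    }
    list(tracks = tracks, epoch_stats = stats_tbl, states = states,
         background = background, run_log = run_log, paths = paths)
  }, error = function(e) {
    cleanup()
    abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
}

#' Write and read track tables as CSV
#'
#' Schema: `frame,time_s,track_id,x,y,area,length,merged,status`, one row per
#' (frame, track). Doubles are printed with 17 significant digits so the
#' round-trip is exact.
#'
#' @param track_table Track table tibble.
#' @param path Output file; `NULL` returns the CSV text.
#' @return `write_tracks_csv`: CSV text (invisibly when written);
#'   `read_tracks_csv`: the track table.
#' @export
write_tracks_csv <- function(track_table, path = NULL) {
  header <- "frame,time_s,track_id,x,y,area,length,merged,status"
  rows <- if (nrow(track_table) > 0) {
    sprintf("%d,%s,%d,%s,%s,%d,%s,%s,%s",
            track_table$frame, num17(track_table$time_s),
            track_table$track_id, num17(track_table$x), num17(track_table$y),
            track_table$area, num17(track_table$length),
            ifelse(track_table$merged, "TRUE", "FALSE"), track_table$status)
  } else character(0)
  txt <- paste(c(header, rows), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_tracks_csv
#' @param text_or_path CSV text (with a newline) or file path.
#' @export
read_tracks_csv <- function(text_or_path) {
  df <- read_csv_strict(text_or_path,
                        c("frame", "time_s", "track_id", "x", "y", "area",
                          "length", "merged", "status"))
  tibble(frame = as.integer(df$frame), time_s = as.numeric(df$time_s),
         track_id = as.integer(df$track_id), x = as.numeric(df$x),
         y = as.numeric(df$y), area = as.integer(df$area),
         length = as.numeric(df$length), merged = as.logical(df$merged),
         status = as.character(df$status))
}

write_epoch_stats_csv <- function(stats_tbl, path = NULL) {
  header <- "track_id,epoch_index,state,t_start,t_end,displacement,mean_velocity"
  rows <- if (nrow(stats_tbl) > 0) {
    sprintf("%d,%d,%s,%s,%s,%s,%s",
            stats_tbl$track_id, stats_tbl$epoch_index, stats_tbl$state,
            num17(stats_tbl$t_start), num17(stats_tbl$t_end),
            num17(stats_tbl$displacement), num17(stats_tbl$mean_velocity))
  } else character(0)
  txt <- paste(c(header, rows), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
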