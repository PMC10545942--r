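#' Stimulation protocol parameters
#'
#' Mirrors the knobs of the firmware-driven light protocols: light values are
#' bytes (0–255), `interval` is the protocol delay between steps or between
#' ON and OFF phases, and `interval_low` is the initial waiting period in the
#' off state before the first pulse.
#'
#' @param max_value Maximum ramp value (byte, 0–255).
#' @param interval Step/phase duration in seconds (> 0).
#' @param interval_low Initial off period in seconds (>= 0).
#' @param brightness Pulse intensity for blinking (byte, 0–255).
#' @return A `protocol_params` object.
#' @export
protocol_params <- function(max_value = 255L, interval = 0.1,
                            interval_low = 10, brightness = 255L) {
  if (max_value < 0 || max_value > 255) abort("`max_value` must be a byte (0-255).")
  if (brightness < 0 || brightness > 255) abort("`brightness` must be a byte (0-255).")
  if (interval <= 0) abort("`interval` must be positive.")
  if (interval_low < 0) abort("`interval_low` must be >= 0.")
  structure(list(max_value = as.integer(max_value), interval = interval,
                 interval_low = interval_low, brightness = as.integer(brightness)),
            class = "protocol_params")
}

new_stimulus_timeline <- function(time_s, value) {
  out <- tibble(time_s = time_s, value = as.integer(value))
  class(out) <- c("stimulus_timeline", class(out))
  out
}

#' Linear intensity ramp
#'
#' Generates the ramp protocol: the light value increases by exactly one byte
#' per step, from 0 up to `max_value`, with steps spaced `interval` seconds
#' apart (event `k` at time `k * interval` with value `k`). The value-0
#' starting event is included.
#'
#' @param params [protocol_params()] (only `max_value` and `interval` used).
#' @return A stimulus timeline: a tibble of step-change events
#'   (`time_s`, `value`), starting at time 0.
#' @examples
#' intensity_ramp(protocol_params(max_value = 5, interval = 0.1))
#' @export
intensity_ramp <- function(params = protocol_params()) {
  k <- 0:params$max_value
  new_stimulus_timeline(k * params$interval, k)
}

#' ON/OFF blinking protocol
#'
#' Generates fixed-intensity ON/OFF cycles: the light stays 0 during the
#' initial `interval_low` seconds, then alternates `brightness` and 0, each
#' phase lasting `interval` seconds, for `n_cycles` ON phases.
#'
#' @inheritParams intensity_ramp
#' @param n_cycles Number of ON phases (>= 1).
#' @return A stimulus timeline tibble (`time_s`, `value`).
#' @examples
#' blinking(protocol_params(interval = 20, interval_low = 0), n_cycles = 3)
#' @export
blinking <- function(params = protocol_params(), n_cycles = 1) {
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  k <- seq_len(n_cycles) - 1
  t_on <- params$interval_low + 2 * k * params$interval
  t_off <- params$interval_low + (2 * k + 1) * params$interval
  times <- as.vector(rbind(t_on, t_off))
  values <- rep(c(params$brightness, 0L), n_cycles)
  if (params$interval_low > 0) {
    times <- c(0, times)
    values <- c(0L, values)
  }
  new_stimulus_timeline(times, values)
}

#' Causal moving-average filter
#'
#' Trailing mean over the last `min(window, i)` samples at index `i`; output
#' length equals input length. Used to smooth noisy sensor signals (e.g.
#' ultrasonic distance readings) for easier interpretation.
#'
#' @param signal Numeric vector.
#' @param window Window length (>= 1).
#' @return Filtered numeric vector.
#' @export
moving_average <- function(signal, window) {
  if (window < 1) abort("`window` must be >= 1.")
  window <- as.integer(window)
  n <- length(signal)
  if (n == 0) return(numeric(0))
  cs <- cumsum(signal)
  out <- numeric(n)
  head_n <- min(window, n)
  out[seq_len(head_n)] <- cs[seq_len(head_n)] / seq_len(head_n)
  if (n > window) {
    i <- (window + 1L):n
    out[i] <- (cs[i] - cs[i - window]) / window
  }
  out
}

#' Clock-drift model between two controllers
#'
#' The acquisition computer and the stimulation controller run independent,
#' unsynchronised clocks; their relation is modelled as a constant-rate line
#' `device = slope * host + offset`. A drift of 3.96 s per hour corresponds
#' to `slope = 1 + 3.96/3600`.
#'
#' @param offset Offset in seconds.
#' @param slope Device-seconds per host-second (> 0).
#' @return A `drift_model` object.
#' @export
drift_model <- function(offset = 0, slope = 1) {
  if (slope <= 0) abort("`slope` must be positive.")
  structure(list(offset = offset, slope = slope), class = "drift_model")
}

#' @rdname drift_model
#' @param drift A `drift_model`.
#' @param t_device,t_host Times in seconds on the respective clocks.
#' @export
device_to_host <- function(drift, t_device) (t_device - drift$offset) / drift$slope

#' @rdname drift_model
#' @export
host_to_device <- function(drift, t_host) drift$slope * t_host + drift$offset

#' Simulate the timestamped state log
#'
#' Emulates the device reporting its current light value at a fixed period
#' (100 ms by default) over a serial link, with the receiving computer
#' stamping each report with its own clock: device sample times are mapped
#' to host time through the drift model, optionally perturbed by Gaussian
#' receive jitter, and written as `timestamp,value` CSV rows.
#'
#' @param timeline A stimulus timeline tibble (`time_s`, `value`), times on
#'   the device clock.
#' @param drift A [drift_model()] (identity by default).
#' @param sample_period_s Reporting period in device seconds.
#' @param jitter_sd Gaussian jitter SD (seconds) added to host stamps.
#' @param seed Seed for the jitter stream.
#' @param path Output file; `NULL` returns the CSV text.
#' @return CSV text (invisibly when written to a file).
#' @export
write_state_log <- function(timeline, drift = drift_model(),
                            sample_period_s = 0.1, jitter_sd = 0, seed = 1,
                            path = NULL) {
  if (sample_period_s <= 0) abort("`sample_period_s` must be positive.")
  t_end <- max(timeline$time_s)
  device_t <- seq(0, t_end, by = sample_period_s)
  if (device_t[length(device_t)] < t_end) device_t <- c(device_t, t_end)
  values <- timeline_value_at(timeline, device_t)
  host_t <- device_to_host(drift, device_t)
  if (jitter_sd > 0) {
    host_t <- host_t + with_private_seed(seed, rnorm(length(host_t), 0, jitter_sd))
  }
  txt <- paste(c("timestamp,value",
                 sprintf("%.9f,%d", host_t, values)), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# step-function lookup: value of the latest event at or before each time
timeline_value_at <- function(timeline, t) {
  k <- findInterval(t, timeline$time_s)
  out <- rep(0L, length(t))
  out[k > 0] <- timeline$value[k[k > 0]]
  out
}

#' Parse a timestamped state log
#'
#' Reads the `timestamp,value` CSV produced by the acquisition computer (or
#' by [write_state_log()]). Malformed rows raise an error naming the line.
#'
#' @param text_or_path CSV text (containing a newline) or a file path.
#' @return A tibble with columns `host_time_s`, `value`, in file order.
#' @export
parse_state_log <- function(text_or_path) {
  lines <- if (length(text_or_path) == 1L && grepl("\n", text_or_path)) {
    strsplit(text_or_path, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(text_or_path)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("State log is empty (no header).")
  header <- tolower(gsub("\\s", "", lines[1]))
  if (!identical(strsplit(header, ",")[[1]][1:2], c("timestamp", "value"))) {
    abort("State log must start with a 'timestamp,value' header.")
  }
  if (length(lines) == 1) return(tibble(host_time_s = numeric(), value = numeric()))
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  ts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  vl <- suppressWarnings(as.numeric(vapply(parts, function(p) p[2] %||% NA_character_, "")))
  bad <- which(lengths(parts) != 2L | is.na(ts) | is.na(vl))
  if (length(bad) > 0) {
    abort(sprintf("Unparseable state-log row at line %d: '%s'.",
                  bad[1] + 1L, body[bad[1]]))
  }
  tibble(host_time_s = ts, value = vl)
}

#' Estimate clock drift from paired timestamps
#'
#' Least-squares fit of the line `device = slope * host + offset`. Applied
#' to the (host timestamp, device-reported time) pairs of a state log, this
#' recovers the constant-rate divergence of the two clocks so that device
#' times can be corrected onto the host clock during analysis.
#'
#' @param device_times,host_times Paired times in seconds (>= 2 pairs).
#' @return A [drift_model()].
#' @examples
#' host <- seq(0, 3600, by = 10)
#' dev <- host * (1 + 3.96 / 3600)
#' estimate_drift(dev, host)
#' @export
estimate_drift <- function(device_times, host_times) {
  if (length(device_times) != length(host_times)) {
    abort("`device_times` and `host_times` must have equal length.")
  }
  if (length(device_times) < 2) abort("Need at least 2 paired times.")
  if (var(device_times) == 0 || var(host_times) == 0) {
    abort("Degenerate input: times must not be all equal.")
  }
  fit <- stats::lm.fit(cbind(1, host_times), device_times)
  drift_model(offset = unname(fit$coefficients[1]),
              slope = unname(fit$coefficients[2]))
}

#' Stimulus state at each video frame
#'
#' Assigns each frame the value of the latest log record at or before its
#' timestamp (frames before the first record get 0). When `drift` is given,
#' record times are taken to be on the device clock and are mapped onto the
#' frame (host) clock first.
#'
#' @param frame_times Frame timestamps in seconds (host clock).
#' @param records Log tibble (`host_time_s`, `value`) from [parse_state_log()].
#' @param drift Optional [drift_model()] if record times are device-stamped.
#' @return Numeric vector of per-frame state values.
#' @export
frame_states <- function(frame_times, records, drift = NULL) {
  if (nrow(records) == 0) abort("`records` must be non-empty.")
  t <- records$host_time_s
  if (!is.null(drift)) t <- device_to_host(drift, t)
  o <- order(t)
  t <- t[o]
  v <- records$value[o]
  k <- findInterval(frame_times, t)
  out <- numeric(length(frame_times))
  out[k > 0] <- v[k[k > 0]]
  out
}
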