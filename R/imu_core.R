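#' falldetect: two-stage smartphone fall detection
#'
#' Segments irregularly sampled smartphone accelerometer/gyroscope streams
#' into 5-second windows, screens them with a 2 g peak-acceleration gate,
#' classifies screened windows with an elastic-net logistic regression, and
#' evaluates the resulting detector with deployment-style metrics. A seeded
#' synthetic IMU generator makes the whole pipeline testable end to end.
#'
#' @keywords internal
"_PACKAGE"

# Window geometry used throughout: 5-s half-open windows [t0, t0 + 5000) ms,
# resampled to 250 points at 20 ms spacing (50 Hz).
WINDOW_MS <- 5000L
GRID_STEP_MS <- 20L
GRID_N <- 250L
MIN_SAMPLES <- 200L
MAX_GAP_MS <- 200L

IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

#' Construct an IMU recording
#'
#' A recording is one participant's timestamped 6-axis sensor stream:
#' tri-axial acceleration in g (gravity-inclusive) and tri-axial angular
#' velocity in rad/s, indexed by integer milliseconds. Samples are sorted by
#' time; duplicate timestamps keep the first occurrence.
#'
#' @param samples data.frame with columns `t`, `ax`, `ay`, `az`,
#'   `gx`, `gy`, `gz` (time in ms; acceleration in g; gyro in rad/s).
#' @param participant_id opaque participant identifier.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(samples, participant_id = "unknown") {
  required <- c("t", IMU_CHANNELS)
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L) {
    stop("samples is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  samples <- as.data.frame(samples)[required]
  for (col in required) samples[[col]] <- as.numeric(samples[[col]])
  bad <- !stats::complete.cases(samples) |
    !is.finite(rowSums(samples[IMU_CHANNELS]))
  if (any(bad)) {
    message(sum(bad), " sample(s) with non-finite values dropped")
    samples <- samples[!bad, , drop = FALSE]
  }
  if (any(samples$t < 0)) stop("negative timestamps are not allowed")
  samples <- samples[order(samples$t), , drop = FALSE]
  dup <- duplicated(samples$t)
  if (any(dup)) {
    message(sum(dup), " duplicate timestamp(s) dropped (first kept)")
    samples <- samples[!dup, , drop = FALSE]
  }
  rownames(samples) <- NULL
  structure(
    list(participant_id = as.character(participant_id), samples = samples),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat("<imu_recording> participant", x$participant_id, "-", n, "samples")
  if (n > 0L) {
    span <- (x$samples$t[n] - x$samples$t[1]) / 1000
    cat(sprintf(", %.1f s span, ~%.1f Hz", span,
                if (span > 0) (n - 1) / span else NA_real_))
  }
  cat("\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param recording an `imu_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(recording) nrow(recording$samples)

#' Read a recording from CSV
#'
#' Expects the dialect `t_ms,ax_g,ay_g,az_g,gx_rads,gy_rads,gz_rads` with one
#' row per sample. Rows with non-finite values are dropped with a message.
#'
#' @param path CSV file path.
#' @param participant_id identifier to attach to the recording.
#' @return An `imu_recording`.
#' @export
read_recording <- function(path, participant_id = "unknown") {
  if (!file.exists(path)) stop("recording file not found: ", path)
  header <- c("t_ms", "ax_g", "ay_g", "az_g", "gx_rads", "gy_rads", "gz_rads")
  first <- readLines(path, n = 1L)
  got <- strsplit(trimws(first), ",")[[1]]
  if (!identical(trimws(got), header)) {
    stop("malformed header at line 1 of ", path,
         " (expected ", paste(header, collapse = ","), ")")
  }
  raw <- utils::read.csv(path, colClasses = "character")
  names(raw) <- c("t", IMU_CHANNELS)
  num <- as.data.frame(lapply(raw, function(col) {
    suppressWarnings(as.numeric(col))
  }))
  # a field that is non-empty but non-numeric is a parse error, not a drop
  for (j in seq_along(num)) {
    bad_parse <- is.na(num[[j]]) & !(raw[[j]] %in% c("", "NA", "nan", "NaN", "inf", "-inf", "Inf", "-Inf"))
    if (any(bad_parse)) {
      stop("non-numeric value in column '", names(raw)[j], "' at line ",
           which(bad_parse)[1] + 1L, " of ", path)
    }
  }
  imu_recording(num, participant_id)
}

#' Write a recording to CSV
#' @param recording an `imu_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  out <- recording$samples
  names(out) <- c("t_ms", "ax_g", "ay_g", "az_g", "gx_rads", "gy_rads", "gz_rads")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-row Euclidean norm of a tri-axial series
#'
#' The signal magnitude vector (SMV): `sqrt(x^2 + y^2 + z^2)` per sample,
#' gravity-inclusive for acceleration.
#'
#' @param series numeric N x 3 matrix (or data.frame).
#' @return length-N numeric vector.
#' @export
magnitude <- function(series) {
  m <- as.matrix(series)
  if (ncol(m) != 3L) stop("series must have 3 columns")
  sqrt(rowSums(m * m))
}

#' Locate the fall impact near a labeled timestamp
#'
#' The impact is the sample maximizing acceleration magnitude within the
#' closed interval `t_label` +/- 2.5 s; ties break to the earliest timestamp.
#'
#' @param recording an `imu_recording`.
#' @param t_label researcher-logged fall timestamp (ms).
#' @param half_width_ms search half-width, default 2500 ms.
#' @return impact timestamp (ms).
#' @export
locate_impact <- function(recording, t_label, half_width_ms = 2500) {
  s <- recording$samples
  keep <- s$t >= t_label - half_width_ms & s$t <= t_label + half_width_ms
  if (!any(keep)) {
    stop("impact not found: no samples within ", half_width_ms,
         " ms of t_label = ", t_label)
  }
  sub <- s[keep, , drop = FALSE]
  mag <- magnitude(sub[c("ax", "ay", "az")])
  sub$t[which.max(mag)]  # which.max returns the first (earliest) maximum
}

new_sensor_window <- function(t_start, raw, label = "unlabeled",
                              source_id = NA_character_) {
  structure(
    list(
      t_start = as.numeric(t_start),
      t_end = as.numeric(t_start) + WINDOW_MS,
      raw = raw,
      valid = NA,
      accel_interp = NULL,
      gyro_interp = NULL,
      label = label,
      source_id = source_id
    ),
    class = "sensor_window"
  )
}

#' @export
print.sensor_window <- function(x, ...) {
  cat(sprintf("<sensor_window> [%s, %s) ms, %d raw samples, valid = %s, label = %s\n",
              format(x$t_start, scientific = FALSE),
              format(x$t_end, scientific = FALSE),
              nrow(x$raw), as.character(x$valid), x$label))
  invisible(x)
}

#' Cut a 5-second window from a recording
#'
#' Collects raw samples in the half-open span `[t_start, t_start + 5000)` ms,
#' applies the quality gate and, when it passes, interpolates both sensors to
#' the 250-point 50 Hz grid.
#'
#' @param recording an `imu_recording`.
#' @param t_start window start (ms).
#' @param label window label: `"fall"`, `"non_fall"` or `"unlabeled"`.
#' @param process if `FALSE`, skip quality gating/interpolation (valid stays NA).
#' @return A `sensor_window`.
#' @export
cut_window <- function(recording, t_start, label = "unlabeled", process = TRUE) {
  s <- recording$samples
  i0 <- findInterval(t_start - 0.5, s$t) + 1L
  i1 <- findInterval(t_start + WINDOW_MS - 0.5, s$t)
  raw <- if (i0 <= i1) s[i0:i1, , drop = FALSE] else s[0L, , drop = FALSE]
  rownames(raw) <- NULL
  w <- new_sensor_window(t_start, raw, label = label,
                         source_id = paste0(recording$participant_id, ":",
                                            format(t_start, scientific = FALSE)))
  if (process) {
    w <- quality_check(w)
    if (w$valid) w <- interpolate_window(w)
  }
  w
}

#' Quality gate for a 5-second window
#'
#' A window is usable iff it holds at least 200 raw samples and no gap between
#' consecutive timestamps exceeds 200 ms. The gap rule is extended to the
#' window edges: the first sample must lie within 200 ms of `t_start` and the
#' last within 200 ms of `t_end`, so interpolation never extrapolates across
#' more than 200 ms.
#'
#' @param window a `sensor_window`.
#' @return The window with its `valid` flag set.
#' @export
quality_check <- function(window) {
  t <- window$raw$t
  window$valid <-
    length(t) >= MIN_SAMPLES &&
    (length(t) < 2L || max(diff(t)) <= MAX_GAP_MS) &&
    (t[1] - window$t_start) <= MAX_GAP_MS &&
    (window$t_end - t[length(t)]) <= MAX_GAP_MS
  if (!window$valid) {
    window$accel_interp <- NULL
    window$gyro_interp <- NULL
  }
  window
}

#' Resample a valid window onto the 50 Hz grid
#'
#' Each of the six channels is linearly interpolated onto
#' `t_start + 20k` ms, k = 0..249. Grid points outside the raw time span take
#' the nearest raw value (constant extrapolation). No filtering or smoothing
#' is applied.
#'
#' @param window a `sensor_window` whose quality gate passed.
#' @return The window with `accel_interp` and `gyro_interp` set (250 x 3).
#' @export
interpolate_window <- function(window) {
  if (!isTRUE(window$valid)) {
    stop("interpolate_window called on a window that failed the quality gate")
  }
  grid <- window$t_start + GRID_STEP_MS * (seq_len(GRID_N) - 1)
  t <- window$raw$t
  interp1 <- function(y) stats::approx(t, y, xout = grid, method = "linear",
                                       rule = 2, ties = "ordered")$y
  acc <- vapply(c("ax", "ay", "az"), function(ch) interp1(window$raw[[ch]]),
                numeric(GRID_N))
  gyr <- vapply(c("gx", "gy", "gz"), function(ch) interp1(window$raw[[ch]]),
                numeric(GRID_N))
  dimnames(acc) <- list(NULL, c("x", "y", "z"))
  dimnames(gyr) <- list(NULL, c("x", "y", "z"))
  window$accel_interp <- acc
  window$gyro_interp <- gyr
  window
}

#' Randomly offset fall windows around an impact
#'
#' For one fall impact, draws `n` window start times uniformly from
#' `[t_impact - 4999, t_impact]` ms so the impact sample lies inside every
#' window, placing the impact at varying positions (start, middle, end).
#' Windows failing the quality gate are kept but flagged invalid.
#'
#' @param recording an `imu_recording`.
#' @param t_impact impact timestamp (ms).
#' @param n number of windows (default 10).
#' @param seed optional integer seed for reproducible draws.
#' @return List of `sensor_window`s labeled `"fall"`.
#' @export
augment_fall_windows <- function(recording, t_impact, n = 10L, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  offsets <- sample.int(WINDOW_MS, n, replace = TRUE) - 1L  # 0..4999
  starts <- t_impact - offsets
  lapply(starts, function(t0) cut_window(recording, t0, label = "fall"))
}

#' Segment a recording into tumbling 5-second windows
#'
#' Non-overlapping consecutive windows tile the recording, starting at the
#' first sample's timestamp rounded down to the whole second. Every window is
#' quality-gated and, when valid, interpolated.
#'
#' @param recording an `imu_recording`.
#' @return List of `sensor_window`s (possibly empty).
#' @export
tumbling_windows <- function(recording) {
  s <- recording$samples
  if (nrow(s) == 0L) return(list())
  t0 <- floor(s$t[1] / 1000) * 1000
  idx <- floor((s$t - t0) / WINDOW_MS)
  n_win <- max(idx) + 1L
  groups <- split(seq_len(nrow(s)), factor(idx, levels = 0:(n_win - 1L)))
  lapply(seq_len(n_win), function(k) {
    rows <- groups[[k]]
    raw <- s[rows, , drop = FALSE]
    rownames(raw) <- NULL
    t_start <- t0 + (k - 1L) * WINDOW_MS
    w <- new_sensor_window(t_start, raw,
                           source_id = paste0(recording$participant_id, ":",
                                              format(t_start, scientific = FALSE)))
    w <- quality_check(w)
    if (w$valid) w <- interpolate_window(w)
    w
  })
}
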