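# The deployed two-stage online detector: a cheap high-sensitivity screen
# (peak interpolated acceleration magnitude > 2 g) and, only for screened
# windows, the elastic-net posterior with the calibrated alert cutoff.

ACCEL_SCREEN_G <- 2.0
POTENTIAL_BAND <- 0.5
RETENTION_MS <- 15 * 60 * 1000

#' First-stage acceleration screen
#'
#' Passes iff the peak of the interpolated accelerometer magnitude series
#' strictly exceeds 2 g. The screen exists to spare the classifier from the
#' overwhelmingly sub-2 g background of daily living while keeping every
#' plausible impact.
#'
#' @param window a valid, interpolated `sensor_window`.
#' @return logical.
#' @export
stage1_screen <- function(window) {
  if (!isTRUE(window$valid) || is.null(window$accel_interp)) {
    stop("stage1_screen requires a valid, interpolated window")
  }
  max(magnitude(window$accel_interp)) > ACCEL_SCREEN_G
}

unknown_context <- function(t_start) {
  list(
    timestamp = format(as.POSIXct(t_start / 1000, origin = "1970-01-01",
                                  tz = "UTC"), "%Y-%m-%dT%H:%M:%OS3Z"),
    lat = NA_real_, lon = NA_real_,
    speed_before = NA_real_,
    weather = "unknown",
    activity = "unknown", activity_confidence = NA_real_
  )
}

#' Context providers
#'
#' A context provider enriches alert events with the portal record fields:
#' `locate(t)` returns `c(lat, lon)`, `lookup(t, location)` a weather
#' category (`clear`, `cloudy`, `rainy`, `snowy`, `unknown`),
#' `classify(t)` a `list(activity =, confidence =)`, and `speed(t)` the mean
#' movement speed (m/s) over the five minutes before `t`. Providers must be
#' total; any failure degrades to `unknown`, never to an error.
#' `null_provider()` answers unknown to everything; `stub_provider()` returns
#' the fixed values it is given (the stand-in for external weather/activity
#' services, which are out of scope).
#'
#' @param weather,activity,confidence,location,speed_before fixed stub values.
#' @return a provider (list of closures).
#' @export
null_provider <- function() {
  list(
    locate = function(t) c(NA_real_, NA_real_),
    lookup = function(t, location) "unknown",
    classify = function(t) list(activity = "unknown", confidence = NA_real_),
    speed = function(t) NA_real_
  )
}

#' @rdname null_provider
#' @export
stub_provider <- function(weather = "clear", activity = "on_foot",
                          confidence = 0.9, location = c(41.89, -87.62),
                          speed_before = 0.8) {
  list(
    locate = function(t) location,
    lookup = function(t, location) weather,
    classify = function(t) list(activity = activity, confidence = confidence),
    speed = function(t) speed_before
  )
}

event_row <- function(participant_id, window, stage1_pass, posterior, status,
                      failed, peak, peak_raw, context) {
  data.frame(
    participant_id = participant_id,
    t_start = window$t_start,
    posterior = posterior,
    stage1_pass = stage1_pass,
    status = status,
    failed = failed,
    peak_accel = peak,
    peak_accel_raw = peak_raw,
    timestamp = context$timestamp,
    lat = context$lat, lon = context$lon,
    speed_before = context$speed_before,
    weather = context$weather,
    activity = context$activity,
    activity_confidence = context$activity_confidence,
    stringsAsFactors = FALSE
  )
}

#' Classify one window with the two-stage detector
#'
#' A total function: windows that failed the quality gate yield a
#' processing-failure record (status `none`, `failed = TRUE`); windows below
#' the 2 g screen yield status `none` with no posterior computed; screened
#' windows get a posterior, with status `alert` when it strictly exceeds the
#' model threshold and `potential` when it lies in (0.5, threshold].
#'
#' @param window a `sensor_window` (valid or not).
#' @param model a fitted `enet_model`.
#' @param participant_id identifier recorded on the event.
#' @return one-row data.frame (a detection event record).
#' @export
classify_window <- function(window, model, participant_id = "unknown") {
  ctx <- unknown_context(window$t_start)
  peak_raw <- if (nrow(window$raw) > 0L) {
    max(magnitude(window$raw[c("ax", "ay", "az")]))
  } else NA_real_
  if (!isTRUE(window$valid)) {
    return(event_row(participant_id, window, stage1_pass = NA,
                     posterior = NA_real_, status = "none", failed = TRUE,
                     peak = NA_real_, peak_raw = peak_raw, context = ctx))
  }
  peak <- max(magnitude(window$accel_interp))
  if (peak <= ACCEL_SCREEN_G) {
    return(event_row(participant_id, window, stage1_pass = FALSE,
                     posterior = NA_real_, status = "none", failed = FALSE,
                     peak = peak, peak_raw = peak_raw, context = ctx))
  }
  post <- predict_posterior(model, compute_features(window))
  status <- if (post > model$threshold) "alert"
            else if (post > POTENTIAL_BAND) "potential"
            else "none"
  event_row(participant_id, window, stage1_pass = TRUE, posterior = post,
            status = status, failed = FALSE, peak = peak,
            peak_raw = peak_raw, context = ctx)
}

#' Stream a recording through the detector
#'
#' Segments the recording into tumbling 5-s windows, classifies each, and for
#' every alert enriches the record through the context provider and invokes
#' `alert_hook` exactly once (hook errors are logged and isolated - the
#' stream continues). Events are returned time-ordered, one row per window.
#'
#' @param recording an `imu_recording`.
#' @param model a fitted `enet_model`.
#' @param provider a context provider (default [null_provider()]).
#' @param alert_hook optional `function(event_row)` called per alert.
#' @return data.frame of detection events (one row per window).
#' @export
stream_detect <- function(recording, model, provider = null_provider(),
                          alert_hook = NULL) {
  windows <- tumbling_windows(recording)
  if (length(windows) == 0L) {
    return(classify_window(new_sensor_window(0, recording$samples[0L, ]),
                           model)[0L, ])
  }
  rows <- lapply(windows, classify_window, model = model,
                 participant_id = recording$participant_id)
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  for (i in which(events$status == "alert")) {
    t <- events$t_start[i]
    ctx <- enrich_context(provider, t)
    events[i, names(ctx)] <- ctx
    if (!is.null(alert_hook)) {
      tryCatch(alert_hook(events[i, , drop = FALSE]),
               error = function(e) {
                 message("alert hook failed at t_start = ", t, ": ",
                         conditionMessage(e))
               })
    }
  }
  events
}

enrich_context <- function(provider, t_start) {
  safe <- function(expr, fallback) {
    tryCatch(expr, error = function(e) fallback)
  }
  loc <- safe(provider$locate(t_start), c(NA_real_, NA_real_))
  if (!is.numeric(loc) || length(loc) != 2L) loc <- c(NA_real_, NA_real_)
  weather <- safe(provider$lookup(t_start, loc), "unknown")
  if (!is.character(weather) ||
      !weather %in% c("clear", "cloudy", "rainy", "snowy", "unknown")) {
    weather <- "unknown"
  }
  act <- safe(provider$classify(t_start),
              list(activity = "unknown", confidence = NA_real_))
  conf <- suppressWarnings(as.numeric(act$confidence))
  if (length(conf) != 1L || (!is.na(conf) && (conf < 0 || conf > 1))) {
    conf <- NA_real_
  }
  ctx <- unknown_context(t_start)
  ctx$lat <- loc[1]
  ctx$lon <- loc[2]
  ctx$weather <- weather
  ctx$activity <- if (is.character(act$activity)) act$activity else "unknown"
  ctx$activity_confidence <- conf
  ctx$speed_before <- safe(suppressWarnings(as.numeric(provider$speed(t_start))),
                           NA_real_)
  ctx
}

#' Retention rule for transmitted windows
#'
#' A window is transmitted iff its start lies within 15 minutes (closed
#' interval) of the start of some event with posterior > 0.5 - the
#' battery/data-saving rule of the deployed system.
#'
#' @param events detection-event data.frame (from [stream_detect()]).
#' @param windows list of `sensor_window`s or numeric vector of window starts.
#' @param retention_ms retention half-width (default 15 min).
#' @return character vector of retained window ids (for `sensor_window`
#'   input) or the retained start times.
#' @export
retention_filter <- function(events, windows, retention_ms = RETENTION_MS) {
  anchors <- events$t_start[!is.na(events$posterior) &
                              events$posterior > POTENTIAL_BAND]
  if (is.list(windows)) {
    starts <- vapply(windows, function(w) w$t_start, numeric(1))
    ids <- vapply(windows, function(w) w$source_id, character(1))
  } else {
    starts <- as.numeric(windows)
    ids <- starts
  }
  if (length(anchors) == 0L) return(ids[0L])
  keep <- vapply(starts, function(t0) any(abs(t0 - anchors) <= retention_ms),
                 logical(1))
  ids[keep]
}

#' Write / read a detection-event log (JSON lines)
#'
#' One JSON object per line per event, carrying every context field plus a
#' `schema_version`.
#'
#' @param events detection-event data.frame.
#' @param path `.jsonl` path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_event_log <- function(events, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    rec <- as.list(events[i, ])
    rec$schema_version <- 1L
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec$schema_version <- NULL
    rec[vapply(rec, is.null, logical(1))] <- NA
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
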