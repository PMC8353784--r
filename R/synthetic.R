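# Seeded generator of labeled smartphone IMU recordings: ambulation and rest
# (ADLs), falls (free-fall -> impact -> rest), stumbles, phone drops and
# sit/stand transitions, with the sampling pathologies of a phone sensor
# stream (timestamp jitter, dropout gaps). Orientation is modelled as a
# slowly varying rotation of the gravity vector - no rigid-body dynamics.

#' Synthetic study configuration
#'
#' Defaults emulate the deployment regime this package targets: 23
#' participants carrying a phone 10 h/day for 90 days at a nominal 50 Hz,
#' with roughly two falls and a couple of fall-like confounders per
#' participant over the period. Signal-shape defaults (3-6 g impacts,
#' 300-500 ms free-fall, sub-2 g ambulation) are chosen so the 2 g screen
#' separates impacts from daily living.
#'
#' @param n_participants participants to simulate.
#' @param days recording days per participant.
#' @param hours_per_day worn hours per day.
#' @param nominal_rate_hz nominal sampling rate.
#' @param timestamp_jitter_ms Gaussian jitter SD on sample times.
#' @param dropout_prob per-second probability of a dropout gap.
#' @param dropout_len_ms dropout length range (ms).
#' @param falls_per_participant,stumbles_per_participant,drops_per_participant
#'   planted event counts per participant.
#' @param impact_peak_g fall impact peak range (g).
#' @param drop_peak_g phone-drop impact peak range (g).
#' @param stumble_peak_g stumble spike peak range (g).
#' @param freefall_ms fall free-fall duration range (ms).
#' @param walk_amp_g gait acceleration amplitude range (g).
#' @param walk_freq_hz gait frequency range (Hz).
#' @param noise_std_g per-axis Gaussian sensor noise SD (g).
#' @param gyro_burst_rads fall rotation-burst peak range (rad/s).
#' @param seed integer seed; generation is fully determined by it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 23L,
                             days = 90L,
                             hours_per_day = 10,
                             nominal_rate_hz = 50,
                             timestamp_jitter_ms = 3,
                             dropout_prob = 0.001,
                             dropout_len_ms = c(250, 1000),
                             falls_per_participant = 2L,
                             stumbles_per_participant = 2L,
                             drops_per_participant = 2L,
                             impact_peak_g = c(3, 6),
                             drop_peak_g = c(2.5, 6),
                             stumble_peak_g = c(1.8, 3.0),
                             freefall_ms = c(300, 500),
                             walk_amp_g = c(0.2, 0.8),
                             walk_freq_hz = c(1.5, 2.5),
                             noise_std_g = 0.03,
                             gyro_burst_rads = c(3, 8),
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), days = as.integer(days),
    hours_per_day = hours_per_day, nominal_rate_hz = nominal_rate_hz,
    timestamp_jitter_ms = timestamp_jitter_ms, dropout_prob = dropout_prob,
    dropout_len_ms = dropout_len_ms,
    falls_per_participant = as.integer(falls_per_participant),
    stumbles_per_participant = as.integer(stumbles_per_participant),
    drops_per_participant = as.integer(drops_per_participant),
    impact_peak_g = impact_peak_g, drop_peak_g = drop_peak_g,
    stumble_peak_g = stumble_peak_g, freefall_ms = freefall_ms,
    walk_amp_g = walk_amp_g, walk_freq_hz = walk_freq_hz,
    noise_std_g = noise_std_g, gyro_burst_rads = gyro_burst_rads,
    seed = as.integer(seed)
  )
  ranges <- c("dropout_len_ms", "impact_peak_g", "drop_peak_g",
              "stumble_peak_g", "freefall_ms", "walk_amp_g", "walk_freq_hz",
              "gyro_burst_rads")
  for (r in ranges) {
    if (length(cfg[[r]]) != 2L || cfg[[r]][1] > cfg[[r]][2]) {
      stop(r, " must be an ordered range c(lo, hi)")
    }
  }
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0, 1]")
  if (nominal_rate_hz <= 0 || hours_per_day <= 0) {
    stop("rates and durations must be positive")
  }
  structure(cfg, class = "synthetic_config")
}

# irregular sample times on [0, duration_ms): nominal grid + Gaussian jitter,
# with dropout gaps removed; dropout segments are declared in the attribute
gen_timestamps <- function(duration_ms, config) {
  step <- 1000 / config$nominal_rate_hz
  nominal <- seq(0, duration_ms - step, by = step)
  ts <- round(nominal + stats::rnorm(length(nominal), 0, config$timestamp_jitter_ms))
  ts <- sort(ts)
  ts <- ts[ts >= 0 & ts < duration_ms]
  ts <- ts[!duplicated(ts)]
  dropouts <- NULL
  n_sec <- floor(duration_ms / 1000)
  if (config$dropout_prob > 0 && n_sec > 0) {
    hit <- which(stats::runif(n_sec) < config$dropout_prob)
    if (length(hit) > 0L) {
      len <- stats::runif(length(hit), config$dropout_len_ms[1],
                          config$dropout_len_ms[2])
      from <- (hit - 1) * 1000
      to <- from + len
      dropouts <- data.frame(from = from, to = to)
      keep <- rep(TRUE, length(ts))
      for (i in seq_len(nrow(dropouts))) {
        keep <- keep & !(ts >= dropouts$from[i] & ts < dropouts$to[i])
      }
      ts <- ts[keep]
    }
  }
  attr(ts, "dropouts") <- dropouts
  ts
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# orthonormal pair perpendicular to u
perp_basis <- function(u) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2] * a[3] - u[3] * a[2],
          u[3] * a[1] - u[1] * a[3],
          u[1] * a[2] - u[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# accel rows = m(t) * u(t) + wobble + noise, for scalar magnitude profile m
# and per-row unit direction matrix U (n x 3)
compose_accel <- function(m, U, wobble, noise_sd) {
  n <- length(m)
  acc <- U * m
  acc <- acc + wobble
  acc + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
}

# slowly drifting gravity direction around u0 (n x 3, unit rows)
drift_directions <- function(t_s, u0, drift_amp = 0.08) {
  b <- perp_basis(u0)
  f1 <- stats::runif(1, 0.005, 0.02)
  f2 <- stats::runif(1, 0.005, 0.02)
  ph <- stats::runif(2, 0, 2 * pi)
  c1 <- drift_amp * sin(2 * pi * f1 * t_s + ph[1])
  c2 <- drift_amp * sin(2 * pi * f2 * t_s + ph[2])
  U <- outer(rep(1, length(t_s)), u0) + outer(c1, b$e1) + outer(c2, b$e2)
  U / sqrt(rowSums(U^2))
}

#' Generate an ambulation / rest (ADL) segment
#'
#' Alternating rest epochs (magnitude near 1 g, slow orientation drift) and
#' walking epochs (1 g baseline plus a sinusoidal gait component with a
#' gait-band gyroscope oscillation), on a jittered 50 Hz grid with dropout
#' gaps. Consumes the session RNG stream; seed at the caller (or use
#' [gen_study()]).
#'
#' @param duration_ms segment duration (ms).
#' @param config a `synthetic_config`.
#' @return data.frame of samples (`t` relative ms, six channels), with any
#'   dropout segments in `attr(, "dropouts")`.
#' @export
gen_adl_segment <- function(duration_ms, config) {
  if (duration_ms <= 0) stop("duration must be positive")
  ts <- gen_timestamps(duration_ms, config)
  n <- length(ts)
  t_s <- ts / 1000
  u0 <- random_unit_vector()
  U <- drift_directions(t_s, u0)
  basis <- perp_basis(u0)

  # alternating rest / walk epochs, 10-30 s each
  walk_amp <- numeric(n)
  walk_freq <- rep(2, n)
  walk_phase <- numeric(n)
  walking <- stats::runif(1) < 0.5
  t_edge <- 0
  while (t_edge < duration_ms) {
    len <- stats::runif(1, 10000, 30000)
    in_epoch <- ts >= t_edge & ts < t_edge + len
    if (walking && any(in_epoch)) {
      walk_amp[in_epoch] <- stats::runif(1, config$walk_amp_g[1],
                                         config$walk_amp_g[2])
      walk_freq[in_epoch] <- stats::runif(1, config$walk_freq_hz[1],
                                          config$walk_freq_hz[2])
      walk_phase[in_epoch] <- stats::runif(1, 0, 2 * pi)
    }
    walking <- !walking
    t_edge <- t_edge + len
  }

  gait <- sin(2 * pi * walk_freq * t_s + walk_phase)
  m <- 1 + walk_amp * gait
  wobble <- outer(0.2 * walk_amp * sin(2 * pi * 2 * walk_freq * t_s + walk_phase),
                  basis$e1)
  acc <- compose_accel(m, U, wobble, config$noise_std_g)

  gyro_amp <- 0.8 * walk_amp  # rad/s, gait-band rotation while walking
  gph <- stats::runif(3, 0, 2 * pi)
  gyr <- vapply(1:3, function(k) {
    gyro_amp * sin(2 * pi * walk_freq * t_s + gph[k]) +
      stats::rnorm(n, 0, 0.02)
  }, numeric(n))

  out <- data.frame(t = ts, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                    gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3])
  attr(out, "dropouts") <- attr(ts, "dropouts")
  out
}

# piecewise-linear interpolation helper on breakpoints (ms -> value)
profile_interp <- function(ts, break_t, break_v) {
  stats::approx(break_t, break_v, xout = ts, method = "linear", rule = 2)$y
}

#' Generate a fall event
#'
#' Phenomenology: 2 s of ambulation, a free-fall phase (magnitude decaying
#' toward ~0.3 g) of 300-500 ms, a ~100 ms half-sine impact peaking at 3-6 g,
#' 500 ms of damped oscillation, then at least 5 s of rest at 1 g in a new
#' orientation. The gyroscope bursts (3-8 rad/s) during the fall phase. The
#' impact is the unique magnitude maximum of the event.
#'
#' @param config a `synthetic_config`.
#' @return list with `samples` (relative ms), `t_impact` (ms, time of the
#'   peak-magnitude sample) and `kind = "fall"`.
#' @export
gen_fall_event <- function(config) {
  pre <- 2000
  ff <- stats::runif(1, config$freefall_ms[1], config$freefall_ms[2])
  imp <- 100
  osc <- 500
  rest <- 5000
  total <- pre + ff + imp + osc + rest
  peak <- stats::runif(1, config$impact_peak_g[1], config$impact_peak_g[2])

  ts <- gen_timestamps(total, config)
  t_s <- ts / 1000
  n <- length(ts)

  walk_a <- stats::runif(1, config$walk_amp_g[1], config$walk_amp_g[2])
  walk_f <- stats::runif(1, config$walk_freq_hz[1], config$walk_freq_hz[2])

  t1 <- pre; t2 <- pre + ff; t3 <- t2 + imp; t4 <- t3 + osc
  m <- numeric(n)
  seg_pre <- ts < t1
  m[seg_pre] <- 1 + walk_a * sin(2 * pi * walk_f * t_s[seg_pre])
  seg_ff <- ts >= t1 & ts < t2
  m[seg_ff] <- profile_interp(ts[seg_ff], c(t1, t2), c(1, 0.3))
  seg_imp <- ts >= t2 & ts < t3
  m[seg_imp] <- peak * sin(pi * (ts[seg_imp] - t2) / imp)
  seg_osc <- ts >= t3 & ts < t4
  m[seg_osc] <- 1 + 0.8 * exp(-(ts[seg_osc] - t3) / 150) *
    sin(2 * pi * 8 * (ts[seg_osc] - t3) / 1000)
  seg_rest <- ts >= t4
  m[seg_rest] <- 1

  u1 <- random_unit_vector()
  u2 <- random_unit_vector()
  s <- pmin(pmax((ts - t1) / (t3 - t1), 0), 1)  # orientation swings over the fall
  U <- outer(1 - s, u1) + outer(s, u2)
  U <- U / sqrt(rowSums(U^2))
  acc <- compose_accel(m, U, 0, config$noise_std_g)

  burst <- stats::runif(1, config$gyro_burst_rads[1], config$gyro_burst_rads[2])
  env <- numeric(n)
  in_fall <- ts >= t1 & ts < t4
  env[in_fall] <- burst * exp(-abs(ts[in_fall] - t2) / 250)
  gph <- stats::runif(3, 0, 2 * pi)
  gyr <- vapply(1:3, function(k) {
    env * sin(2 * pi * 3 * t_s + gph[k]) + stats::rnorm(n, 0, 0.02)
  }, numeric(n))

  samples <- data.frame(t = ts, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                        gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3])
  attr(samples, "dropouts") <- attr(ts, "dropouts")
  mag <- magnitude(samples[c("ax", "ay", "az")])
  list(samples = samples, t_impact = ts[which.max(mag)], kind = "fall")
}

#' Generate a fall-like confounder event
#'
#' `stumble`: a brief 1.8-3 g spike during gait, with gait resuming and no
#' post-event rest. `phone_drop`: free fall to near 0 g, a sharp impact
#' spike, then complete stillness at an arbitrary orientation with almost no
#' rotation. `sit_stand`: a smooth 0.5-1.5 g magnitude swing over about a
#' second. All are non-fall ground truth; stumbles carry the `stumble` tag.
#'
#' @param kind one of `"stumble"`, `"phone_drop"`, `"sit_stand"`.
#' @param config a `synthetic_config`.
#' @return list with `samples`, `t_impact` (peak time) and `kind`.
#' @export
gen_confounder_event <- function(kind = c("stumble", "phone_drop", "sit_stand"),
                                 config) {
  kind <- match.arg(kind)
  if (kind == "stumble") {
    pre <- 1500; spike <- 80; post <- 2500
    total <- pre + spike + post
    peak <- stats::runif(1, config$stumble_peak_g[1], config$stumble_peak_g[2])
    ts <- gen_timestamps(total, config)
    t_s <- ts / 1000
    n <- length(ts)
    walk_a <- stats::runif(1, config$walk_amp_g[1], config$walk_amp_g[2])
    walk_f <- stats::runif(1, config$walk_freq_hz[1], config$walk_freq_hz[2])
    m <- 1 + walk_a * sin(2 * pi * walk_f * t_s)
    in_spike <- ts >= pre & ts < pre + spike
    # the spike rises out of the gait baseline and peaks at exactly `peak`
    m[in_spike] <- pmax(m[in_spike],
                        peak * sin(pi * (ts[in_spike] - pre) / spike))
    u <- random_unit_vector()
    U <- drift_directions(t_s, u, drift_amp = 0.05)
    acc <- compose_accel(m, U, 0, config$noise_std_g)
    env <- 0.8 * walk_a + 1.2 * exp(-abs(ts - pre - spike / 2) / 150)
    gph <- stats::runif(3, 0, 2 * pi)
    gyr <- vapply(1:3, function(k) {
      env * sin(2 * pi * walk_f * t_s + gph[k]) + stats::rnorm(n, 0, 0.02)
    }, numeric(n))
  } else if (kind == "phone_drop") {
    hold <- 500
    ff <- stats::runif(1, 300, 600)
    spike <- 60; still <- 5000
    total <- hold + ff + spike + still
    peak <- stats::runif(1, config$drop_peak_g[1], config$drop_peak_g[2])
    ts <- gen_timestamps(total, config)
    t_s <- ts / 1000
    n <- length(ts)
    t1 <- hold; t2 <- hold + ff; t3 <- t2 + spike
    m <- rep(1, n)
    seg_ff <- ts >= t1 & ts < t2
    m[seg_ff] <- profile_interp(ts[seg_ff], c(t1, t1 + 60, t2), c(1, 0.05, 0.05))
    seg_sp <- ts >= t2 & ts < t3
    m[seg_sp] <- peak * sin(pi * (ts[seg_sp] - t2) / spike)
    m[ts >= t3] <- 1
    u1 <- random_unit_vector(); u2 <- random_unit_vector()
    s <- pmin(pmax((ts - t1) / (t3 - t1), 0), 1)
    U <- outer(1 - s, u1) + outer(s, u2)
    U <- U / sqrt(rowSums(U^2))
    # stillness after a drop: far quieter than a body at rest
    noise <- ifelse(ts >= t3, 0.004, config$noise_std_g)
    acc <- U * m + matrix(stats::rnorm(3 * n, 0, 1), n, 3) * noise
    env <- 0.3 * exp(-abs(ts - t2) / 100)  # phones tumble little, bodies a lot
    gph <- stats::runif(3, 0, 2 * pi)
    gyr <- vapply(1:3, function(k) {
      env * sin(2 * pi * 4 * t_s + gph[k]) +
        stats::rnorm(n, 0, ifelse(ts >= t3, 0.002, 0.02))
    }, numeric(n))
  } else {  # sit_stand
    total <- 3000
    ts <- gen_timestamps(total, config)
    t_s <- ts / 1000
    n <- length(ts)
    m <- rep(1, n)
    swing <- ts >= 1000 & ts < 2000
    m[swing] <- 1 + 0.5 * sin(2 * pi * (ts[swing] - 1000) / 1000)
    u <- random_unit_vector()
    U <- drift_directions(t_s, u, drift_amp = 0.1)
    acc <- compose_accel(m, U, 0, config$noise_std_g)
    gph <- stats::runif(3, 0, 2 * pi)
    gyr <- vapply(1:3, function(k) {
      0.3 * sin(2 * pi * 0.5 * t_s + gph[k]) + stats::rnorm(n, 0, 0.02)
    }, numeric(n))
  }
  samples <- data.frame(t = ts, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                        gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3])
  attr(samples, "dropouts") <- attr(ts, "dropouts")
  mag <- magnitude(samples[c("ax", "ay", "az")])
  list(samples = samples, t_impact = ts[which.max(mag)], kind = kind)
}

event_duration_ms <- function(kind, config) {
  switch(kind,
         fall = 2000 + config$freefall_ms[2] + 100 + 500 + 5000,
         stumble = 1500 + 80 + 2500,
         phone_drop = 500 + 600 + 60 + 5000,
         sit_stand = 3000)
}

#' Generate a full synthetic study
#'
#' For each participant, one continuous recording of
#' `days * hours_per_day` worn hours with the configured number of falls,
#' stumbles and phone drops planted at uniformly random, non-overlapping
#' times. Returns (and optionally writes) the recordings, the fall-label
#' table (`participant_id`, `t_label_ms`, where the label is the impact time
#' blurred by up to +/- 1.5 s, as a researcher's log would be), and a
#' manifest of every planted event. Fully determined by `config$seed`.
#'
#' @param config a `synthetic_config`.
#' @param dir optional output directory: writes `<participant>.csv` files,
#'   `falls.csv` and `manifest.json`.
#' @param t_epoch_ms epoch offset of the first sample (default places the
#'   study in 2020).
#' @return list with `recordings` (named list of `imu_recording`),
#'   `labels` (data.frame) and `manifest` (list of planted events).
#' @export
gen_study <- function(config = synthetic_config(), dir = NULL,
                      t_epoch_ms = 1.6e12) {
  set.seed(config$seed)
  duration_ms <- config$days * config$hours_per_day * 3600 * 1000
  kinds <- c(rep("fall", config$falls_per_participant),
             rep("stumble", config$stumbles_per_participant),
             rep("phone_drop", config$drops_per_participant))
  recordings <- list()
  labels <- data.frame(participant_id = character(0), t_label_ms = numeric(0))
  manifest <- list()

  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("p%02d", p)
    margin <- max(vapply(unique(kinds), event_duration_ms, numeric(1),
                         config = config), 10000) + 10000
    starts <- schedule_events(length(kinds), duration_ms, margin)
    base <- gen_adl_segment(duration_ms, config)
    dropouts <- attr(base, "dropouts")
    samples <- base
    for (i in seq_along(kinds)) {
      ev <- if (kinds[i] == "fall") gen_fall_event(config)
            else gen_confounder_event(kinds[i], config)
      ev_len <- ev$samples$t[nrow(ev$samples)] + 20
      samples <- samples[samples$t < starts[i] | samples$t >= starts[i] + ev_len, ]
      ev_abs <- ev$samples
      ev_abs$t <- ev_abs$t + starts[i]
      samples <- rbind(samples, ev_abs)
      ev_drop <- attr(ev$samples, "dropouts")
      if (!is.null(ev_drop)) {
        ev_drop$from <- ev_drop$from + starts[i]
        ev_drop$to <- ev_drop$to + starts[i]
        dropouts <- rbind(dropouts, ev_drop)
      }
      t_impact_abs <- t_epoch_ms + starts[i] + ev$t_impact
      manifest[[length(manifest) + 1L]] <- list(
        participant_id = pid, kind = ev$kind,
        t_start_ms = t_epoch_ms + starts[i],
        t_impact_ms = t_impact_abs
      )
      if (ev$kind == "fall") {
        labels <- rbind(labels, data.frame(
          participant_id = pid,
          t_label_ms = round(t_impact_abs + stats::runif(1, -1500, 1500))
        ))
      }
    }
    samples <- samples[order(samples$t), ]
    samples$t <- samples$t + t_epoch_ms
    recordings[[pid]] <- imu_recording(samples, pid)
    if (!is.null(dropouts) && nrow(dropouts) > 0L) {
      manifest[[length(manifest) + 1L]] <- list(
        participant_id = pid, kind = "dropouts",
        segments = data.frame(from = dropouts$from + t_epoch_ms,
                              to = dropouts$to + t_epoch_ms)
      )
    }
  }

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(recordings)) {
      write_recording(recordings[[pid]], file.path(dir, paste0(pid, ".csv")))
    }
    utils::write.csv(labels, file.path(dir, "falls.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, dataframe = "rows")
  }
  list(recordings = recordings, labels = labels, manifest = manifest)
}

# uniformly random non-overlapping event start times with a separation
# margin: draw order statistics on the free space, then re-insert the
# margins (uniform over the set of valid placements, no rejection needed)
schedule_events <- function(n_events, duration_ms, margin_ms) {
  if (n_events == 0L) return(numeric(0))
  free <- duration_ms - 2 * margin_ms - (n_events - 1) * margin_ms
  if (free <= 0) {
    stop("recording too short to place ", n_events, " non-overlapping events")
  }
  u <- sort(stats::runif(n_events, 0, free))
  round(margin_ms + u + (seq_len(n_events) - 1) * margin_ms)
}

#' Generate standalone labeled training windows
#'
#' Draws `n_fall` fall events and `n_confounder` confounder events
#' (alternating stumbles and phone drops), cuts one 5-s window per event at
#' a random offset containing the peak (as the training augmentation does),
#' keeps only windows that pass the quality gate and the 2 g screen - the
#' population the second-stage classifier is defined on - and returns their
#' features. Participant groups are assigned round-robin so the set is
#' usable for leave-one-participant-out validation.
#'
#' @param n_fall,n_confounder window counts.
#' @param config a `synthetic_config`.
#' @param seed integer seed.
#' @param n_groups pseudo-participant count for group assignment.
#' @return A `training_set` (X: n x 40; y: 1 = fall; groups).
#' @export
gen_labeled_windows <- function(n_fall, n_confounder,
                                config = synthetic_config(), seed = 1L,
                                n_groups = 8L) {
  set.seed(seed)
  rows <- list()
  y <- numeric(0)
  pad_ms <- 6000
  take <- function(ev, label) {
    # embed the event in ambulation so any window offset has full coverage
    pre <- gen_adl_segment(pad_ms, config)
    post <- gen_adl_segment(pad_ms, config)
    ev_len <- ev$samples$t[nrow(ev$samples)] + 20
    ev_abs <- ev$samples
    ev_abs$t <- ev_abs$t + pad_ms
    post$t <- post$t + pad_ms + ev_len
    rec <- imu_recording(rbind(pre, ev_abs, post), "synthetic")
    offset <- sample.int(WINDOW_MS, 1L) - 1L
    w <- cut_window(rec, pad_ms + ev$t_impact - offset, label = label)
    if (isTRUE(w$valid) && stage1_screen(w)) compute_features(w) else NULL
  }
  got <- 0L
  while (got < n_fall) {
    f <- take(gen_fall_event(config), "fall")
    if (!is.null(f)) {
      rows[[length(rows) + 1L]] <- f
      y <- c(y, 1)
      got <- got + 1L
    }
  }
  got <- 0L
  conf_kinds <- c("stumble", "phone_drop")
  k <- 0L
  while (got < n_confounder) {
    k <- k + 1L
    ev <- gen_confounder_event(conf_kinds[(k %% 2L) + 1L], config)
    f <- take(ev, "non_fall")
    if (!is.null(f)) {
      rows[[length(rows) + 1L]] <- f
      y <- c(y, 0)
      got <- got + 1L
    }
  }
  X <- do.call(rbind, rows)
  groups <- sprintf("g%02d", (seq_len(nrow(X)) - 1L) %% n_groups + 1L)
  training_set(X, y, groups)
}
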