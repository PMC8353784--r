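# a deterministic window whose interpolated peak magnitude is exactly `peak`
peak_window <- function(peak) {
  rec <- grid_recording(n = 250, az = 1)
  rec$samples$az[125] <- peak
  cut_window(rec, 0)
}

test_that("the 2 g screen is strict and evaluated on the interpolated magnitude", {
  expect_true(stage1_screen(peak_window(2.5)))
  expect_false(stage1_screen(peak_window(1.0)))   # resting window
  expect_false(stage1_screen(peak_window(2.0)))   # boundary: strictly greater
  bad <- quality_check(cut_window(grid_recording(n = 10), 0, process = FALSE))
  expect_error(stage1_screen(bad), "valid")
})

test_that("classify_window routes windows through failure, screen and posterior", {
  model <- fixture_model()

  # quality failure: processing-failure flag, no classification
  bad <- quality_check(cut_window(grid_recording(n = 10), 0, process = FALSE))
  ev <- classify_window(bad, model)
  expect_true(ev$failed)
  expect_equal(ev$status, "none")
  expect_true(is.na(ev$posterior))

  # sub-2 g walking window: screened out, posterior never computed
  ev2 <- classify_window(peak_window(1.4), model)
  expect_false(ev2$failed)
  expect_false(ev2$stage1_pass)
  expect_true(is.na(ev2$posterior))
  expect_equal(ev2$status, "none")

  # synthetic fall window under the synthetic-trained model: alert
  set.seed(8)
  fall <- gen_fall_event(synthetic_config())
  rec <- imu_recording(fall$samples, "s")
  w <- cut_window(rec, fall$t_impact - 2000)
  ev3 <- classify_window(w, model)
  expect_true(ev3$stage1_pass)
  expect_equal(ev3$status, "alert")
  expect_gt(ev3$posterior, model$threshold)
})

test_that("alert status implies a screened window above the threshold", {
  model <- fixture_model()
  set.seed(14)
  events <- list(gen_fall_event(synthetic_config()),
                 gen_confounder_event("phone_drop", synthetic_config()),
                 gen_confounder_event("stumble", synthetic_config()))
  for (ev in events) {
    w <- cut_window(imu_recording(ev$samples, "s"), ev$t_impact - 1000)
    if (!isTRUE(w$valid)) next
    row <- classify_window(w, model)
    if (row$status == "alert") {
      expect_true(row$stage1_pass)
      expect_gt(row$posterior, model$threshold)
    }
  }
})

test_that("no window with peak magnitude <= 2 g can ever alert", {
  model <- fixture_model()
  set.seed(4)
  for (rep in 1:20) {
    peak <- runif(1, 0.5, 2.0)
    w <- peak_window(peak)
    ev <- classify_window(w, model)
    expect_false(isTRUE(ev$stage1_pass))
    expect_equal(ev$status, "none")
  }
})

# a short recording with one planted fall embedded in ambulation
one_fall_recording <- function(seed = 19, cfg = synthetic_config()) {
  set.seed(seed)
  pre <- gen_adl_segment(60000, cfg)
  fall <- gen_fall_event(cfg)
  post <- gen_adl_segment(60000, cfg)
  fall$samples$t <- fall$samples$t + 60000
  ev_len <- max(fall$samples$t) + 20 - 60000
  post$t <- post$t + 60000 + ev_len
  rec <- imu_recording(rbind(pre, fall$samples, post), "p1")
  list(recording = rec, t_impact = 60000 + fall$t_impact)
}

test_that("stream_detect alerts exactly once on a single planted fall", {
  model <- fixture_model()
  fx <- one_fall_recording()
  hook_calls <- 0
  events <- stream_detect(fx$recording, model, provider = stub_provider(),
                          alert_hook = function(e) hook_calls <<- hook_calls + 1)
  expect_equal(hook_calls, sum(events$status == "alert"))
  expect_equal(sum(events$status == "alert"), 1)
  alert <- events[events$status == "alert", ]
  expect_lte(abs(alert$t_start + 2500 - fx$t_impact), 5000)
  expect_equal(alert$weather, "clear")
  expect_equal(alert$activity, "on_foot")
  # events are time-ordered and deterministic
  expect_true(!is.unsorted(events$t_start))
  again <- stream_detect(fx$recording, model, provider = stub_provider())
  expect_equal(again, events)
})

test_that("empty recordings, failing hooks and failing providers are isolated", {
  model <- fixture_model()
  empty <- imu_recording(data.frame(t = numeric(0), ax = numeric(0),
                                    ay = numeric(0), az = numeric(0),
                                    gx = numeric(0), gy = numeric(0),
                                    gz = numeric(0)), "e")
  hook_calls <- 0
  ev <- stream_detect(empty, model, alert_hook = function(e) hook_calls <<- hook_calls + 1)
  expect_equal(nrow(ev), 0)
  expect_equal(hook_calls, 0)

  fx <- one_fall_recording()
  expect_message(
    ev2 <- stream_detect(fx$recording, model,
                         alert_hook = function(e) stop("hook exploded")),
    "alert hook failed"
  )
  expect_equal(sum(ev2$status == "alert"), 1)  # stream continued

  broken <- list(locate = function(t) stop("no gps"),
                 lookup = function(t, loc) stop("no network"),
                 classify = function(t) stop("no api"),
                 speed = function(t) stop("no gps"))
  ev3 <- stream_detect(fx$recording, model, provider = broken)
  alert <- ev3[ev3$status == "alert", ]
  expect_equal(alert$weather, "unknown")
  expect_equal(alert$activity, "unknown")
  expect_true(is.na(alert$lat))
  expect_equal(sum(ev3$status == "alert"), 1)  # detection unaffected
})

test_that("processing-failure count and classified count conserve the window total", {
  model <- fixture_model()
  cfg <- synthetic_config(dropout_prob = 0.05)  # dropout-rich stream
  set.seed(29)
  rec <- imu_recording(gen_adl_segment(300000, cfg), "d")
  events <- stream_detect(rec, model)
  n_windows <- length(tumbling_windows(rec))
  expect_equal(sum(events$failed) + sum(!events$failed), n_windows)
  expect_gt(sum(events$failed), 0)
})

test_that("the retention rule keeps windows within a closed 15-minute band", {
  events <- data.frame(t_start = c(1000 * 3600), posterior = 0.7,
                       status = "potential")
  starts <- c(
    1000 * 3600 - 900000,      # exactly 15 min before: retained (closed)
    1000 * 3600 - 900001,      # just outside
    1000 * 3600 + 450000,      # inside
    1000 * 3600 + 900000,      # exactly 15 min after
    1000 * 3600 + 900001
  )
  kept <- retention_filter(events, starts)
  expect_equal(kept, starts[c(1, 3, 4)])

  no_events <- data.frame(t_start = numeric(0), posterior = numeric(0),
                          status = character(0))
  expect_length(retention_filter(no_events, starts), 0)
  below <- data.frame(t_start = 0, posterior = 0.4, status = "none")
  expect_length(retention_filter(below, starts), 0)
})

test_that("event logs round-trip through JSON lines", {
  model <- fixture_model()
  fx <- one_fall_recording()
  events <- stream_detect(fx$recording, model, provider = stub_provider())
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(events, path)
  expect_equal(length(readLines(path)), nrow(events))
  back <- read_event_log(path)
  expect_equal(back$t_start, events$t_start)
  expect_equal(back$status, events$status)
  expect_equal(back$posterior, events$posterior, tolerance = 1e-12)
  expect_equal(back$weather, events$weather)
})
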