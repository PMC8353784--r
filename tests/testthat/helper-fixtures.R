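# Shared fixtures, built in code. Heavier shared objects (a fitted model on
# synthetic windows) are memoized so several test files can reuse them.

# a recording on the exact 20 ms grid with given channel values (recycled)
grid_recording <- function(n = 250, t0 = 0, step = 20,
                           ax = 0, ay = 0, az = 1,
                           gx = 0, gy = 0, gz = 0, id = "grid") {
  t <- t0 + step * (seq_len(n) - 1)
  imu_recording(data.frame(t = t, ax = rep_len(ax, n), ay = rep_len(ay, n),
                           az = rep_len(az, n), gx = rep_len(gx, n),
                           gy = rep_len(gy, n), gz = rep_len(gz, n)), id)
}

# a random valid interpolated window (seeded by the caller)
random_window <- function(scale = 1) {
  n <- 250
  df <- data.frame(t = 20 * (0:(n - 1)),
                   ax = rnorm(n) * scale, ay = rnorm(n) * scale,
                   az = (1 + rnorm(n, 0, 0.2)) * scale,
                   gx = rnorm(n, 0, 0.5) * scale, gy = rnorm(n, 0, 0.5) * scale,
                   gz = rnorm(n, 0, 0.5) * scale)
  cut_window(imu_recording(df, "rand"), 0)
}

.fixture_env <- new.env(parent = emptyenv())

# small labeled synthetic training set + fitted, calibrated model
fixture_training <- function() {
  if (is.null(.fixture_env$train)) {
    .fixture_env$train <- gen_labeled_windows(120, 120, synthetic_config(),
                                              seed = 42)
  }
  .fixture_env$train
}

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    tr <- fixture_training()
    m <- enet_fit(tr)
    m$threshold <- calibrate_threshold(m, tr$X[tr$y == 1, , drop = FALSE])
    .fixture_env$model <- m
  }
  .fixture_env$model
}

# independent brute-force feature oracle: same statistical conventions,
# written from the definitions (sums and the type-7 order-statistic formula),
# sharing no code with the package implementation
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_features <- function(acc, gyr) {
  one_sensor <- function(M) {
    mag <- sqrt(M[, 1]^2 + M[, 2]^2 + M[, 3]^2)
    n <- length(mag)
    mu <- sum(mag) / n
    m2 <- sum((mag - mu)^2) / n
    m3 <- sum((mag - mu)^3) / n
    m4 <- sum((mag - mu)^4) / n
    d <- mag[-1] - mag[-n]
    c(mu,
      oracle_quantile(mag, 0.5),
      sqrt(sum((mag - mu)^2) / (n - 1)),
      if (m2 > 0) m3 / m2^1.5 else 0,
      if (m2 > 0) m4 / m2^2 else 0,
      oracle_quantile(mag, 0.75) - oracle_quantile(mag, 0.25),
      oracle_quantile(d, 0.75) - oracle_quantile(d, 0.25),
      min(mag), min(d), max(mag), max(d),
      max(M[, 1]), max(M[, 2]), max(M[, 3]),
      min(M[, 1]), min(M[, 2]), min(M[, 3]),
      oracle_quantile(M[, 1], 0.75) - oracle_quantile(M[, 1], 0.25),
      oracle_quantile(M[, 2], 0.75) - oracle_quantile(M[, 2], 0.25),
      oracle_quantile(M[, 3], 0.75) - oracle_quantile(M[, 3], 0.25))
  }
  c(one_sensor(acc), one_sensor(gyr))
}

# brute-force AUROC over all positive-negative pairs
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
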