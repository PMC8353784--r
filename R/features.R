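# 40 time-domain features per window: 20 per sensor (accelerometer, gyroscope).
# Scalar features act on the magnitude series; derivative features on its
# first difference; per-axis features on each of x/y/z.

FEATURE_SUFFIXES <- c(
  "mean", "median", "std", "skew", "kurt", "iqr", "d_iqr",
  "min", "d_min", "max", "d_max",
  "max_x", "max_y", "max_z", "min_x", "min_y", "min_z",
  "iqr_x", "iqr_y", "iqr_z"
)

#' Canonical feature names
#'
#' The fixed order of the 40 features: 20 per sensor, named
#' `<sensor>_<feature>` with sensor `acc` then `gyr`.
#'
#' @return character vector of length 40.
#' @export
feature_names <- function() {
  as.vector(vapply(c("acc", "gyr"),
                   function(s) paste(s, FEATURE_SUFFIXES, sep = "_"),
                   character(length(FEATURE_SUFFIXES))))
}

#' Scalar summary statistics of a window series
#'
#' Conventions are fixed across the package: sample standard deviation
#' (n - 1 denominator); skewness `m3 / m2^1.5` and non-excess kurtosis
#' `m4 / m2^2` from population central moments (a Gaussian has kurtosis 3);
#' quartiles by linear interpolation (R type 7). A zero-variance series takes
#' skew = kurt = 0 so feature vectors stay finite for resting windows.
#'
#' @param series finite numeric vector, length >= 2.
#' @return Named numeric vector: mean, median, std, skew, kurt, iqr, min, max.
#' @export
scalar_stats <- function(series) {
  if (length(series) < 2L) stop("degenerate input: series must have length >= 2")
  if (any(!is.finite(series))) stop("series must be finite")
  m <- mean(series)
  d <- series - m
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  q <- stats::quantile(series, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = m, median = q[2], std = stats::sd(series), skew = skew, kurt = kurt,
    iqr = q[3] - q[1], min = min(series), max = max(series))
}

#' First-difference of a series
#'
#' `series[k + 1] - series[k]`, one value per 20 ms grid step (not divided
#' by the step).
#'
#' @param series numeric vector, length >= 2.
#' @return numeric vector of length `length(series) - 1`.
#' @export
series_derivative <- function(series) {
  if (length(series) < 2L) stop("degenerate input: series must have length >= 2")
  diff(series)
}

sensor_features <- function(interp) {
  mag <- magnitude(interp)
  st <- scalar_stats(mag)
  dmag <- series_derivative(mag)
  dq <- stats::quantile(dmag, c(0.25, 0.75), names = FALSE, type = 7)
  ax_stat <- function(fun) apply(interp, 2L, fun)
  iqr_ax <- apply(interp, 2L, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    q[2] - q[1]
  })
  vals <- c(
    st[["mean"]], st[["median"]], st[["std"]], st[["skew"]], st[["kurt"]],
    st[["iqr"]], dq[2] - dq[1],
    st[["min"]], min(dmag), st[["max"]], max(dmag),
    ax_stat(max), ax_stat(min), iqr_ax
  )
  names(vals) <- FEATURE_SUFFIXES
  vals
}

#' Compute the 40-feature vector of a valid window
#'
#' For each sensor, the eight scalar statistics of the interpolated magnitude
#' series, the IQR/min/max of its first difference, and the per-axis
#' max/min/IQR - 20 features per sensor in canonical order.
#'
#' @param window a valid, interpolated `sensor_window`.
#' @return Named numeric vector of length 40 (see [feature_names()]).
#' @export
compute_features <- function(window) {
  if (!isTRUE(window$valid) || is.null(window$accel_interp)) {
    stop("compute_features requires a valid, interpolated window")
  }
  vals <- c(sensor_features(window$accel_interp),
            sensor_features(window$gyro_interp))
  names(vals) <- feature_names()
  vals
}

#' Feature matrix for a list of windows
#'
#' Invalid windows are skipped. Returns a data.frame with `window_id`,
#' `label`, then the 40 canonical feature columns (the export format).
#'
#' @param windows list of `sensor_window`s.
#' @return data.frame with one row per valid window.
#' @export
feature_matrix <- function(windows) {
  valid <- Filter(function(w) isTRUE(w$valid), windows)
  if (length(valid) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, 40,
                                dimnames = list(NULL, feature_names())))
    return(cbind(data.frame(window_id = character(0), label = character(0)),
                 out))
  }
  feats <- t(vapply(valid, compute_features, numeric(40)))
  cbind(
    data.frame(
      window_id = vapply(valid, function(w) w$source_id, character(1)),
      label = vapply(valid, function(w) w$label, character(1)),
      stringsAsFactors = FALSE
    ),
    as.data.frame(feats)
  )
}

#' Write / read a feature matrix CSV
#' @param features data.frame from [feature_matrix()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window_id", "label", feature_names())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("feature CSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df[need]
}
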