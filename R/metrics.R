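# Deployment evaluation: match alert events against ground-truth falls and
# derive the confusion-count metrics a field study reports (sensitivity,
# specificity, precision, accuracy, F1, false-alarm interval).

#' Confusion counts for a deployment period
#'
#' `fn` may include undetected falls that never produced a classified window
#' (e.g. the phone was not worn), so `tp + fp + tn + fn` may exceed
#' `total_windows` by up to the number of such falls; this mirrors field
#' bookkeeping where ground truth comes from participant reports.
#'
#' @param tp,fp,tn,fn non-negative integers.
#' @param total_windows total 5-s windows assessed.
#' @param recording_days days of system use.
#' @param failed number of windows that failed to process.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn, total_windows = tp + fp + tn + fn,
                             recording_days = NA_real_, failed = 0L) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn, failed = failed)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.na(recording_days) && recording_days <= 0) {
    stop("recording_days must be positive")
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, failed = failed,
         total_windows = total_windows, recording_days = recording_days),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %s FP %s TN %s FN %s (total %s windows, %s days)\n",
              x$tp, x$fp, x$tn, x$fn,
              format(x$total_windows, big.mark = ","), x$recording_days))
  invisible(x)
}

#' Match alert events against ground-truth falls
#'
#' Greedy one-to-one matching in time order: each truth fall is matched to
#' the nearest still-unmatched alert within `tolerance_ms`; matched pairs are
#' true positives, unmatched alerts false positives, unmatched falls false
#' negatives. Conservation (`tp + fn` = falls, `tp + fp` = alerts) is
#' asserted before returning.
#'
#' @param alert_times numeric alert timestamps (ms), or a detection-event
#'   data.frame (rows with status `"alert"` are used, keyed by `t_start`).
#' @param truth_times numeric ground-truth fall timestamps (ms).
#' @param tolerance_ms matching tolerance, default 10 s.
#' @return list with `tp`, `fp`, `fn` and the matched pairs.
#' @export
match_events <- function(alert_times, truth_times, tolerance_ms = 10000) {
  if (is.data.frame(alert_times)) {
    alert_times <- alert_times$t_start[alert_times$status == "alert"]
  }
  alerts <- sort(as.numeric(alert_times))
  truths <- sort(as.numeric(truth_times))
  used <- logical(length(alerts))
  pairs <- list()
  for (tf in truths) {
    if (length(alerts) > 0L) {
      d <- abs(alerts - tf)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) == 1L && is.finite(d[j]) && d[j] <= tolerance_ms) {
        used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(truth = tf, alert = alerts[j])
      }
    }
  }
  tp <- sum(used)
  res <- list(tp = tp, fp = length(alerts) - tp, fn = length(truths) - tp,
              pairs = pairs)
  stopifnot(res$tp + res$fn == length(truths),
            res$tp + res$fp == length(alerts))
  res
}

ratio_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator)")
    return(NA_real_)
  }
  num / den
}

#' Deployment performance metrics
#'
#' Percentages carry full precision; rounding happens only at rendering.
#' Accuracy uses `total_windows` as its denominator (the number of 5-s clips
#' the system assessed). Undefined ratios are `NA`, never 0.
#'
#' @param counts a `confusion_counts`.
#' @return An object of class `performance_report` (a named list):
#'   sensitivity/specificity/precision/accuracy in percent, `f1` in `[0, 1]`,
#'   `daily_false_alarm_rate` (FP/day), `days_per_false_alarm`, and
#'   `failure_rate` (fraction of windows that failed to process).
#' @export
performance <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    sens <- 100 * ratio_or_na(tp, tp + fn, "sensitivity")
    spec <- 100 * ratio_or_na(tn, tn + fp, "specificity")
    prec <- 100 * ratio_or_na(tp, tp + fp, "precision")
    acc <- 100 * ratio_or_na(tp + tn, total_windows, "accuracy")
    f1 <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) {
      warning("F1 undefined")
      NA_real_
    } else {
      2 * (prec / 100) * (sens / 100) / (prec / 100 + sens / 100)
    }
    structure(
      list(
        sensitivity = sens, specificity = spec, precision = prec,
        accuracy = acc, f1 = f1,
        daily_false_alarm_rate = if (is.na(recording_days)) NA_real_ else fp / recording_days,
        days_per_false_alarm = if (is.na(recording_days)) NA_real_
                               else ratio_or_na(recording_days, fp, "days_per_false_alarm"),
        failure_rate = ratio_or_na(failed, total_windows, "failure_rate"),
        counts = counts
      ),
      class = "performance_report"
    )
  })
}

#' @export
print.performance_report <- function(x, ...) {
  fmt <- function(v, digits = 1) {
    if (is.na(v)) "n/a" else formatC(v, format = "f", digits = digits)
  }
  cat("<performance_report>\n")
  cat("  sensitivity ", fmt(x$sensitivity), " %\n", sep = "")
  cat("  specificity ", fmt(x$specificity, 4), " %\n", sep = "")
  cat("  precision   ", fmt(x$precision), " %\n", sep = "")
  cat("  accuracy    ", fmt(x$accuracy, 4), " %\n", sep = "")
  cat("  F1          ", fmt(x$f1, 3), "\n", sep = "")
  cat("  false alarms: ", fmt(x$daily_false_alarm_rate, 3), " per day (one per ",
      fmt(x$days_per_false_alarm, 0), " days)\n", sep = "")
  invisible(x)
}

metric_fields <- c("sensitivity", "specificity", "precision", "accuracy",
                   "f1", "daily_false_alarm_rate", "days_per_false_alarm",
                   "failure_rate")

#' Per-participant performance table with mean (SD) summary
#'
#' Computes a `performance_report` per participant and appends mean and
#' sample-SD rows across participants. A participant is excluded from a
#' metric's average when that metric is undefined for them (e.g. sensitivity
#' for a participant with no falls); the number included is reported per
#' metric.
#'
#' @param counts_by_participant named list of `confusion_counts`.
#' @return list with `table` (one row per participant), `mean`, `sd` and
#'   `n_included` per metric.
#' @export
per_participant_report <- function(counts_by_participant) {
  if (length(counts_by_participant) == 0L) stop("need at least one participant")
  reports <- lapply(counts_by_participant, function(cc) {
    suppressWarnings(performance(cc))
  })
  tab <- do.call(rbind, lapply(names(reports), function(id) {
    r <- reports[[id]]
    cbind(data.frame(participant_id = id, stringsAsFactors = FALSE),
          as.data.frame(r[metric_fields]))
  }))
  rownames(tab) <- NULL
  mu <- vapply(metric_fields, function(m) mean(tab[[m]], na.rm = TRUE), numeric(1))
  sdv <- vapply(metric_fields, function(m) {
    v <- tab[[m]][!is.na(tab[[m]])]
    if (length(v) >= 2L) stats::sd(v) else if (length(v) == 1L) 0 else NA_real_
  }, numeric(1))
  n_inc <- vapply(metric_fields, function(m) sum(!is.na(tab[[m]])), integer(1))
  list(table = tab, mean = mu, sd = sdv, n_included = n_inc)
}

#' Write a performance report as JSON (full precision)
#' @param report a `performance_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  doc <- report[metric_fields]
  doc$counts <- unclass(report$counts)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Render a performance report as a markdown table
#'
#' Prints to the deployment-study precision: one decimal for percentages,
#' three for F1, four decimals for near-unity percentages.
#'
#' @param report a `performance_report`.
#' @return character vector of markdown lines.
#' @export
render_report_md <- function(report) {
  f <- function(v, d) if (is.na(v)) "n/a" else formatC(v, format = "f", digits = d)
  c("| Metric | Value |",
    "|---|---|",
    sprintf("| Sensitivity | %s %% |", f(report$sensitivity, 1)),
    sprintf("| Specificity | %s %% |", f(report$specificity, 4)),
    sprintf("| Precision | %s %% |", f(report$precision, 1)),
    sprintf("| Accuracy | %s %% |", f(report$accuracy, 4)),
    sprintf("| F1-score | %s |", f(report$f1, 3)),
    sprintf("| Daily false alarm rate | %s |", f(report$daily_false_alarm_rate, 3)),
    sprintf("| Days per false alarm | %s |", f(report$days_per_false_alarm, 0)),
    sprintf("| Failure rate | %s %% |", f(100 * report$failure_rate, 4)))
}
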