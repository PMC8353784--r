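# Training-set assembly: the end-to-end path from labeled recordings to the
# screened window population the second-stage classifier is defined on.

#' Build a training set from recordings and fall labels
#'
#' Reproduces the training procedure of the deployed detector. For every
#' labeled fall, the impact is localized ([locate_impact()]) and ten windows
#' are drawn at random offsets containing it ([augment_fall_windows()]).
#' Non-fall examples are the tumbling windows of the same recordings that
#' pass the quality gate and the 2 g screen and do not contain a fall
#' impact. Only screened windows enter the set: the classifier never sees a
#' sub-2 g window in deployment either.
#'
#' @param recordings named list of `imu_recording`s (names = participant ids).
#' @param labels data.frame with `participant_id`, `t_label_ms`.
#' @param n_aug fall windows per fall event (default 10).
#' @param seed integer seed for the augmentation offsets.
#' @return A `training_set`.
#' @export
build_training_set <- function(recordings, labels, n_aug = 10L, seed = 1L) {
  set.seed(seed)
  X <- list()
  y <- numeric(0)
  groups <- character(0)
  for (pid in names(recordings)) {
    rec <- recordings[[pid]]
    t_lab <- labels$t_label_ms[labels$participant_id == pid]
    impacts <- vapply(t_lab, function(t) locate_impact(rec, t), numeric(1))
    for (ti in impacts) {
      for (w in augment_fall_windows(rec, ti, n = n_aug)) {
        if (isTRUE(w$valid) && stage1_screen(w)) {
          X[[length(X) + 1L]] <- compute_features(w)
          y <- c(y, 1)
          groups <- c(groups, pid)
        }
      }
    }
    for (w in tumbling_windows(rec)) {
      if (!isTRUE(w$valid) || !stage1_screen(w)) next
      near_fall <- length(impacts) > 0L &&
        any(impacts >= w$t_start & impacts < w$t_end)
      if (near_fall) next
      X[[length(X) + 1L]] <- compute_features(w)
      y <- c(y, 0)
      groups <- c(groups, pid)
    }
  }
  if (length(X) == 0L) stop("no usable windows found")
  training_set(do.call(rbind, X), y, groups)
}
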