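# Elastic-net penalized logistic regression, fit by cyclic coordinate
# descent with soft-thresholding under the global 1/4 curvature bound of the
# logistic loss. Penalty convention (the dominant one):
#   (1/n) * log-loss + lam * (alpha * ||w||_1 + (1 - alpha)/2 * ||w||_2^2)
# with the intercept unpenalized and features standardized before fitting.

#' Assemble a training set
#'
#' Binds a feature matrix, binary labels (1 = fall) and participant group ids.
#' By design only windows that passed the 2 g screen belong here: the second
#' stage is trained on, and only ever sees, screened windows.
#'
#' @param X numeric n x 40 matrix (columns in [feature_names()] order).
#' @param y binary labels, 1 = fall.
#' @param groups participant identifier per row.
#' @return An object of class `training_set`.
#' @export
training_set <- function(X, y, groups) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  groups <- as.character(groups)
  if (nrow(X) != length(y) || nrow(X) != length(groups)) {
    stop("X, y and groups must have matching lengths")
  }
  if (!all(y %in% c(0, 1))) stop("y must be binary (1 = fall)")
  structure(list(X = X, y = y, groups = groups), class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d windows (%d fall / %d non-fall), %d participants\n",
              length(x$y), sum(x$y == 1), sum(x$y == 0),
              length(unique(x$groups))))
  invisible(x)
}

#' Column standardization statistics
#'
#' Column means and sample standard deviations. Zero-variance columns are
#' recorded with std 1 and masked: they are held at weight exactly 0 during
#' fitting.
#'
#' @param X numeric matrix, n >= 2.
#' @return list with `means`, `stds`, and logical `mask` (TRUE = usable).
#' @export
standardize_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("standardization needs at least 2 rows")
  means <- colMeans(X)
  stds <- apply(X, 2L, stats::sd)
  mask <- stds > 0
  stds[!mask] <- 1
  list(means = means, stds = stds, mask = mask)
}

#' Elastic-net logistic objective
#'
#' Mean negative log-likelihood plus
#' `lam * (alpha * ||w||_1 + (1 - alpha)/2 * ||w||_2^2)`; the intercept is
#' unpenalized. Log terms are clipped at 1e-15.
#'
#' @param w weight vector (standardized feature space).
#' @param b intercept.
#' @param X_std standardized feature matrix.
#' @param y binary labels.
#' @param alpha L1/L2 mixing parameter in `[0, 1]`.
#' @param lam penalty strength, >= 0.
#' @return scalar objective value.
#' @export
enet_objective <- function(w, b, X_std, y, alpha, lam) {
  eta <- drop(X_std %*% w) + b
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  nll <- -mean(y * log(p) + (1 - y) * log(1 - p))
  nll + lam * (alpha * sum(abs(w)) + (1 - alpha) / 2 * sum(w^2))
}

soft_threshold <- function(z, gamma) sign(z) * pmax(abs(z) - gamma, 0)

#' Fit an elastic-net logistic regression
#'
#' Standardizes features, then minimizes [enet_objective()] by deterministic
#' cyclic coordinate descent: each coordinate takes a soft-thresholded step on
#' the quadratic majorization of the logistic loss with curvature bound 1/4.
#' Convergence is declared when the objective decreases by less than `tol`
#' over a full cycle. Defaults are the deployment hyperparameters
#' `alpha = 0.6`, `lam = 0.015`; the shipped decision threshold default is
#' 0.908 (the deployed constant) until [calibrate_threshold()] replaces it.
#'
#' @param train a `training_set` (or matrix via `X`, `y` arguments).
#' @param alpha L1/L2 mixing in `[0, 1]`.
#' @param lam penalty strength.
#' @param threshold initial decision threshold.
#' @param tol convergence tolerance on the per-cycle objective decrease.
#' @param max_cycles maximum full coordinate cycles.
#' @return An `enet_model`: standardization statistics, weights (standardized
#'   space), intercept, hyperparameters, decision threshold.
#' @export
enet_fit <- function(train, alpha = 0.6, lam = 0.015, threshold = 0.908,
                     tol = 1e-8, max_cycles = 10000L) {
  X <- train$X
  y <- train$y
  if (length(unique(y)) < 2L) stop("both classes must be present to fit")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lam < 0) stop("lam must be >= 0")
  std <- standardize_fit(X)
  Xs <- sweep(sweep(X, 2L, std$means, "-"), 2L, std$stds, "/")
  n <- nrow(Xs)
  p <- ncol(Xs)
  active <- which(std$mask)

  w <- numeric(p)
  b <- 0
  eta <- rep(0, n)
  # per-coordinate curvature bound: (1/4) * mean(x_j^2)
  hj <- 0.25 * colMeans(Xs^2)
  l1 <- lam * alpha
  l2 <- lam * (1 - alpha)

  obj <- enet_objective(w, b, Xs, y, alpha, lam)
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    mu <- stats::plogis(eta)
    b_new <- b - mean(mu - y) / 0.25
    eta <- eta + (b_new - b)
    b <- b_new
    for (j in active) {
      mu <- stats::plogis(eta)
      gj <- mean(Xs[, j] * (mu - y))
      z <- hj[j] * w[j] - gj
      wj_new <- soft_threshold(z, l1) / (hj[j] + l2)
      if (wj_new != w[j]) {
        eta <- eta + (wj_new - w[j]) * Xs[, j]
        w[j] <- wj_new
      }
    }
    obj_new <- enet_objective(w, b, Xs, y, alpha, lam)
    if (obj - obj_new < tol) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  if (!converged) {
    warning(sprintf("coordinate descent did not converge in %d cycles (objective %.10g)",
                    max_cycles, obj))
  }
  structure(
    list(
      feature_names = colnames(X),
      feature_means = std$means,
      feature_stds = std$stds,
      mask = std$mask,
      weights = w,
      intercept = b,
      alpha = alpha,
      lam = lam,
      threshold = threshold,
      objective = obj,
      converged = converged
    ),
    class = "enet_model"
  )
}

#' @export
print.enet_model <- function(x, ...) {
  cat(sprintf("<enet_model> alpha = %g, lambda = %g, threshold = %g\n",
              x$alpha, x$lam, x$threshold))
  cat(sprintf("  %d/%d non-zero weights, intercept %.4f, objective %.6g\n",
              sum(x$weights != 0), length(x$weights), x$intercept, x$objective))
  invisible(x)
}

#' Posterior fall probability
#'
#' Logistic transform of the linear score on standardized features; strictly
#' inside (0, 1).
#'
#' @param model an `enet_model`.
#' @param features numeric vector of length 40 or an n x 40 matrix.
#' @return probability vector.
#' @export
predict_posterior <- function(model, features) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1L) else as.matrix(features)
  if (ncol(X) != length(model$weights)) {
    stop("feature dimension mismatch: expected ", length(model$weights))
  }
  Xs <- sweep(sweep(X, 2L, model$feature_means, "-"), 2L, model$feature_stds, "/")
  eta <- drop(Xs %*% model$weights) + model$intercept
  p <- stats::plogis(eta)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Calibrate the alert threshold at the 5th percentile of fall posteriors
#'
#' Places the decision cutoff at the 5th percentile (linear interpolation,
#' R type 7) of the posterior probabilities of training fall windows, so that
#' by construction at least 95% of training falls score at or above it - the
#' construction targeting 95% training sensitivity.
#'
#' @param model an `enet_model`.
#' @param fall_features feature matrix of fall (y = 1) windows, n >= 20.
#' @return the threshold probability.
#' @export
calibrate_threshold <- function(model, fall_features) {
  X <- if (is.null(dim(fall_features))) matrix(fall_features, nrow = 1L) else as.matrix(fall_features)
  if (nrow(X) < 20L) stop("calibration needs at least 20 fall windows")
  threshold_from_posteriors(predict_posterior(model, X))
}

#' @rdname calibrate_threshold
#' @param posteriors fall-window posterior probabilities, n >= 20.
#' @export
threshold_from_posteriors <- function(posteriors) {
  if (length(posteriors) < 20L) stop("calibration needs at least 20 fall windows")
  stats::quantile(posteriors, 0.05, names = FALSE, type = 7)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, counting ties as 1/2.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUROC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-participant-out cross-validation
#'
#' For each participant: fit on all others, score the held-out windows, and
#' compute AUROC. Folds whose test split has a single class are skipped with
#' a warning.
#'
#' @param train a `training_set` with >= 2 participants.
#' @param alpha,lam elastic-net hyperparameters.
#' @param ... passed to [enet_fit()].
#' @return list with `folds` (named per-participant AUROC) and `mean_auroc`.
#' @export
loso_cv <- function(train, alpha = 0.6, lam = 0.015, ...) {
  ids <- unique(train$groups)
  if (length(ids) < 2L) stop("LOSO-CV needs at least 2 participants")
  folds <- numeric(0)
  for (id in ids) {
    test <- train$groups == id
    if (length(unique(train$y[test])) < 2L) {
      warning("fold '", id, "' skipped: held-out windows have a single class")
      next
    }
    fit <- enet_fit(training_set(train$X[!test, , drop = FALSE],
                                 train$y[!test], train$groups[!test]),
                    alpha = alpha, lam = lam, ...)
    scores <- predict_posterior(fit, train$X[test, , drop = FALSE])
    folds[id] <- auroc(scores, train$y[test])
  }
  list(folds = folds, mean_auroc = mean(folds))
}

#' Hyperparameter grid search over LOSO-CV folds
#'
#' Scores every (alpha, lam) pair by mean LOSO AUROC. Ties break toward the
#' larger lam, then the larger alpha (the sparser model). The default grids
#' bracket the deployed optimum (alpha 0.6, lam 0.015).
#'
#' @param train a `training_set`.
#' @param alpha_grid candidate mixing parameters.
#' @param lam_grid candidate penalty strengths.
#' @param ... passed to [enet_fit()].
#' @return list with `alpha`, `lam`, and the full `table` of fold means.
#' @export
grid_search <- function(train,
                        alpha_grid = c(0.2, 0.4, 0.6, 0.8, 1.0),
                        lam_grid = 10^seq(-4, 0, length.out = 10),
                        ...) {
  if (length(alpha_grid) == 0L || length(lam_grid) == 0L) {
    stop("grids must be non-empty")
  }
  tab <- expand.grid(alpha = alpha_grid, lam = lam_grid,
                     KEEP.OUT.ATTRS = FALSE)
  tab$mean_auroc <- vapply(seq_len(nrow(tab)), function(i) {
    loso_cv(train, alpha = tab$alpha[i], lam = tab$lam[i], ...)$mean_auroc
  }, numeric(1))
  ord <- order(-tab$mean_auroc, -tab$lam, -tab$alpha)
  best <- tab[ord[1], ]
  list(alpha = best$alpha, lam = best$lam, table = tab)
}

MODEL_FORMAT_VERSION <- 1L

#' Persist / load a fitted model as JSON
#'
#' The document stores standardization statistics, weights, intercept,
#' hyperparameters, threshold, feature names and a format version.
#'
#' @param model an `enet_model`.
#' @param path JSON file path.
#' @return `path` (write) or the `enet_model` (read).
#' @export
write_model <- function(model, path) {
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    feature_names = model$feature_names,
    feature_means = model$feature_means,
    feature_stds = model$feature_stds,
    mask = model$mask,
    weights = model$weights,
    intercept = model$intercept,
    alpha = model$alpha,
    lam = model$lam,
    threshold = model$threshold
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format_version) || doc$format_version > MODEL_FORMAT_VERSION) {
    stop("unsupported model format version")
  }
  structure(
    list(
      feature_names = doc$feature_names,
      feature_means = as.numeric(doc$feature_means),
      feature_stds = as.numeric(doc$feature_stds),
      mask = as.logical(doc$mask),
      weights = as.numeric(doc$weights),
      intercept = as.numeric(doc$intercept),
      alpha = as.numeric(doc$alpha),
      lam = as.numeric(doc$lam),
      threshold = as.numeric(doc$threshold),
      objective = NA_real_,
      converged = NA
    ),
    class = "enet_model"
  )
}
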