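# A tiny linearly-separable-ish toy problem used by several fitting tests
toy_problem <- function(n = 50, p = 5, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  eta <- 1.5 * X[, 1] - 1.0 * X[, 3] + 0.5
  y <- as.numeric(runif(n) < plogis(eta))
  colnames(X) <- paste0("f", seq_len(p))
  training_set(X, y, rep(c("a", "b"), length.out = n))
}

test_that("standardization statistics and the zero-variance mask", {
  expect_equal(standardize_fit(matrix(c(2, 2), 2, 1)),
               list(means = 2, stds = 1, mask = FALSE))
  s <- standardize_fit(matrix(c(0, 2), 2, 1))
  expect_equal(s$means, 1)
  expect_equal(s$stds, sqrt(2))
  expect_true(s$mask)

  X <- matrix(rnorm(60), 20, 3)
  st <- standardize_fit(X)
  Xs <- scale(X, st$means, st$stds)
  expect_equal(colMeans(Xs), rep(0, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(apply(Xs, 2, sd), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(standardize_fit(X[1, , drop = FALSE]), "at least 2")
})

test_that("the objective has its closed-form values and penalty structure", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  expect_equal(enet_objective(c(0, 0), 0, X, y, 0.6, 0.015), log(2))

  w <- c(0.5, -1)
  b <- 0.2
  p <- plogis(drop(X %*% w) + b)
  nll <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(enet_objective(w, b, X, y, 0.6, 0), nll)
  expect_equal(enet_objective(w, b, X, y, 1, 0.1), nll + 0.1 * sum(abs(w)))
  expect_equal(enet_objective(w, b, X, y, 0, 0.1), nll + 0.05 * sum(w^2))
})

test_that("coordinate descent attains the optimum of a generic convex optimizer", {
  toy <- toy_problem()
  for (hp in list(c(0.6, 0.015), c(1, 0.05), c(0, 0.1))) {
    fit <- enet_fit(toy, alpha = hp[1], lam = hp[2])
    std <- standardize_fit(toy$X)
    Xs <- scale(toy$X, std$means, std$stds)
    obj_fun <- function(par) {
      enet_objective(par[-1], par[1], Xs, toy$y, hp[1], hp[2])
    }
    oracle <- optim(rep(0, ncol(toy$X) + 1), obj_fun, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
    ours <- enet_objective(fit$weights, fit$intercept, Xs, toy$y, hp[1], hp[2])
    expect_lte(ours, oracle$value + 1e-6)
    # and never worse than the null model (convexity sanity)
    expect_lte(ours, enet_objective(rep(0, ncol(toy$X)), 0, Xs, toy$y,
                                    hp[1], hp[2]))
  }
})

test_that("the fit matches glmnet under the shared penalty convention", {
  skip_if_not_installed("glmnet")
  toy <- toy_problem(n = 200, p = 8, seed = 5)
  alpha <- 0.6
  lam <- 0.03
  fit <- enet_fit(toy, alpha = alpha, lam = lam)
  std <- standardize_fit(toy$X)
  Xs <- scale(toy$X, std$means, std$stds)
  g <- glmnet::glmnet(Xs, toy$y, family = "binomial", alpha = alpha,
                      lambda = c(0.3, 0.1, lam), standardize = FALSE,
                      thresh = 1e-12)
  gw <- as.numeric(g$beta[, 3])
  gb <- g$a0[3]
  ours <- enet_objective(fit$weights, fit$intercept, Xs, toy$y, alpha, lam)
  theirs <- enet_objective(gw, gb, Xs, toy$y, alpha, lam)
  expect_equal(ours, theirs, tolerance = 1e-5)
  expect_equal(fit$weights, gw, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("penalty-dominated and sparsity limits behave as theory predicts", {
  toy <- toy_problem(n = 100, seed = 3)
  big <- enet_fit(toy, alpha = 0.6, lam = 1000)
  expect_equal(big$weights, rep(0, 5), ignore_attr = TRUE)
  odds <- mean(toy$y) / (1 - mean(toy$y))
  expect_equal(big$intercept, log(odds), tolerance = 1e-4)

  # L1 norm of the fitted weights is non-increasing in lambda
  lams <- c(0.001, 0.01, 0.05, 0.2, 1)
  l1 <- vapply(lams, function(l) sum(abs(enet_fit(toy, 0.6, l)$weights)),
               numeric(1))
  expect_true(all(diff(l1) <= 1e-8))

  # pure-noise feature is exactly zeroed at moderate lam with alpha = 1
  set.seed(21)
  X <- cbind(sig = rnorm(200), noise = rnorm(200))
  y <- as.numeric(runif(200) < plogis(2 * X[, 1]))
  lasso <- enet_fit(training_set(X, y, rep("a", 200)), alpha = 1, lam = 0.05)
  expect_identical(lasso$weights[2], 0)
  expect_gt(abs(lasso$weights[1]), 0)

  expect_error(enet_fit(training_set(X, rep(1, 200), rep("a", 200))),
               "both classes")
})

test_that("posterior prediction is logistic, monotone and batch-consistent", {
  toy <- toy_problem()
  fit <- enet_fit(toy)
  null_model <- fit
  null_model$weights <- rep(0, 5)
  null_model$intercept <- 0
  expect_equal(predict_posterior(null_model, toy$X[1, ]), 0.5)

  post <- predict_posterior(fit, toy$X)
  expect_true(all(post > 0 & post < 1))
  one_by_one <- vapply(seq_len(nrow(toy$X)),
                       function(i) predict_posterior(fit, toy$X[i, ]),
                       numeric(1))
  expect_equal(post, one_by_one)

  # increasing the linear score increases the posterior
  j <- which.max(abs(fit$weights))
  x_lo <- toy$X[1, ]
  x_hi <- x_lo
  x_hi[j] <- x_hi[j] + sign(fit$weights[j]) * 10
  expect_gt(predict_posterior(fit, x_hi), predict_posterior(fit, x_lo))
})

test_that("prediction is invariant to affine rescaling of a raw feature", {
  toy <- toy_problem(n = 120, seed = 13)
  fit <- enet_fit(toy)
  X2 <- toy$X
  X2[, 2] <- 100 * X2[, 2] + 7  # rescale one raw feature, refit standardization
  fit2 <- enet_fit(training_set(X2, toy$y, toy$groups))
  expect_equal(predict_posterior(fit, toy$X), predict_posterior(fit2, X2),
               tolerance = 1e-8)
})

test_that("threshold calibration is the 5th percentile with linear interpolation", {
  post <- seq(0.905, 1.000, by = 0.005)  # 20 equally spaced fall posteriors
  expect_equal(threshold_from_posteriors(post), 0.90975)
  expect_equal(threshold_from_posteriors(rep(0.7, 25)), 0.7)
  expect_error(threshold_from_posteriors(runif(5)), "at least 20")

  set.seed(2)
  for (n in c(20, 101, 500)) {
    p <- runif(n, 0.5, 1)
    thr <- threshold_from_posteriors(p)
    expect_gte(mean(p >= thr), 0.95)
    expect_gte(thr, min(p))
    expect_lte(thr, max(p))
  }
})

test_that("AUROC equals the Mann-Whitney pairwise count", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")

  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("LOSO-CV holds out whole participants without leakage", {
  toy <- toy_problem(n = 80, seed = 17)
  cv <- loso_cv(toy, alpha = 0.6, lam = 0.015)
  expect_length(cv$folds, 2)
  expect_named(cv$folds, c("a", "b"))
  expect_equal(cv$mean_auroc, mean(cv$folds))

  # the held-out participant's rows do not influence the fold fit
  keep <- toy$groups != "a"
  refit <- enet_fit(training_set(toy$X[keep, ], toy$y[keep], toy$groups[keep]))
  scores <- predict_posterior(refit, toy$X[!keep, ])
  expect_equal(unname(cv$folds["a"]), auroc(scores, toy$y[!keep]))

  # a single-class test fold is skipped with a warning
  bad <- toy
  bad$groups[which(bad$y == 0)[1:5]] <- "c"
  expect_warning(cv2 <- loso_cv(bad), "single class")
  expect_length(cv2$folds, 2)

  expect_error(loso_cv(training_set(toy$X, toy$y, rep("a", 80))),
               "at least 2 participants")
})

test_that("grid search maximizes mean AUROC with sparser-model tie-breaks", {
  toy <- toy_problem(n = 80, seed = 23)
  one <- grid_search(toy, alpha_grid = 0.6, lam_grid = 0.015)
  expect_equal(one$alpha, 0.6)
  expect_equal(one$lam, 0.015)
  expect_equal(nrow(one$table), 1)

  gs <- grid_search(toy, alpha_grid = c(0.2, 0.8), lam_grid = c(0.001, 0.01, 0.1))
  expect_equal(nrow(gs$table), 6)
  best_val <- max(gs$table$mean_auroc)
  argmax <- gs$table[gs$table$mean_auroc == best_val, ]
  expect_equal(gs$lam, max(argmax$lam))
  expect_equal(gs$alpha, max(argmax$alpha[argmax$lam == max(argmax$lam)]))
  expect_error(grid_search(toy, numeric(0), 0.1), "non-empty")
})

test_that("models survive a JSON round trip", {
  toy <- toy_problem()
  fit <- enet_fit(toy)
  fit$threshold <- 0.93
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  for (field in c("feature_names", "feature_means", "feature_stds",
                  "weights", "intercept", "alpha", "lam", "threshold")) {
    expect_equal(back[[field]], fit[[field]], ignore_attr = TRUE)
  }
  expect_equal(predict_posterior(back, toy$X), predict_posterior(fit, toy$X))
})
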