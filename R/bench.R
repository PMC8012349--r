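#' Configuration for the predictive benchmark
#'
#' Settings for the nested cross-validation comparison of regression
#' learners: per iteration the data are split 90/10, hyperparameters are
#' tuned by 5-fold cross-validation inside the 90% training part, the tuned
#' model is refit on the full training part and scored on the held-out 10%.
#' All algorithms see identical splits within an iteration (paired design).
#'
#' @param algorithms subset of `random_forest`, `bayes_glm`, `glm`,
#'   `componentwise_boosting`, `lasso`, `pls`.
#' @param test_fraction held-out fraction per iteration.
#' @param inner_folds folds for hyperparameter tuning.
#' @param iterations number of resampling iterations.
#' @param seed master seed; each iteration draws from its own substream.
#' @param r2_method `"ss"` (default): R2 = 1 - SS_res/SS_tot on the
#'   evaluation fold; `"cor"`: squared Pearson correlation between observed
#'   and predicted (the convention of common resampling frameworks; unbiased
#'   for a planted variance fraction even on small test folds, where the
#'   sum-of-squares form is pulled down by the variability of the fold
#'   total sum of squares).
#' @param r2_centering for `r2_method = "ss"`: `"test"` centers the total sum
#'   of squares on the evaluation fold's own mean (default); `"train"`
#'   centers on the training mean.
#' @param num_trees,mtry_grid random-forest settings.
#' @param boost_nu,boost_mstop_grid componentwise-boosting settings.
#' @param pls_ncomp_grid PLS component grid.
#' @param ridge_lambda prior precision of the Gaussian-prior linear model.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(algorithms = c("random_forest", "bayes_glm", "glm",
                                            "componentwise_boosting", "lasso", "pls"),
                             test_fraction = 0.10, inner_folds = 5,
                             iterations = 100, seed = 1,
                             r2_method = c("ss", "cor"),
                             r2_centering = c("test", "train"),
                             num_trees = 200,
                             mtry_grid = NULL,
                             boost_nu = 0.1,
                             boost_mstop_grid = c(50, 100, 200),
                             pls_ncomp_grid = 1:5,
                             ridge_lambda = 1) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  assert_config(test_fraction > 0 && test_fraction < 1,
                "`test_fraction` must lie in (0, 1)")
  assert_config(inner_folds >= 2, "`inner_folds` must be >= 2")
  assert_config(iterations >= 1, "`iterations` must be >= 1")
  structure(list(algorithms = algorithms, test_fraction = test_fraction,
                 inner_folds = inner_folds, iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 r2_method = match.arg(r2_method),
                 r2_centering = match.arg(r2_centering),
                 num_trees = num_trees, mtry_grid = mtry_grid,
                 boost_nu = boost_nu, boost_mstop_grid = boost_mstop_grid,
                 pls_ncomp_grid = pls_ncomp_grid, ridge_lambda = ridge_lambda),
            class = "benchmark_config")
}

r_squared <- function(obs, pred, method = "ss", centering = "test",
                      train_mean = NULL) {
  if (stats::sd(obs) == 0) return(NA_real_)
  if (method == "cor") {
    if (stats::sd(pred) == 0) return(0)
    return(stats::cor(obs, pred)^2)
  }
  center <- if (centering == "train" && !is.null(train_mean)) train_mean else mean(obs)
  1 - sum((obs - pred)^2) / sum((obs - center)^2)
}

## ---- learners ----------------------------------------------------------

ols_fit <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  co
}
ols_predict <- function(co, X) as.numeric(cbind(1, X) %*% co)

ridge_fit <- function(X, y, lambda) {
  xc <- colMeans(X); yc <- mean(y)
  xs <- col_sd(X); xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  b <- solve(crossprod(Xs) + diag(lambda, ncol(X)), crossprod(Xs, y - yc))
  list(b = as.numeric(b) / xs, intercept = yc - sum(as.numeric(b) / xs * xc))
}
ridge_predict <- function(fit, X) as.numeric(X %*% fit$b) + fit$intercept

# Componentwise L2 boosting: at each step fit the single best simple linear
# base learner to the current residuals and take a shrunken step.
cwb_fit <- function(X, y, mstop_grid, nu) {
  xc <- colMeans(X); yc <- mean(y)
  Xs <- sweep(X, 2, xc)
  ss <- colSums(Xs^2); ss[ss == 0] <- Inf
  beta <- numeric(ncol(X))
  resid <- y - yc
  mmax <- max(mstop_grid)
  snapshots <- matrix(0, ncol(X), length(mstop_grid))
  for (m in seq_len(mmax)) {
    cors <- as.numeric(crossprod(Xs, resid)) / ss
    rss_red <- cors^2 * ss
    j <- which.max(rss_red)
    step <- nu * cors[j]
    beta[j] <- beta[j] + step
    resid <- resid - step * Xs[, j]
    hit <- which(mstop_grid == m)
    if (length(hit)) snapshots[, hit] <- beta
  }
  list(snapshots = snapshots, mstop_grid = mstop_grid, xc = xc, yc = yc)
}
cwb_predict <- function(fit, X, which_mstop) {
  b <- fit$snapshots[, which_mstop]
  as.numeric(sweep(X, 2, fit$xc) %*% b) + fit$yc
}

# PLS coefficient path: regression vectors for 1..A components in one pass.
pls_coef_path <- function(X, y, ncomp) {
  xc <- colMeans(X); yc <- mean(y)
  Xd <- sweep(X, 2, xc); yd <- y - yc
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  path <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- Xd %*% w; t2 <- sum(tt^2)
    qa <- sum(yd * tt) / t2
    pa <- crossprod(Xd, tt) / t2
    Xd <- Xd - tt %*% t(pa); yd <- yd - qa * tt
    W[, a] <- w; P[, a] <- pa; q[a] <- qa
    path[, a] <- W[, 1:a, drop = FALSE] %*%
      solve(crossprod(P[, 1:a, drop = FALSE], W[, 1:a, drop = FALSE]),
            q[1:a])
  }
  if (ncomp < ncol(path)) for (a in seq_len(ncol(path))[-seq_len(max(ncomp, 1))])
    path[, a] <- path[, max(ncomp, 1)]
  list(path = path, xc = xc, yc = yc)
}
pls_path_predict <- function(fit, X, a) {
  as.numeric(sweep(X, 2, fit$xc) %*% fit$path[, a]) + fit$yc
}

## tune + final fit for one algorithm on one training set; returns inner-CV
## pooled predictions and a prediction function for new data.
fit_algorithm <- function(alg, X, y, folds, cfg, seed) {
  n <- nrow(X)
  cv_pred <- rep(NA_real_, n)
  if (alg == "glm") {
    for (f in unique(folds)) {
      i <- folds == f
      cv_pred[i] <- ols_predict(ols_fit(X[!i, , drop = FALSE], y[!i]),
                                X[i, , drop = FALSE])
    }
    co <- ols_fit(X, y)
    list(cv_pred = cv_pred, predict = function(Xn) ols_predict(co, Xn), par = NA)
  } else if (alg == "bayes_glm") {
    for (f in unique(folds)) {
      i <- folds == f
      cv_pred[i] <- ridge_predict(
        ridge_fit(X[!i, , drop = FALSE], y[!i], cfg$ridge_lambda),
        X[i, , drop = FALSE])
    }
    fit <- ridge_fit(X, y, cfg$ridge_lambda)
    list(cv_pred = cv_pred, predict = function(Xn) ridge_predict(fit, Xn), par = NA)
  } else if (alg == "lasso") {
    path_fit <- glmnet::glmnet(X, y, alpha = 1, lambda.min.ratio = 1e-6)
    lambdas <- path_fit$lambda
    pred_mat <- matrix(NA_real_, n, length(lambdas))
    for (f in unique(folds)) {
      i <- folds == f
      fold_fit <- glmnet::glmnet(X[!i, , drop = FALSE], y[!i], alpha = 1,
                                 lambda = lambdas)
      pred_mat[i, ] <- stats::predict(fold_fit, X[i, , drop = FALSE])
    }
    mse <- colMeans((pred_mat - y)^2)
    best <- which.min(mse)
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lambdas)
    list(cv_pred = pred_mat[, best],
         predict = function(Xn) as.numeric(stats::predict(fit, Xn, s = lambdas[best])),
         par = lambdas[best])
  } else if (alg == "componentwise_boosting") {
    grid <- cfg$boost_mstop_grid
    pred_mat <- matrix(NA_real_, n, length(grid))
    for (f in unique(folds)) {
      i <- folds == f
      fit <- cwb_fit(X[!i, , drop = FALSE], y[!i], grid, cfg$boost_nu)
      for (g in seq_along(grid)) {
        pred_mat[i, g] <- cwb_predict(fit, X[i, , drop = FALSE], g)
      }
    }
    best <- which.min(colMeans((pred_mat - y)^2))
    fit <- cwb_fit(X, y, grid, cfg$boost_nu)
    list(cv_pred = pred_mat[, best],
         predict = function(Xn) cwb_predict(fit, Xn, best), par = grid[best])
  } else if (alg == "pls") {
    grid <- cfg$pls_ncomp_grid
    amax <- min(max(grid), ncol(X), nrow(X) - 2L)
    grid <- grid[grid <= amax]
    pred_mat <- matrix(NA_real_, n, length(grid))
    for (f in unique(folds)) {
      i <- folds == f
      fit <- pls_coef_path(X[!i, , drop = FALSE], y[!i], max(grid))
      for (g in seq_along(grid)) {
        pred_mat[i, g] <- pls_path_predict(fit, X[i, , drop = FALSE], grid[g])
      }
    }
    best <- which.min(colMeans((pred_mat - y)^2))
    fit <- pls_coef_path(X, y, max(grid))
    list(cv_pred = pred_mat[, best],
         predict = function(Xn) pls_path_predict(fit, Xn, grid[best]),
         par = grid[best])
  } else if (alg == "random_forest") {
    p <- ncol(X)
    grid <- cfg$mtry_grid %||% unique(pmax(1, round(p * c(1 / 6, 1 / 3, 2 / 3))))
    pred_mat <- matrix(NA_real_, n, length(grid))
    for (f in unique(folds)) {
      i <- folds == f
      for (g in seq_along(grid)) {
        fit <- ranger::ranger(y = y[!i], x = X[!i, , drop = FALSE],
                              num.trees = cfg$num_trees, mtry = grid[g],
                              seed = seed + g, num.threads = 1)
        pred_mat[i, g] <- stats::predict(fit, data = X[i, , drop = FALSE],
                                         num.threads = 1)$predictions
      }
    }
    best <- which.min(colMeans((pred_mat - y)^2))
    fit <- ranger::ranger(y = y, x = X, num.trees = cfg$num_trees,
                          mtry = grid[best], seed = seed, num.threads = 1)
    list(cv_pred = pred_mat[, best],
         predict = function(Xn) stats::predict(fit, data = Xn,
                                               num.threads = 1)$predictions,
         par = grid[best])
  } else stop("unknown algorithm: ", alg)
}

#' Nested cross-validation benchmark
#'
#' For each of `config$iterations` iterations: draw one train/test split,
#' tune each algorithm by inner-fold cross-validation on the training part,
#' refit on the full training part, and record the pooled inner-CV R2 and
#' the held-out test R2. Splits are identical across algorithms within an
#' iteration. Iterations with a degenerate (constant) evaluation fold are
#' flagged and excluded from aggregation.
#'
#' @param X numeric predictor matrix with column names.
#' @param y numeric response.
#' @param config a [benchmark_config()].
#' @return list of class `benchmark_result`: `summary` (per algorithm mean/SD
#'   of CV and test R2), `per_iteration`, `excluded_iterations`,
#'   `split_hashes`, `config`.
#' @export
nested_cv_evaluate <- function(X, y, config = benchmark_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 20) stop("need at least 20 samples for the benchmark")
  if (anyNA(X) || anyNA(y)) stop("benchmark input must be complete")
  n <- nrow(X)
  n_test <- max(1L, round(config$test_fraction * n))
  rows <- list()
  split_hashes <- character(config$iterations)
  for (k in seq_len(config$iterations)) {
    seed_k <- substream_seed(config$seed, paste0("bench_iter_", k))
    set.seed(seed_k)
    test_idx <- sample.int(n, n_test)
    train_idx <- setdiff(seq_len(n), test_idx)
    folds <- sample(rep(seq_len(config$inner_folds),
                        length.out = length(train_idx)))
    split_hashes[k] <- paste(c(test_idx, 0L, folds), collapse = ",")
    Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]
    Xte <- X[test_idx, , drop = FALSE]; yte <- y[test_idx]
    degenerate <- stats::sd(yte) == 0 || stats::sd(ytr) == 0
    for (alg in config$algorithms) {
      if (degenerate) {
        rows[[length(rows) + 1L]] <- data.frame(
          iteration = k, algorithm = alg, cv_r2 = NA_real_, test_r2 = NA_real_,
          par = NA_real_, degenerate = TRUE)
        next
      }
      res <- fit_algorithm(alg, Xtr, ytr, folds, config, seed_k)
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = k, algorithm = alg,
        cv_r2 = r_squared(ytr, res$cv_pred, config$r2_method,
                          config$r2_centering),
        test_r2 = r_squared(yte, res$predict(Xte), config$r2_method,
                            config$r2_centering, train_mean = mean(ytr)),
        par = as.numeric(res$par)[1], degenerate = FALSE)
    }
  }
  per_iter <- do.call(rbind, rows)
  ok <- !per_iter$degenerate
  agg <- do.call(rbind, lapply(split(per_iter[ok, ], per_iter$algorithm[ok]),
                               function(d) data.frame(
                                 algorithm = d$algorithm[1],
                                 mean_cv_r2 = mean(d$cv_r2),
                                 sd_cv_r2 = stats::sd(d$cv_r2),
                                 mean_test_r2 = mean(d$test_r2),
                                 sd_test_r2 = stats::sd(d$test_r2),
                                 n_iterations = nrow(d))))
  rownames(agg) <- NULL
  structure(list(summary = agg, per_iteration = per_iter,
                 excluded_iterations = unique(per_iter$iteration[per_iter$degenerate]),
                 split_hashes = split_hashes, config = config),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Sugars-and-acids baseline model
#'
#' Ordinary least squares on exactly the five named chemistry columns
#' (`sucrose`, `glucose`, `fructose`, `malic_acid`, `citric_acid`) under the
#' identical split/iteration scheme; any other columns present in `X` are
#' excluded by construction, so augmenting `X` with extra predictors cannot
#' change the baseline.
#'
#' @param X predictor matrix containing the five named columns.
#' @param y response.
#' @param config a [benchmark_config()] (its `algorithms` are ignored).
#' @return a `benchmark_result` with the single algorithm
#'   `"baseline_sugars_acids"`.
#' @export
baseline_sugars_acids <- function(X, y, config = benchmark_config()) {
  X <- as.matrix(X)
  needed <- c("sucrose", "glucose", "fructose", "malic_acid", "citric_acid")
  missing <- setdiff(needed, colnames(X))
  if (length(missing)) {
    invalid_config(paste("baseline requires columns:", paste(missing, collapse = ", ")))
  }
  cfg <- config
  cfg$algorithms <- "glm"
  out <- nested_cv_evaluate(X[, needed, drop = FALSE], y, cfg)
  out$summary$algorithm <- "baseline_sugars_acids"
  out$per_iteration$algorithm <- "baseline_sugars_acids"
  out
}
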