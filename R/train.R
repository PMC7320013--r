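# Voxel-wise model training: ridge regression on the standardized design,
# with the regularization strength chosen by leave-one-run-out
# cross-validation inside the training set and then averaged across voxels.

#' The regularization grid
#'
#' Ten ridge penalties, log-spaced between 1 and 1e7.
#'
#' @return Numeric vector of length 10.
#' @export
lambda_grid <- function() 10^seq(0, 7, length.out = 10)

# Standardize columns; zero-variance columns become all-zero.
standardize_cols <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  Xs <- sweep(X, 2, center)
  if (is.null(scale)) {
    scale <- sqrt(colSums(Xs^2) / (nrow(X) - 1))
    scale[scale == 0] <- 1
  }
  Xs <- sweep(Xs, 2, scale, "/")
  list(X = Xs, center = center, scale = scale)
}

# Ridge coefficients for (possibly many) response columns via one SVD of the
# predictor matrix, for each penalty in `lambdas`. X is assumed centered /
# standardized and Y centered; no intercept is fit here.
ridge_solve <- function(X, Y, lambdas) {
  s <- svd(X)
  UtY <- crossprod(s$u, Y)
  lapply(lambdas, function(lam) {
    shrink <- s$d / (s$d^2 + lam)
    s$v %*% (shrink * UtY)
  })
}

#' Ridge regression
#'
#' Solves \eqn{w = (X^\top X + \lambda I)^{-1} X^\top y}. With
#' `standardize = TRUE` (the default used throughout model training) the
#' predictor columns are z-scored first, an unpenalized intercept is fit as
#' the response mean, and the returned coefficients live on the
#' standardized scale together with the centering/scaling needed to apply
#' them to new data.
#'
#' @param X Predictor matrix (rows = observations).
#' @param y Response vector or matrix (one column per response).
#' @param lambda Ridge penalty, >= 0.
#' @param standardize Z-score predictor columns before solving.
#' @param intercept Fit an unpenalized intercept (response mean).
#' @return A list with `coefficients` (p x n_response), `intercept`,
#'   `center`, `scale`, and `lambda`.
#' @export
fit_ridge <- function(X, y, lambda, standardize = TRUE, intercept = standardize) {
  X <- as.matrix(X)
  Y <- as.matrix(y)
  if (nrow(X) != nrow(Y)) stop("`X` and `y` must have the same number of rows")
  if (length(lambda) != 1 || lambda < 0) stop("`lambda` must be a single value >= 0")
  center <- NULL; scale <- NULL; mu <- rep(0, ncol(Y))
  if (standardize) {
    std <- standardize_cols(X)
    X <- std$X; center <- std$center; scale <- std$scale
  }
  if (intercept) {
    mu <- colMeans(Y)
    Y <- sweep(Y, 2, mu)
  }
  coefs <- tryCatch(
    solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, Y)),
    error = function(e) {
      stop("ridge system is singular; use lambda > 0 (", conditionMessage(e), ")")
    }
  )
  list(coefficients = coefs, intercept = mu, center = center, scale = scale,
       lambda = lambda)
}

#' Cross-validated selection of the ridge penalty
#'
#' For every voxel and every penalty in the grid, weights are fit on all
#' training runs but one and scored by the Pearson correlation between the
#' predicted and observed time course of the held-out run; each training run
#' serves as validation set once and scores are averaged over folds. Each
#' voxel's penalty is the argmax of its fold-averaged score (ties towards
#' the smaller penalty). A voxel whose best fold-averaged score is <= 0 --
#' i.e. regularization never lifts its validation correlation above zero --
#' is flagged `excluded` from the later penalty averaging.
#'
#' The movement covariate is included in every fit but dropped from every
#' prediction, matching the final model test.
#'
#' @param dataset A `"voxel_dataset"`.
#' @param design A [build_design()] object for the whole session.
#' @param train_runs Run labels making up the training set (>= 2).
#' @param grid Penalty grid, default [lambda_grid()].
#' @return A list with `lambda` (per voxel), `excluded` (logical),
#'   `training_score` (fold-averaged validation r at the selected penalty),
#'   and `score_matrix` (voxel x penalty fold-averaged scores).
#' @export
select_lambda <- function(dataset, design, train_runs, grid = lambda_grid()) {
  if (length(train_runs) < 2) stop("need at least 2 training runs")
  n_k <- ncol(design$X)
  mean_scores <- 0
  for (val_run in train_runs) {
    fit_runs <- setdiff(train_runs, val_run)
    fit_rows <- design$run_ids %in% fit_runs
    val_rows <- design$run_ids %in% val_run
    Xf <- cbind(design$X[fit_rows, , drop = FALSE], design$movement[fit_rows])
    std <- standardize_cols(Xf)
    Yf <- dataset$Y[fit_rows, , drop = FALSE]
    Yfc <- sweep(Yf, 2, colMeans(Yf))
    coefs <- ridge_solve(std$X, Yfc, grid)
    Xv <- cbind(design$X[val_rows, , drop = FALSE], design$movement[val_rows])
    Xvs <- standardize_cols(Xv, std$center, std$scale)$X[, seq_len(n_k), drop = FALSE]
    Yv <- dataset$Y[val_rows, , drop = FALSE]
    fold <- vapply(coefs, function(w) {
      pred <- Xvs %*% w[seq_len(n_k), , drop = FALSE]
      paired_col_cor(pred, Yv)
    }, numeric(ncol(dataset$Y)))
    fold[is.na(fold)] <- 0
    mean_scores <- mean_scores + fold / length(train_runs)
  }
  mean_scores <- matrix(mean_scores, ncol = length(grid))
  best_idx <- max.col(mean_scores, ties.method = "first")
  best_score <- mean_scores[cbind(seq_len(nrow(mean_scores)), best_idx)]
  list(lambda = grid[best_idx], excluded = best_score <= 0,
       training_score = best_score, score_matrix = mean_scores)
}

#' Train the encoding model for one basis set
#'
#' Runs [select_lambda()] on the training runs, averages the selected
#' penalty geometrically across non-excluded voxels (the grid is
#' log-spaced, so averaging in log space respects its geometry), and fits
#' the final voxel-wise weights on the full training set under that single
#' penalty -- excluded voxels still receive final weights. The movement
#' covariate is fit alongside the kernels; its weight is stored but never
#' used for prediction.
#'
#' @param dataset A `"voxel_dataset"`.
#' @param design A [build_design()] for the whole session.
#' @param test_run The held-out test run (default 3, the run halfway
#'   through a five-run session); training runs are all others.
#' @param train_runs Optional explicit training runs (overrides `test_run`).
#' @param grid Penalty grid.
#' @return An object of class `"weight_map"`: list with `weights`
#'   (voxel x kernel, on the standardized design scale), `movement_weight`,
#'   `intercept`, `center`/`scale` (training standardization of the
#'   kernel + movement columns), `lambda` (the averaged penalty),
#'   `lambda_voxel`, `excluded`, `training_score`, `fwhm`, `train_runs`,
#'   `test_run`.
#' @export
train_model <- function(dataset, design, test_run = 3, train_runs = NULL,
                        grid = lambda_grid()) {
  runs <- unique(design$run_ids)
  if (is.null(train_runs)) {
    if (!test_run %in% runs) stop("`test_run` not present in the design")
    train_runs <- setdiff(runs, test_run)
  } else if (test_run %in% train_runs) {
    stop("training runs must exclude the test run")
  }
  sel <- select_lambda(dataset, design, train_runs, grid)
  if (all(sel$excluded)) {
    stop("all voxels were excluded from penalty determination; ",
         "no voxel reached a positive cross-validated score")
  }
  lambda_final <- exp(mean(log(sel$lambda[!sel$excluded])))

  rows <- design$run_ids %in% train_runs
  n_k <- ncol(design$X)
  Xt <- cbind(design$X[rows, , drop = FALSE], design$movement[rows])
  std <- standardize_cols(Xt)
  Yt <- dataset$Y[rows, , drop = FALSE]
  mu <- colMeans(Yt)
  coefs <- ridge_solve(std$X, sweep(Yt, 2, mu), lambda_final)[[1]]

  out <- list(
    weights = t(coefs[seq_len(n_k), , drop = FALSE]),
    movement_weight = coefs[n_k + 1, ],
    intercept = mu, center = std$center, scale = std$scale,
    lambda = lambda_final, lambda_voxel = sel$lambda,
    excluded = sel$excluded, training_score = sel$training_score,
    fwhm = design$fwhm, train_runs = train_runs, test_run = test_run
  )
  class(out) <- "weight_map"
  out
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf(
    "Weight map: %d voxels x %d kernels (FWHM %g deg), lambda %.3g, %d excluded\n",
    nrow(x$weights), ncol(x$weights), x$fwhm, x$lambda, sum(x$excluded)))
  invisible(x)
}
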