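# Forward model test on the held-out run: voxel-wise prediction, Pearson
# performance, weight-shuffle null Z scores, ROI aggregation over the most
# reliable training voxels, tuning-width selection, behavioral-state
# contrasts, and leave-one-run-out evaluation.

#' Predict voxel time courses from trained weights
#'
#' Applies the training-set standardization to the kernel columns of a
#' design and multiplies by the trained kernel weights; the movement
#' covariate is excluded from prediction and the training intercept added.
#'
#' @param wm A [train_model()] weight map.
#' @param design A `"design_matrix"` (typically the test-run rows, see
#'   [subset_design()]); its basis must match the weights.
#' @return TR x voxel matrix of predicted time courses.
#' @export
predict_timecourse <- function(wm, design) {
  n_k <- ncol(wm$weights)
  if (ncol(design$X) != n_k || design$fwhm != wm$fwhm) {
    stop("design basis does not match the weight map (FWHM ",
         design$fwhm, " vs ", wm$fwhm, ")")
  }
  Xs <- standardize_cols(design$X, wm$center[seq_len(n_k)],
                         wm$scale[seq_len(n_k)])$X
  sweep(Xs %*% t(wm$weights), 2, wm$intercept, "+")
}

#' Model performance (Pearson correlation)
#'
#' @param pred,observed Vectors, or matrices with matched columns.
#' @return Per-column Pearson correlation.
#' @export
model_performance <- function(pred, observed) {
  pred <- as.matrix(pred); observed <- as.matrix(observed)
  if (!all(dim(pred) == dim(observed))) stop("shape mismatch")
  r <- paired_col_cor(pred, observed)
  if (any(is.na(r))) stop("zero-variance time course: correlation undefined")
  r
}

# k unique non-identity permutations of 1..K, as a K x k index matrix.
# k is capped at K! - 1 when the permutation space is small.
unique_permutations <- function(K, k, seed = NULL) {
  n_avail <- factorial(K) - 1
  if (k > n_avail) k <- n_avail
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    assign(paste(seq_len(K), collapse = ","), TRUE, envir = seen)  # identity
    out <- matrix(0L, K, k)
    got <- 0
    while (got < k) {
      p <- sample.int(K)
      key <- paste(p, collapse = ",")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        got <- got + 1
        out[, got] <- p
      }
    }
    out
  })
}

#' Shuffle-null standardized model performance
#'
#' Builds each voxel's null by permuting its kernel-weight vector (`k`
#' unique non-identity permutations, identity excluded), recomputing the
#' predicted time course and its Pearson correlation with the observed one,
#' and standardizing the observed correlation against that null:
#' \eqn{z = (r_{obs} - \mathrm{mean}(r_{null})) / \mathrm{sd}(r_{null})}.
#' Voxels with constant weight vectors have a degenerate null (all
#' permutations identical) and get `z = 0` with a flag.
#'
#' @param wm A weight map.
#' @param design Test-run design matrix.
#' @param observed TR x voxel matrix of observed test time courses.
#' @param voxels Optional voxel indices to score (default all).
#' @param k Number of unique weight shuffles.
#' @param seed Optional integer seed.
#' @return A list with `z`, `r_obs`, `null_mean`, `null_sd`, `degenerate`.
#' @export
shuffle_null_z <- function(wm, design, observed, voxels = NULL, k = 500,
                           seed = NULL) {
  n_k <- ncol(wm$weights)
  voxels <- voxels %||% seq_len(nrow(wm$weights))
  Xs <- standardize_cols(design$X, wm$center[seq_len(n_k)],
                         wm$scale[seq_len(n_k)])$X
  perms <- unique_permutations(n_k, k, seed)
  n_perm <- ncol(perms)
  W <- wm$weights[voxels, , drop = FALSE]
  r_obs <- paired_col_cor(Xs %*% t(W), observed[, voxels, drop = FALSE])
  z <- numeric(length(voxels))
  null_mean <- numeric(length(voxels)); null_sd <- numeric(length(voxels))
  degenerate <- logical(length(voxels))
  for (i in seq_along(voxels)) {
    w <- W[i, ]
    if (max(w) - min(w) == 0) {
      degenerate[i] <- TRUE
      next
    }
    P <- matrix(w[perms], n_k, n_perm)
    null_r <- col_cor(Xs %*% P, observed[, voxels[i]])
    null_r[is.na(null_r)] <- 0
    null_mean[i] <- mean(null_r)
    null_sd[i] <- stats::sd(null_r)
    z[i] <- if (null_sd[i] > 0) (r_obs[i] - null_mean[i]) / null_sd[i] else 0
    degenerate[i] <- null_sd[i] == 0
  }
  list(z = z, r_obs = r_obs, null_mean = null_mean, null_sd = null_sd,
       degenerate = degenerate)
}

#' Select the most reliable training voxels
#'
#' @param training_scores Per-voxel cross-validated training correlations.
#' @param top_frac Fraction to keep (default the top quarter); at least one
#'   voxel is always selected.
#' @return Integer indices of the `ceiling(top_frac * n)` best voxels.
#' @export
roi_select <- function(training_scores, top_frac = 0.25) {
  n <- length(training_scores)
  if (n == 0) stop("empty ROI")
  m <- max(1, ceiling(top_frac * n))
  order(training_scores, decreasing = TRUE)[seq_len(m)]
}

#' ROI-level model performance
#'
#' Mean shuffle-null Z over the voxels with the highest training
#' predictability.
#'
#' @param z Per-voxel Z scores (for all voxels).
#' @param training_scores Per-voxel training scores.
#' @param top_frac Fraction of voxels to average over.
#' @return The mean Z over the selected voxels.
#' @export
roi_aggregate <- function(z, training_scores, top_frac = 0.25) {
  mean(z[roi_select(training_scores, top_frac)])
}

#' Forward-model evaluation on the held-out run
#'
#' Predicts the test run, computes per-voxel Pearson performance, selects
#' the top training voxels, converts their performance to shuffle-null Z
#' scores, and averages those into the ROI-level tuning strength.
#'
#' @param wm A [train_model()] weight map.
#' @param design Full-session design matrix for the same basis.
#' @param dataset The `"voxel_dataset"`.
#' @param k Number of weight shuffles for the null.
#' @param seed Optional integer seed.
#' @param top_frac Voxel-selection fraction.
#' @return An object of class `"tuning_result"`: list with `per_voxel`
#'   (data frame: `r`, `training_score`, `selected`, `z`), `roi_z`,
#'   `mean_r` (across all voxels), `fwhm`, `test_run`.
#' @export
evaluate_model <- function(wm, design, dataset, k = 500, seed = NULL,
                           top_frac = 0.25) {
  dtest <- subset_design(design, wm$test_run)
  rows <- design$run_ids %in% wm$test_run
  Y_test <- dataset$Y[rows, , drop = FALSE]
  pred <- predict_timecourse(wm, dtest)
  r <- paired_col_cor(pred, Y_test)
  sel <- roi_select(wm$training_score, top_frac)
  nz <- shuffle_null_z(wm, dtest, Y_test, voxels = sel, k = k, seed = seed)
  z_all <- rep(NA_real_, ncol(Y_test))
  z_all[sel] <- nz$z
  out <- list(
    per_voxel = data.frame(
      r = r, training_score = wm$training_score,
      selected = seq_along(r) %in% sel, z = z_all
    ),
    roi_z = mean(nz$z), mean_r = mean(r, na.rm = TRUE),
    fwhm = wm$fwhm, test_run = wm$test_run
  )
  class(out) <- "tuning_result"
  out
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("Tuning result (FWHM %g deg, test run %s): roi_z %.3f, mean r %.3f\n",
              x$fwhm, paste(x$test_run, collapse = ","), x$roi_z, x$mean_r))
  invisible(x)
}

#' Select the tuning width from per-basis performances
#'
#' The tuning width is the kernel FWHM whose basis set maximizes the
#' ROI-level performance; exact ties break towards the narrower kernel.
#'
#' @param roi_z Per-basis performances.
#' @param fwhms Corresponding kernel widths in degrees.
#' @return A list with `optimal_fwhm` and `strength` (the maximum).
#' @export
select_tuning_width <- function(roi_z, fwhms) {
  stopifnot(length(roi_z) == length(fwhms))
  best <- which(roi_z == max(roi_z))
  pick <- best[which.min(fwhms[best])]
  list(optimal_fwhm = fwhms[pick], strength = roi_z[pick])
}

#' Train and test across all basis sets
#'
#' Repeats model training and forward testing for each kernel width and
#' collects the ROI-level results.
#'
#' @param dataset A `"voxel_dataset"`.
#' @param log Behavior log used to build designs (ignored when `designs`
#'   given).
#' @param fwhms Kernel widths to iterate over.
#' @param designs Optional precomputed list of designs named by FWHM.
#' @param test_run Held-out run.
#' @param k Shuffles for the null.
#' @param seed Optional integer seed.
#' @param top_frac Voxel-selection fraction.
#' @return A list with `table` (data frame: `fwhm`, `roi_z`, `mean_r`,
#'   `lambda`, `n_excluded`), `results` (per-basis `"tuning_result"`s),
#'   `optimal_fwhm`, and `strength`.
#' @export
fit_roi_curve <- function(dataset, log = NULL, fwhms = standard_fwhms(),
                          designs = NULL, test_run = 3, k = 500, seed = NULL,
                          top_frac = 0.25) {
  if (is.null(designs)) {
    if (is.null(log)) stop("provide `log` or precomputed `designs`")
    designs <- lapply(fwhms, function(f) build_design(log, f))
    names(designs) <- as.character(fwhms)
  }
  results <- vector("list", length(fwhms))
  rows <- vector("list", length(fwhms))
  for (i in seq_along(fwhms)) {
    d <- designs[[as.character(fwhms[i])]]
    wm <- train_model(dataset, d, test_run = test_run)
    ev <- evaluate_model(wm, d, dataset, k = k, seed = seed,
                         top_frac = top_frac)
    results[[i]] <- ev
    rows[[i]] <- data.frame(fwhm = fwhms[i], roi_z = ev$roi_z,
                            mean_r = ev$mean_r, lambda = wm$lambda,
                            n_excluded = sum(wm$excluded))
  }
  tab <- do.call(rbind, rows)
  width <- select_tuning_width(tab$roi_z, tab$fwhm)
  list(table = tab, results = results,
       optimal_fwhm = width$optimal_fwhm, strength = width$strength)
}

#' Locomotion vs stationary state models
#'
#' Repeats the full train/test procedure twice, restricting the within-TR
#' design aggregation once to locomotion and once to stationary samples
#' (the TR grid and convolution are identical, so performances are
#' comparable), and contrasts the ROI-level performances per basis set.
#'
#' @param dataset A `"voxel_dataset"`.
#' @param log Behavior log.
#' @param fwhms Kernel widths.
#' @param speed_threshold Passed to [label_states()].
#' @param test_run,k,seed,top_frac As in [fit_roi_curve()].
#' @return A list of class `"state_contrast"` with `table` (data frame:
#'   `fwhm`, `roi_z_locomotion`, `roi_z_stationary`, `delta`) and
#'   `best_delta_fwhm` (the width with the largest absolute contrast).
#' @export
state_models <- function(dataset, log, fwhms = standard_fwhms(),
                         speed_threshold = 0, test_run = 3, k = 500,
                         seed = NULL, top_frac = 0.25) {
  labels <- label_states(log, speed_threshold)
  for (st in c("locomotion", "stationary")) {
    if (!any(labels == st)) stop("no samples in state '", st, "'")
  }
  curves <- lapply(c("locomotion", "stationary"), function(st) {
    designs <- lapply(fwhms, function(f) {
      build_design(log, f, state = st, state_labels = labels)
    })
    names(designs) <- as.character(fwhms)
    fit_roi_curve(dataset, designs = designs, fwhms = fwhms,
                  test_run = test_run, k = k, seed = seed,
                  top_frac = top_frac)
  })
  tab <- data.frame(
    fwhm = fwhms,
    roi_z_locomotion = curves[[1]]$table$roi_z,
    roi_z_stationary = curves[[2]]$table$roi_z
  )
  tab$delta <- tab$roi_z_locomotion - tab$roi_z_stationary
  out <- list(table = tab,
              best_delta_fwhm = tab$fwhm[which.max(abs(tab$delta))],
              locomotion = curves[[1]], stationary = curves[[2]])
  class(out) <- "state_contrast"
  out
}

#' Leave-one-run-out evaluation across all runs
#'
#' Each run serves as the test set once, with weights trained on all other
#' runs; the run-indexed ROI performances trace tuning over time.
#'
#' @param dataset A `"voxel_dataset"`.
#' @param design Full-session design matrix for one basis.
#' @param k,seed,top_frac As in [evaluate_model()].
#' @return Data frame with one row per run: `run`, `roi_z`, `mean_r`.
#' @export
loro_evaluate <- function(dataset, design, k = 500, seed = NULL,
                          top_frac = 0.25) {
  runs <- unique(design$run_ids)
  if (length(runs) < 3) stop("leave-one-run-out needs at least 3 runs")
  rows <- lapply(runs, function(r) {
    wm <- train_model(dataset, design, test_run = r)
    ev <- evaluate_model(wm, design, dataset, k = k, seed = seed,
                         top_frac = top_frac)
    data.frame(run = r, roi_z = ev$roi_z, mean_r = ev$mean_r)
  })
  do.call(rbind, rows)
}
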