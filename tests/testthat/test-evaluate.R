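# Forward model test: prediction, shuffle nulls, ROI aggregation,
# tuning-width selection, state contrasts, and leave-one-run-out.

test_that("prediction applies training standardization and skips movement", {
  d <- small_design(30)
  ds <- small_dataset(noise = 1, n_voxels = 6)
  wm <- train_model(ds, d)
  dtest <- subset_design(d, 3)
  pred <- predict_timecourse(wm, dtest)
  expect_equal(dim(pred), c(24, 6))
  # hand-built prediction for voxel 2
  Xs <- sweep(sweep(dtest$X, 2, wm$center[1:12]), 2, wm$scale[1:12], "/")
  expect_equal(pred[, 2], drop(Xs %*% wm$weights[2, ]) + wm$intercept[2],
               tolerance = 1e-12)
  # changing the movement weight must not change predictions
  wm2 <- wm
  wm2$movement_weight <- wm$movement_weight + 100
  expect_identical(predict_timecourse(wm2, dtest), pred)
})

test_that("prediction refuses a mismatched basis", {
  ds <- small_dataset(noise = 1, n_voxels = 4)
  wm <- train_model(ds, small_design(30))
  expect_error(predict_timecourse(wm, subset_design(small_design(60), 3)),
               "does not match")
})

test_that("zero kernel weights predict a constant (the intercept)", {
  ds <- small_dataset(noise = 1, n_voxels = 3)
  wm <- train_model(ds, small_design(30))
  wm$weights[] <- 0
  pred <- predict_timecourse(wm, subset_design(small_design(30), 3))
  for (v in 1:3) expect_equal(unique(pred[, v]), wm$intercept[v])
})

test_that("model_performance is the Pearson correlation, with guards", {
  x <- sin(1:50)
  expect_equal(model_performance(x, 3 * x + 2), 1, tolerance = 1e-12)
  expect_equal(model_performance(x, -x), -1, tolerance = 1e-12)
  expect_equal(unname(model_performance(cbind(x, -x), cbind(x, x))),
               c(1, -1), tolerance = 1e-12)
  expect_error(model_performance(x, x[1:10]), "shape mismatch")
  expect_error(model_performance(x, rep(1, 50)), "zero-variance")
})

test_that("null correlations of unrelated series are narrow at session length", {
  # at 210 TRs, |r| < 0.2 for the overwhelming majority of noise pairs
  set.seed(8)
  r <- replicate(500, cor(rnorm(210), rnorm(210)))
  expect_gt(mean(abs(r) < 0.2), 0.95)
})

test_that("unique_permutations yields unique non-identity permutations", {
  P <- vhdtune:::unique_permutations(6, 100, seed = 1)
  expect_equal(dim(P), c(6, 100))
  keys <- apply(P, 2, paste, collapse = ",")
  expect_equal(length(unique(keys)), 100)
  expect_false(any(keys == paste(1:6, collapse = ",")))
  for (j in 1:100) expect_equal(sort(P[, j]), 1:6)
  # the permutation space caps the request: 3! - 1 = 5
  P3 <- vhdtune:::unique_permutations(3, 10, seed = 2)
  expect_equal(ncol(P3), 5)
  expect_equal(length(unique(apply(P3, 2, paste, collapse = ","))), 5)
})

test_that("shuffle-null z is near zero for noise and large for signal", {
  d <- small_design(30)
  # strong signal: noiseless voxels
  truth <- make_ground_truth("unimodal", 30, noise_multiplier = 0, seed = 4)
  ds <- simulate_voxels(small_log(), truth, 3, seed = 5, design = d)
  wm <- train_model(ds, d)
  dtest <- subset_design(d, 3)
  Y_test <- ds$Y[d$run_ids == 3, ]
  nz <- shuffle_null_z(wm, dtest, Y_test, k = 200, seed = 1)
  # unimodal weights keep some correlation under shuffling, so the null sd
  # is wide; z is bounded but must still be clearly positive
  expect_true(all(nz$z > 1.5))
  expect_true(all(nz$r_obs > 0.99))
  expect_false(any(nz$degenerate))
})

test_that("constant weight vectors give a degenerate null and z = 0", {
  d <- small_design(30)
  ds <- small_dataset(noise = 1, n_voxels = 2)
  wm <- train_model(ds, d)
  wm$weights[1, ] <- 2  # constant: every permutation is the identity
  dtest <- subset_design(d, 3)
  nz <- shuffle_null_z(wm, dtest, ds$Y[d$run_ids == 3, ], k = 50, seed = 1)
  expect_true(nz$degenerate[1])
  expect_equal(nz$z[1], 0)
  expect_false(nz$degenerate[2])
})

test_that("shuffle nulls are reproducible under a seed", {
  d <- small_design(30)
  ds <- small_dataset(noise = 2, n_voxels = 3)
  wm <- train_model(ds, d)
  dtest <- subset_design(d, 3)
  Y_test <- ds$Y[d$run_ids == 3, ]
  a <- shuffle_null_z(wm, dtest, Y_test, k = 100, seed = 7)
  b <- shuffle_null_z(wm, dtest, Y_test, k = 100, seed = 7)
  expect_identical(a, b)
})

test_that("roi_select keeps the ceiling of the top quarter", {
  scores <- c(0.1, 0.9, 0.5, 0.2)
  expect_equal(roi_select(scores), 2)          # ceiling(1) of 4
  expect_equal(sort(roi_select(scores, 0.5)), c(2, 3))
  expect_equal(length(roi_select(rnorm(13))), 4)  # ceiling(3.25)
  expect_equal(roi_select(0.3), 1)             # never empty
  expect_error(roi_select(numeric(0)), "empty ROI")
})

test_that("roi_aggregate averages z over the selected voxels", {
  z <- c(1, 2, 3, 4)
  scores <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(roi_aggregate(z, scores, top_frac = 0.5), mean(c(1, 2)))
  expect_equal(roi_aggregate(rep(2, 8), rnorm(8)), 2)
})

test_that("evaluate_model ties the pieces together", {
  d <- small_design(30)
  ds <- small_dataset(noise = 1, n_voxels = 8)
  wm <- train_model(ds, d)
  ev <- evaluate_model(wm, d, ds, k = 100, seed = 3)
  expect_s3_class(ev, "tuning_result")
  expect_equal(nrow(ev$per_voxel), 8)
  expect_equal(sum(ev$per_voxel$selected), 2)  # ceiling(0.25 * 8)
  # z is reported only for selected voxels
  expect_equal(is.na(ev$per_voxel$z), !ev$per_voxel$selected)
  expect_equal(ev$roi_z, mean(ev$per_voxel$z, na.rm = TRUE))
  expect_equal(ev$mean_r, mean(ev$per_voxel$r))
  # tuned voxels at unit noise have clearly positive tuning strength
  expect_gt(ev$roi_z, 1)
  expect_gt(ev$mean_r, 0.4)
})

test_that("tuning-width ties break towards the narrower kernel", {
  expect_equal(select_tuning_width(c(1, 3, 3, 2), c(10, 20, 30, 45)),
               list(optimal_fwhm = 20, strength = 3))
  expect_equal(select_tuning_width(c(5, 1), c(60, 10))$optimal_fwhm, 60)
  expect_error(select_tuning_width(c(1, 2), c(10, 20, 30)))
})

test_that("fit_roi_curve peaks at the simulated tuning width", {
  fwhms <- c(15, 30, 60)
  truths <- lapply(1:20, function(i) {
    make_ground_truth("unimodal", 30, noise_multiplier = 1, seed = 50 + i)
  })
  ds <- simulate_voxels(small_log(), truths, 20, seed = 77,
                        design = small_design(30))
  curve <- fit_roi_curve(ds, small_log(), fwhms = fwhms, k = 100, seed = 5)
  expect_equal(nrow(curve$table), 3)
  expect_equal(curve$table$fwhm, fwhms)
  expect_equal(curve$optimal_fwhm, 30)
  expect_equal(curve$strength, max(curve$table$roi_z))
})

test_that("state models contrast locomotion against stationary designs", {
  log <- small_log()
  # voxels driven only by the locomotion design: contrast must favor it
  labels <- label_states(log)
  d_loco <- build_design(log, 30, state = "locomotion", state_labels = labels)
  truth <- make_ground_truth("unimodal", 30, noise_multiplier = 0.5, seed = 3)
  W <- sapply(1:10, function(i) truth$weights)
  signal <- d_loco$X %*% W
  set.seed(12)
  ds <- list(Y = signal + matrix(rnorm(length(signal)),
                                 nrow(signal)) * 0.5 * sd(signal),
             run_ids = d_loco$run_ids, tr = log$tr,
             truth = rep(list(truth), 10), true_fwhm = 30)
  class(ds) <- "voxel_dataset"
  sc <- state_models(ds, log, fwhms = 30, k = 100, seed = 4)
  expect_s3_class(sc, "state_contrast")
  expect_equal(nrow(sc$table), 1)
  expect_gt(sc$table$delta, 0)
  expect_equal(sc$best_delta_fwhm, 30)
})

test_that("leave-one-run-out evaluates every run once", {
  d <- small_design(30)
  ds <- small_dataset(noise = 1, n_voxels = 6)
  tab <- loro_evaluate(ds, d, k = 50, seed = 2)
  expect_equal(tab$run, 1:5)
  expect_true(all(is.finite(tab$roi_z)))
  d2 <- d
  d2$X <- d$X[d$run_ids <= 2, ]
  d2$movement <- d$movement[d$run_ids <= 2]
  d2$run_ids <- d$run_ids[d$run_ids <= 2]
  ds2 <- ds
  ds2$Y <- ds$Y[ds$run_ids <= 2, ]
  ds2$run_ids <- ds$run_ids[ds$run_ids <= 2]
  expect_error(loro_evaluate(ds2, d2), "at least 3 runs")
})
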