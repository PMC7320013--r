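# End-to-end drivers: full multi-basis analysis of one dataset, the
# simulation-based parameter-recovery study, and null-calibration checks.

#' Experiment configuration
#'
#' Collects the pipeline-level defaults: the iterated kernel widths, the
#' ridge penalty grid, the held-out test run (the run halfway through a
#' five-run session), the shuffle counts for voxel-level nulls and
#' group-level permutation tests, and the voxel-selection fraction.
#'
#' @param fwhms Kernel widths in degrees.
#' @param grid Ridge penalty grid.
#' @param test_run Held-out test run.
#' @param k_model Weight shuffles per voxel (model-level null).
#' @param k_group Permutations for group-level tests.
#' @param top_frac Voxel-selection fraction.
#' @param seed Optional master seed.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(fwhms = standard_fwhms(), grid = lambda_grid(),
                              test_run = 3, k_model = 500, k_group = 10000,
                              top_frac = 0.25, seed = NULL) {
  out <- list(fwhms = fwhms, grid = grid, test_run = test_run,
              k_model = k_model, k_group = k_group, top_frac = top_frac,
              seed = seed)
  class(out) <- "experiment_config"
  out
}

#' Run the full encoding-model pipeline on one dataset
#'
#' Design construction, training, and forward testing for every basis set,
#' plus the inverted-encoding-model read-out at the selected tuning width.
#'
#' @param log Behavior log.
#' @param dataset A `"voxel_dataset"`.
#' @param config An [experiment_config()].
#' @param states Also fit locomotion/stationary state models.
#' @return A list with `curve` (the [fit_roi_curve()] result), `iem`
#'   (the [iem_analysis()] at the optimal width), `state_contrast`
#'   (when `states = TRUE`), and `config`.
#' @export
run_pipeline <- function(log, dataset, config = experiment_config(),
                         states = FALSE) {
  designs <- lapply(config$fwhms, function(f) build_design(log, f))
  names(designs) <- as.character(config$fwhms)
  curve <- fit_roi_curve(dataset, designs = designs, fwhms = config$fwhms,
                         test_run = config$test_run, k = config$k_model,
                         seed = config$seed, top_frac = config$top_frac)
  best <- as.character(curve$optimal_fwhm)
  wm_best <- train_model(dataset, designs[[best]], test_run = config$test_run)
  iem <- iem_analysis(wm_best, designs[[best]], dataset, k = config$k_model,
                      seed = config$seed, top_frac = config$top_frac)
  contrast <- NULL
  if (states) {
    contrast <- state_models(dataset, log, fwhms = config$fwhms,
                             test_run = config$test_run, k = config$k_model,
                             seed = config$seed, top_frac = config$top_frac)
  }
  list(curve = curve, iem = iem, state_contrast = contrast, config = config)
}

#' Simulation-based parameter recovery
#'
#' For every cell of a profiles x true-widths x noise-multipliers grid,
#' simulates `n_voxels` tuned voxels from one shared behavior log (each
#' voxel with its own randomly drawn preferred directions), runs the full
#' train/test pipeline across all basis sets, and records the
#' voxel-averaged test performance per basis, the winning width, and the
#' forward and inverted read-outs at the true width.
#'
#' @param profiles Tuning profiles to simulate.
#' @param widths True kernel widths in degrees.
#' @param noises Noise multipliers (noise SD in units of signal SD).
#' @param n_voxels Voxels per cell.
#' @param seed Master seed; all per-cell seeds derive from it.
#' @param log Optional behavior log (defaults to a session simulated from
#'   `config`).
#' @param config A [sim_config()] for the behavior session.
#' @param fwhms Basis widths iterated over by the pipeline.
#' @param k Shuffles for the voxel-level nulls.
#' @param top_frac Voxel-selection fraction.
#' @param test_run Held-out run.
#' @return A list of class `"recovery_report"` with `cells` (one row per
#'   grid cell: winner width, whether it equals the truth, mean and SE of
#'   the test performance at the true width, forward `roi_z` and IEM
#'   `iem_z`), `perf` (long data frame of voxel-averaged performance per
#'   cell and basis), and `log`.
#' @export
run_recovery <- function(profiles = c("unimodal", "bimodal", "random"),
                         widths = c(10, 30, 60), noises = c(1, 3, 6),
                         n_voxels = 200, seed = 1, log = NULL,
                         config = sim_config(), fwhms = standard_fwhms(),
                         k = 500, top_frac = 0.25, test_run = 3) {
  if (is.null(log)) log <- simulate_session(config, seed = seed)
  designs <- lapply(fwhms, function(f) build_design(log, f))
  names(designs) <- as.character(fwhms)

  grid <- expand.grid(profile = profiles, true_fwhm = widths, noise = noises,
                      stringsAsFactors = FALSE)
  cells <- vector("list", nrow(grid))
  perf <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$profile[i]; w <- grid$true_fwhm[i]; s <- grid$noise[i]
    cell_seed <- seed + 101 * i
    truths <- with_seed(cell_seed, {
      lapply(seq_len(n_voxels), function(v) {
        make_ground_truth(p, w, noise_multiplier = s)
      })
    })
    dataset <- simulate_voxels(log, truths, n_voxels, seed = cell_seed + 1,
                               design = designs[[as.character(w)]])
    mean_r <- numeric(length(fwhms))
    wm_true <- NULL
    for (j in seq_along(fwhms)) {
      d <- designs[[as.character(fwhms[j])]]
      wm <- train_model(dataset, d, test_run = test_run)
      dtest <- subset_design(d, test_run)
      rows <- d$run_ids %in% test_run
      r <- paired_col_cor(predict_timecourse(wm, dtest),
                          dataset$Y[rows, , drop = FALSE])
      mean_r[j] <- mean(r, na.rm = TRUE)
      if (fwhms[j] == w) {
        wm_true <- wm
        r_true <- r
      }
    }
    win <- select_tuning_width(mean_r, fwhms)
    d_true <- designs[[as.character(w)]]
    ev <- evaluate_model(wm_true, d_true, dataset, k = k,
                         seed = cell_seed + 2, top_frac = top_frac)
    iem <- iem_analysis(wm_true, d_true, dataset, k = k,
                        seed = cell_seed + 3, top_frac = top_frac)
    cells[[i]] <- data.frame(
      profile = p, true_fwhm = w, noise = s,
      winner_fwhm = win$optimal_fwhm, correct = win$optimal_fwhm == w,
      mean_r_true = mean_r[fwhms == w],
      se_true = stats::sd(r_true) / sqrt(length(r_true)),
      roi_z = ev$roi_z, iem_z = iem$score_z
    )
    perf[[i]] <- data.frame(profile = p, true_fwhm = w, noise = s,
                            basis_fwhm = fwhms, mean_r = mean_r)
  }
  out <- list(cells = do.call(rbind, cells), perf = do.call(rbind, perf),
              log = log, fwhms = fwhms, n_voxels = n_voxels, seed = seed)
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery report: %d cells x %d voxels; true width won in %d/%d\n",
              nrow(x$cells), x$n_voxels, sum(x$cells$correct), nrow(x$cells)))
  invisible(x)
}

#' Null calibration of the forward ROI read-out
#'
#' Runs the full train/test pipeline on replicated pure-noise ROIs and
#' returns the ROI-level Z scores. Because voxel selection uses training
#' data that is independent of the test run, the expected ROI Z under the
#' null is zero.
#'
#' @param n_rois Number of pure-noise ROIs.
#' @param n_voxels Voxels per ROI.
#' @param log Behavior log providing the design.
#' @param fwhm Basis width used for the null model.
#' @param k Shuffles per voxel.
#' @param seed Master seed.
#' @param top_frac Voxel-selection fraction.
#' @param test_run Held-out run.
#' @return Numeric vector of `n_rois` ROI-level Z scores.
#' @export
calibrate_null_roi_z <- function(n_rois = 100, n_voxels = 50, log,
                                 fwhm = 30, k = 500, seed = 1,
                                 top_frac = 0.25, test_run = 3) {
  design <- build_design(log, fwhm)
  vapply(seq_len(n_rois), function(i) {
    dataset <- simulate_null_voxels(log$trs_per_run, log$n_runs, n_voxels,
                                    tr = log$tr, seed = seed + 13 * i)
    wm <- train_model(dataset, design, test_run = test_run)
    ev <- evaluate_model(wm, design, dataset, k = k, seed = seed + 13 * i + 1,
                         top_frac = top_frac)
    ev$roi_z
  }, numeric(1))
}

#' Type-I error calibration of the sign-flip test
#'
#' Draws `n_rep` null groups of `n` standard-normal scores, applies the
#' exhaustive one-sample sign-flip test to each, and returns the fraction
#' rejected at level `alpha`.
#'
#' @param n_rep Number of null replicates.
#' @param n Group size.
#' @param alpha Rejection level.
#' @param tail Test tail.
#' @param seed Integer seed.
#' @return Rejection frequency.
#' @export
calibrate_signflip <- function(n_rep = 1000, n = 10, alpha = 0.05,
                               tail = "one", seed = 1) {
  values <- with_seed(seed, matrix(stats::rnorm(n_rep * n), n_rep, n))
  ps <- vapply(seq_len(n_rep), function(i) {
    signflip_ttest(values[i, ], tail = tail, n_boot = 0)$p
  }, numeric(1))
  mean(ps <= alpha)
}
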