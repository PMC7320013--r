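# Simulation of voxel time courses with known directional tuning:
# noiseless signals are built exactly like design regressors (true basis,
# within-TR median, scaling, HRF), then white Gaussian noise is added at a
# chosen multiple of the signal standard deviation.

#' Ground-truth tuning for a simulated voxel
#'
#' Draws preferred directions on the kernel centers of the true-width basis:
#' one direction for a unimodal profile, two distinct directions for a
#' bimodal profile, and a uniformly drawn number (1..K) of distinct
#' directions with uniform (0, 1] amplitudes for a random profile. Unimodal
#' and bimodal directions get unit amplitude.
#'
#' @param profile `"unimodal"`, `"bimodal"`, or `"random"`.
#' @param true_fwhm True kernel width in degrees (a divisor of 360).
#' @param noise_multiplier Noise SD as a multiple of the signal SD (>= 0).
#' @param seed Optional integer seed.
#' @return A list of class `"ground_truth"` with `profile`, `true_fwhm`,
#'   `preferred_directions`, `direction_weights`, `noise_multiplier`, and
#'   `weights` (the full K-vector of kernel amplitudes).
#' @export
make_ground_truth <- function(profile = c("unimodal", "bimodal", "random"),
                              true_fwhm, noise_multiplier = 1, seed = NULL) {
  profile <- match.arg(profile)
  if (noise_multiplier < 0) stop("`noise_multiplier` must be >= 0")
  basis <- build_basis(true_fwhm)
  K <- length(basis$centers)
  with_seed(seed, {
    if (profile == "unimodal") {
      dirs <- sample(basis$centers, 1)
      amps <- 1
    } else if (profile == "bimodal") {
      if (K < 2) stop("bimodal profile needs at least 2 kernel centers")
      dirs <- sample(basis$centers, 2)
      amps <- c(1, 1)
    } else {
      m <- sample.int(K, 1)
      dirs <- sample(basis$centers, m)
      amps <- stats::runif(m)
    }
    w <- numeric(K)
    w[match(dirs, basis$centers)] <- amps
    out <- list(profile = profile, true_fwhm = true_fwhm,
                preferred_directions = dirs, direction_weights = amps,
                noise_multiplier = noise_multiplier, weights = w)
    class(out) <- "ground_truth"
    out
  })
}

#' Simulate tuned voxel time courses
#'
#' The noiseless signal of a voxel is the convolved design matrix of its
#' true basis (built from `log` exactly as in [build_design()]) multiplied
#' by the ground-truth kernel amplitudes. Independent Gaussian noise with
#' standard deviation `noise_multiplier * sd(signal)` is then added per
#' voxel.
#'
#' @param log A [simulate_session()] behavior log spanning all runs.
#' @param truth A single [make_ground_truth()] object (shared by all
#'   voxels) or a list of `n_voxels` of them (one per voxel, all with the
#'   same `true_fwhm`).
#' @param n_voxels Number of voxels.
#' @param seed Optional integer seed for the noise (and, when `truth` is a
#'   profile name, the per-voxel truths).
#' @param design Optional precomputed [build_design()] for the true basis;
#'   built from `log` when `NULL`.
#' @return An object of class `"voxel_dataset"`: list with `Y`
#'   (TR x voxel matrix across all runs), `run_ids`, `tr`, `truth`
#'   (per-voxel list), and `true_fwhm`.
#' @export
simulate_voxels <- function(log, truth, n_voxels, seed = NULL, design = NULL) {
  if (inherits(truth, "ground_truth")) {
    truths <- rep(list(truth), n_voxels)
  } else if (is.list(truth) && all(vapply(truth, inherits, logical(1), "ground_truth"))) {
    if (length(truth) != n_voxels) stop("need one ground truth per voxel")
    truths <- truth
  } else {
    stop("`truth` must be a ground_truth or a list of them")
  }
  fwhm <- truths[[1]]$true_fwhm
  if (!all(vapply(truths, function(t) t$true_fwhm, numeric(1)) == fwhm)) {
    stop("all per-voxel truths must share the same `true_fwhm`")
  }
  if (is.null(design)) design <- build_design(log, fwhm)
  W <- vapply(truths, function(t) t$weights, numeric(ncol(design$X)))
  signal <- design$X %*% W          # TR x voxel
  sds <- apply(signal, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate ground truth: zero-variance signal")
  noise_sd <- sds * vapply(truths, function(t) t$noise_multiplier, numeric(1))
  Y <- with_seed(seed, {
    signal + matrix(stats::rnorm(length(signal)), nrow(signal)) *
      rep(noise_sd, each = nrow(signal))
  })
  out <- list(Y = Y, run_ids = design$run_ids, tr = log$tr,
              truth = truths, true_fwhm = fwhm, signal_sd = sds)
  class(out) <- "voxel_dataset"
  out
}

#' Simulate pure-noise voxels (no directional tuning)
#'
#' @param n_trs,n_runs Scanner grid.
#' @param n_voxels Number of voxels.
#' @param tr Repetition time in s.
#' @param seed Optional integer seed.
#' @return A `"voxel_dataset"` with `truth = NULL`.
#' @export
simulate_null_voxels <- function(n_trs, n_runs, n_voxels, tr = 2.756,
                                 seed = NULL) {
  total <- n_trs * n_runs
  Y <- with_seed(seed, matrix(stats::rnorm(total * n_voxels), total, n_voxels))
  out <- list(Y = Y, run_ids = rep(seq_len(n_runs), each = n_trs), tr = tr,
              truth = NULL, true_fwhm = NA_real_)
  class(out) <- "voxel_dataset"
  out
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf("Voxel dataset: %d TRs (%d runs) x %d voxels",
              nrow(x$Y), length(unique(x$run_ids)), ncol(x$Y)))
  if (!is.na(x$true_fwhm)) cat(sprintf(", true FWHM %g deg", x$true_fwhm))
  cat("\n")
  invisible(x)
}
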