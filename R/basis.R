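# Von Mises directional basis sets and design-matrix construction:
# kernel activities from the vHD trace, within-TR median aggregation,
# per-run 0-1 scaling, and causal convolution with a double-gamma HRF.

#' The standard set of kernel widths
#'
#' Full-widths-at-half-maximum (degrees) of the iterated basis sets. All are
#' divisors of 360, so that kernel spacing can equal kernel width and every
#' basis covers the circle evenly.
#'
#' @return Numeric vector of FWHMs in degrees.
#' @export
standard_fwhms <- function() c(10, 15, 20, 24, 30, 36, 45, 60)

#' Von Mises concentration for a given kernel width
#'
#' For the peak-normalized von Mises kernel
#' \eqn{f(\Delta) = \exp(\kappa(\cos\Delta - 1))}, returns the concentration
#' \eqn{\kappa} at which the kernel value at \eqn{\Delta = \mathrm{fwhm}/2}
#' equals exactly one half:
#' \eqn{\kappa = \ln 2 / (1 - \cos(\mathrm{fwhm}/2))}.
#'
#' @param fwhm Full width at half maximum in degrees, in (0, 360).
#' @return Concentration parameter (dimensionless).
#' @export
fwhm_to_kappa <- function(fwhm) {
  if (any(!is.finite(fwhm)) || any(fwhm <= 0) || any(fwhm >= 360)) {
    stop("`fwhm` must lie strictly between 0 and 360 degrees")
  }
  log(2) / (1 - cospi(fwhm / 360))
}

#' Build a directional basis set
#'
#' Constructs `360 / fwhm` peak-normalized von Mises kernels centered at
#' `0, fwhm, 2 fwhm, ...` degrees, i.e. with spacing matched to the kernel
#' width, evaluated on a 1-degree angular grid.
#'
#' @param fwhm Kernel full width at half maximum in degrees; must divide 360.
#' @return An object of class `"kernel_basis"`: a list with `fwhm`, `kappa`,
#'   `centers` (degrees), `angular_grid` (0:359), and `kernels`
#'   (360 x K matrix of kernel values on the grid).
#' @export
build_basis <- function(fwhm) {
  if (length(fwhm) != 1 || !is.finite(fwhm) || fwhm <= 0 || 360 %% fwhm != 0) {
    stop("`fwhm` must be a positive divisor of 360 (got ", fwhm, ")")
  }
  kappa <- fwhm_to_kappa(fwhm)
  centers <- seq(0, 360 - fwhm, by = fwhm)
  grid <- 0:359
  kernels <- exp(kappa * (cospi(outer(grid, centers, "-") / 180) - 1))
  basis <- list(fwhm = fwhm, kappa = kappa, centers = centers,
                angular_grid = grid, kernels = kernels)
  class(basis) <- "kernel_basis"
  basis
}

#' @export
print.kernel_basis <- function(x, ...) {
  cat(sprintf("von Mises basis: %d kernels, FWHM %g deg (kappa %.4g)\n",
              length(x$centers), x$fwhm, x$kappa))
  invisible(x)
}

#' Kernel activities for a head-direction trace
#'
#' Evaluates every kernel of a basis at each vHD sample using circular
#' distance: the activity of the kernel centered at \eqn{\mu} for direction
#' \eqn{\theta} is \eqn{\exp(\kappa(\cos(\theta - \mu) - 1))}, so it is 1 at
#' the center and 0.5 at half a FWHM away.
#'
#' @param basis A [build_basis()] object.
#' @param vhd Numeric vector of directions in degrees.
#' @return A `length(vhd)` x K activity matrix.
#' @export
kernel_activity <- function(basis, vhd) {
  exp(basis$kappa * (cospi(outer(as.numeric(vhd), basis$centers, "-") / 180) - 1))
}

#' Canonical double-gamma HRF specification
#'
#' The default parameters are the canonical ones: response peak at 6 s,
#' undershoot peak at 16 s, peak-to-undershoot ratio 6, kernel length 32 s,
#' unit dispersions.
#'
#' @param time_to_peak,undershoot_peak,ratio,length_s HRF shape parameters
#'   in seconds (and the dimensionless peak/undershoot amplitude ratio).
#' @return A list of class `"hrf_spec"`.
#' @export
hrf_spec <- function(time_to_peak = 6, undershoot_peak = 16, ratio = 6,
                     length_s = 32) {
  out <- list(time_to_peak = time_to_peak, undershoot_peak = undershoot_peak,
              ratio = ratio, length_s = length_s)
  class(out) <- "hrf_spec"
  out
}

#' Sample the HRF on the TR grid
#'
#' Gamma-density difference with unit scale; the mode of a gamma density
#' with shape a and unit scale is a - 1, so shapes are `time_to_peak + 1`
#' and `undershoot_peak + 1`.
#'
#' @param tr Repetition time in s.
#' @param spec An [hrf_spec()].
#' @return Numeric vector of HRF values at `0, tr, 2 tr, ...` up to the
#'   kernel length.
#' @export
hrf_kernel <- function(tr, spec = hrf_spec()) {
  t <- seq(0, spec$length_s, by = tr)
  stats::dgamma(t, shape = spec$time_to_peak + 1) -
    stats::dgamma(t, shape = spec$undershoot_peak + 1) / spec$ratio
}

#' Aggregate sample-rate activities to the TR grid
#'
#' For each TR (half-open window `[k tr, (k+1) tr)`) and each kernel, takes
#' the median activity over all samples falling in the window. When a state
#' restriction is given, only samples in that state enter the median; TRs
#' with no qualifying samples get a row of zeros.
#'
#' @param activities Sample x kernel activity matrix (or a one-column matrix
#'   for a single regressor).
#' @param sample_times Sample times in s (sorted, aligned to run start at 0).
#' @param n_trs Total number of TRs in the grid.
#' @param tr Repetition time in s.
#' @param state_labels Optional per-sample labels from [label_states()].
#' @param state One of `"none"`, `"locomotion"`, `"stationary"`.
#' @param fun Aggregation function over in-window samples (default median).
#' @return An `n_trs` x K matrix.
#' @export
aggregate_to_tr <- function(activities, sample_times, n_trs, tr,
                            state_labels = NULL,
                            state = c("none", "locomotion", "stationary"),
                            fun = stats::median) {
  state <- match.arg(state)
  activities <- as.matrix(activities)
  if (is.unsorted(sample_times)) stop("`sample_times` must be sorted")
  keep <- sample_times >= 0 & sample_times < n_trs * tr
  if (!is.null(state_labels) && state != "none") {
    keep <- keep & (state_labels == state)
  }
  if (!any(sample_times >= 0 & sample_times < n_trs * tr)) {
    stop("sample span does not overlap the TR grid")
  }
  idx <- which(keep)
  tr_of <- floor(sample_times[idx] / tr) + 1
  out <- matrix(0, n_trs, ncol(activities))
  groups <- split(idx, tr_of)
  for (g in names(groups)) {
    rows <- groups[[g]]
    out[as.integer(g), ] <- apply(activities[rows, , drop = FALSE], 2, fun)
  }
  out
}

#' Scale regressors and convolve with the HRF
#'
#' Each column is min-max scaled to `[0, 1]` within each run (constant
#' columns are left as zeros), then causally convolved with the double-gamma
#' HRF sampled on the TR grid; the convolution is truncated to the run
#' length so nothing bleeds across runs.
#'
#' @param tr_matrix TR x kernel matrix from [aggregate_to_tr()].
#' @param run_ids Per-row run label.
#' @param tr Repetition time in s.
#' @param hrf An [hrf_spec()].
#' @return Matrix of the same shape.
#' @export
scale_and_convolve <- function(tr_matrix, run_ids, tr, hrf = hrf_spec()) {
  tr_matrix <- as.matrix(tr_matrix)
  if (any(!is.finite(tr_matrix))) stop("`tr_matrix` must be finite")
  h <- hrf_kernel(tr, hrf)
  out <- matrix(0, nrow(tr_matrix), ncol(tr_matrix))
  for (run in unique(run_ids)) {
    rows <- which(run_ids == run)
    block <- tr_matrix[rows, , drop = FALSE]
    rng_lo <- apply(block, 2, min)
    rng_hi <- apply(block, 2, max)
    span <- rng_hi - rng_lo
    scaled <- sweep(block, 2, rng_lo)
    nz <- span > 0
    scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, span[nz], "/")
    scaled[, !nz] <- 0
    n <- length(rows)
    conv <- apply(scaled, 2, function(col) {
      full <- stats::convolve(col, rev(h), type = "open")
      full[seq_len(n)]
    })
    out[rows, ] <- conv
  }
  out
}

#' Build a design matrix from a behavior log
#'
#' Full design pipeline for one basis set: kernel activities at the
#' behavioral sampling rate, within-TR median aggregation (optionally
#' restricted to a locomotion or stationary state), per-run 0-1 scaling,
#' HRF convolution, plus a movement covariate (the within-TR fraction of
#' translating samples, scaled and convolved the same way). The movement
#' covariate is always computed from all samples so that state-restricted
#' designs stay on an identical TR grid.
#'
#' @param log A [simulate_session()] behavior log.
#' @param fwhm Kernel width in degrees (a divisor of 360).
#' @param state `"none"` (default), `"locomotion"`, or `"stationary"`;
#'   restricts the within-TR median to in-state samples.
#' @param state_labels Optional precomputed [label_states()] labels.
#' @param hrf An [hrf_spec()].
#' @return An object of class `"design_matrix"`: list with `X`
#'   (TR x kernel convolved regressors), `movement` (TR vector), `run_ids`,
#'   `fwhm`, `state`, `tr`, and `basis`.
#' @export
build_design <- function(log, fwhm, state = c("none", "locomotion", "stationary"),
                         state_labels = NULL, hrf = hrf_spec()) {
  state <- match.arg(state)
  if (state != "none" && is.null(state_labels)) {
    state_labels <- label_states(log)
  }
  basis <- build_basis(fwhm)
  n_trs <- log$n_runs * log$trs_per_run
  run_ids <- rep(seq_len(log$n_runs), each = log$trs_per_run)
  act <- kernel_activity(basis, log$samples$vhd)
  agg <- aggregate_to_tr(act, log$samples$t, n_trs, log$tr,
                         state_labels = state_labels, state = state)
  X <- scale_and_convolve(agg, run_ids, log$tr, hrf)
  colnames(X) <- paste0("k", basis$centers)
  mov_agg <- aggregate_to_tr(matrix(as.numeric(log$samples$translating)),
                             log$samples$t, n_trs, log$tr, fun = mean)
  movement <- drop(scale_and_convolve(mov_agg, run_ids, log$tr, hrf))
  design <- list(X = X, movement = movement, run_ids = run_ids,
                 fwhm = fwhm, state = state, tr = log$tr, basis = basis)
  class(design) <- "design_matrix"
  design
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d TRs x %d kernels (FWHM %g deg), state %s\n",
              nrow(x$X), ncol(x$X), x$fwhm, x$state))
  invisible(x)
}

#' Subset a design matrix by run
#'
#' @param design A [build_design()] object.
#' @param runs Run labels to keep.
#' @return A `"design_matrix"` restricted to those rows.
#' @export
subset_design <- function(design, runs) {
  rows <- design$run_ids %in% runs
  out <- design
  out$X <- design$X[rows, , drop = FALSE]
  out$movement <- design$movement[rows]
  out$run_ids <- design$run_ids[rows]
  out
}
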