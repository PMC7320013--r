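# Inverted encoding model: reconstruct kernel activities from multivoxel
# patterns via the Moore-Penrose pseudoinverse of the trained weights, and
# score the reconstruction against the test design by 2-D correlation with
# a weight-shuffle null.

#' Reconstruct kernel activities from voxel patterns
#'
#' Multiplies the Moore-Penrose pseudoinverse of the voxel x kernel weight
#' matrix with the multivoxel pattern at each acquisition, yielding the
#' estimated kernel activities at every TR.
#'
#' @param weights Voxel x kernel weight matrix (m x K).
#' @param patterns TR x voxel matrix of observed patterns.
#' @return K x TR matrix of reconstructed kernel activities.
#' @export
invert_and_reconstruct <- function(weights, patterns) {
  weights <- as.matrix(weights)
  patterns <- as.matrix(patterns)
  if (ncol(patterns) != nrow(weights)) {
    stop("patterns have ", ncol(patterns), " voxels but weights have ",
         nrow(weights))
  }
  if (all(weights == 0)) stop("all-zero weight matrix cannot be inverted")
  pracma::pinv(weights) %*% t(patterns)
}

#' Score a reconstruction against the test design
#'
#' The score is the Pearson correlation between the flattened K x TR
#' reconstruction and the equally flattened test design (2-D correlation).
#' The null is built by permuting the kernel labels of the weight matrix
#' (`k` unique non-identity permutations) and redoing the full
#' reconstruction each time; since a permutation matrix is orthogonal,
#' `pinv(W P) = t(P) pinv(W)`, so each shuffled reconstruction is the
#' row-permuted original -- the identity is exact, not an approximation.
#'
#' @param recon K x TR reconstruction from [invert_and_reconstruct()].
#' @param target K x TR reference (the standardized, HRF-convolved test
#'   design, transposed to kernel x TR).
#' @param k Number of unique shuffles.
#' @param seed Optional integer seed.
#' @return A list with `score_r`, `score_z`, `null_mean`, `null_sd`.
#' @export
reconstruction_score <- function(recon, target, k = 500, seed = NULL) {
  recon <- as.matrix(recon); target <- as.matrix(target)
  if (!all(dim(recon) == dim(target))) stop("shape mismatch")
  if (stats::sd(recon) == 0 || stats::sd(target) == 0) {
    stop("zero-variance input: 2-D correlation undefined")
  }
  score_r <- stats::cor(as.vector(recon), as.vector(target))
  perms <- unique_permutations(nrow(recon), k, seed)
  null_r <- apply(perms, 2, function(p) {
    stats::cor(as.vector(recon[p, , drop = FALSE]), as.vector(target))
  })
  null_mean <- mean(null_r); null_sd <- stats::sd(null_r)
  score_z <- if (null_sd > 0) (score_r - null_mean) / null_sd else 0
  list(score_r = score_r, score_z = score_z, null_mean = null_mean,
       null_sd = null_sd)
}

#' Inverted-encoding-model analysis of the test run
#'
#' Reconstructs kernel activities from the test-run patterns of the
#' top-training voxels (the same selection as the forward ROI analysis) and
#' scores them against the standardized test design.
#'
#' @param wm A [train_model()] weight map.
#' @param design Full-session design matrix for the same basis.
#' @param dataset The `"voxel_dataset"`.
#' @param k Number of shuffles.
#' @param seed Optional integer seed.
#' @param top_frac Voxel-selection fraction.
#' @return An object of class `"reconstruction"`: list with `recon`
#'   (K x TR), `score_r`, `score_z`, `voxels` (indices used).
#' @export
iem_analysis <- function(wm, design, dataset, k = 500, seed = NULL,
                         top_frac = 0.25) {
  sel <- roi_select(wm$training_score, top_frac)
  dtest <- subset_design(design, wm$test_run)
  rows <- design$run_ids %in% wm$test_run
  n_k <- ncol(wm$weights)
  Xs <- standardize_cols(dtest$X, wm$center[seq_len(n_k)],
                         wm$scale[seq_len(n_k)])$X
  patterns <- sweep(dataset$Y[rows, sel, drop = FALSE], 2, wm$intercept[sel])
  recon <- invert_and_reconstruct(wm$weights[sel, , drop = FALSE], patterns)
  sc <- reconstruction_score(recon, t(Xs), k = k, seed = seed)
  out <- list(recon = recon, score_r = sc$score_r, score_z = sc$score_z,
              voxels = sel, fwhm = wm$fwhm)
  class(out) <- "reconstruction"
  out
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("IEM reconstruction (FWHM %g deg, %d voxels): r %.3f, z %.2f\n",
              x$fwhm, length(x$voxels), x$score_r, x$score_z))
  invisible(x)
}
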