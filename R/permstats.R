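# Group-level permutation inference (sign-flip, two-sample, rank
# correlation), effect sizes with bootstrap intervals, FDR control, and the
# directional-sampling summaries of the behavior.

perm_tail_p <- function(null_stats, observed, tail) {
  eps <- 1e-12
  if (tail == "one") mean(null_stats >= observed - eps)
  else mean(abs(null_stats) >= abs(observed) - eps)
}

# t statistics for every row of a sign matrix S (rows = sign assignments)
# applied to values v. The sum of squares is sign-invariant, so only the
# mean varies across assignments.
signflip_t <- function(S, v) {
  n <- length(v)
  m <- as.vector(S %*% v) / n
  s2 <- (sum(v^2) - n * m^2) / (n - 1)
  t <- m / sqrt(s2 / n)
  t[s2 <= 0] <- sign(m[s2 <= 0]) * Inf
  t
}

#' One-sample sign-flip permutation t test
#'
#' Tests group-level scores against zero. With `2^n <= k` all sign
#' assignments are enumerated (the identity included, which puts the
#' smallest attainable one-sided p at `1 / 2^n`; for n = 10 that is
#' 1/1024 = 0.000977); otherwise `k` random assignments including the
#' identity are drawn.
#'
#' @param values Per-participant scores.
#' @param tail `"one"` (greater than zero) or `"two"`.
#' @param k Maximum number of permutations.
#' @param n_boot Bootstrap resamples for the Cohen's d interval
#'   (0 skips the interval).
#' @param seed Optional integer seed (used only when sampling).
#' @return A list of class `"perm_test"` with `statistic` (the observed t),
#'   `p`, `n_perms`, `exhaustive`, `tail`, `effect_d`, `d_ci`.
#' @export
signflip_ttest <- function(values, tail = c("one", "two"), k = 10000,
                           n_boot = 2000, seed = NULL) {
  tail <- match.arg(tail)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (all(values == 0)) stop("degenerate input: all values are zero")
  exhaustive <- 2^n <= k
  S <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    with_seed(seed, {
      M <- matrix(sample(c(1, -1), (k - 1) * n, replace = TRUE), k - 1, n)
      rbind(rep(1, n), M)
    })
  }
  t_null <- signflip_t(S, values)
  t_obs <- signflip_t(matrix(1, 1, n), values)
  p <- perm_tail_p(t_null, t_obs, tail)
  # constant non-zero scores have an infinite standardized effect
  d <- tryCatch(cohens_d_ci(values, n_boot = n_boot, seed = seed),
                error = function(e) list(d = sign(mean(values)) * Inf,
                                         ci = c(NA_real_, NA_real_)))
  out <- list(statistic = t_obs, p = p, n_perms = nrow(S),
              exhaustive = exhaustive, tail = tail,
              effect_d = d$d, d_ci = d$ci)
  class(out) <- "perm_test"
  out
}

#' Two-sample permutation t test
#'
#' Unpaired: the pooled-variance t statistic under `k` random group-label
#' permutations (the observed labeling included). Paired: sign flips of the
#' within-pair differences, delegated to [signflip_ttest()].
#'
#' @param a,b Group scores (equal length when `paired`).
#' @param paired Within-pair swaps instead of label permutations.
#' @param tail `"one"` (a greater) or `"two"`.
#' @param k Number of permutations.
#' @param n_boot,seed As in [signflip_ttest()].
#' @return A `"perm_test"` list.
#' @export
perm_ttest2 <- function(a, b, paired = FALSE, tail = c("two", "one"),
                        k = 10000, n_boot = 2000, seed = NULL) {
  tail <- match.arg(tail)
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  if (paired) {
    if (length(a) != length(b)) stop("paired test needs equal lengths")
    d <- a - b
    if (all(d == 0)) {
      dd <- cohens_d_ci(a, b, n_boot = 0)
      out <- list(statistic = 0, p = 1, n_perms = 2^length(d),
                  exhaustive = TRUE, tail = tail, effect_d = dd$d,
                  d_ci = c(NA_real_, NA_real_))
      class(out) <- "perm_test"
      return(out)
    }
    res <- signflip_ttest(d, tail = if (tail == "one") "one" else "two",
                          k = k, n_boot = n_boot, seed = seed)
    eff <- cohens_d_ci(a, b, n_boot = n_boot, seed = seed)
    res$effect_d <- eff$d; res$d_ci <- eff$ci
    return(res)
  }
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  all_v <- c(a, b)
  na <- length(a)
  t_obs <- pooled_t(a, b)
  t_null <- with_seed(seed, {
    c(t_obs, replicate(k - 1, {
      idx <- sample.int(length(all_v), na)
      pooled_t(all_v[idx], all_v[-idx])
    }))
  })
  p <- perm_tail_p(t_null, t_obs, tail)
  eff <- cohens_d_ci(a, b, n_boot = n_boot, seed = seed)
  out <- list(statistic = t_obs, p = p, n_perms = k, exhaustive = FALSE,
              tail = tail, effect_d = eff$d, d_ci = eff$ci)
  class(out) <- "perm_test"
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation t test (%s-tailed): t = %.3f, p = %.4g (%s%d perms), d = %.2f\n",
              x$tail, x$statistic, x$p,
              if (x$exhaustive) "exhaustive " else "", x$n_perms, x$effect_d))
  invisible(x)
}

#' Permutation-based rank correlation
#'
#' Spearman's rho with a null built by permuting `y`; all `n!` permutations
#' are enumerated when feasible within `k`, otherwise `k` random
#' permutations including the identity are used. Two-tailed p.
#'
#' @param x,y Equal-length vectors (n >= 3).
#' @param k Maximum number of permutations.
#' @param seed Optional integer seed.
#' @return A list with `rho`, `p`, `n_perms`, `exhaustive`.
#' @export
perm_rankcorr <- function(x, y, k = 10000, seed = NULL) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("`x` and `y` must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  rho_obs <- stats::cor(x, y, method = "spearman")
  exhaustive <- factorial(n) <= k
  rho_null <- if (exhaustive) {
    P <- pracma::perms(seq_len(n))
    apply(P, 1, function(p) stats::cor(x, y[p], method = "spearman"))
  } else {
    with_seed(seed, {
      c(rho_obs, replicate(k - 1, {
        stats::cor(x, sample(y), method = "spearman")
      }))
    })
  }
  p <- perm_tail_p(rho_null, rho_obs, "two")
  list(rho = rho_obs, p = p, n_perms = length(rho_null),
       exhaustive = exhaustive)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure over a family of p-values.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param q FDR level.
#' @return A list with `significant` (logical mask, in input order) and
#'   `adjusted` (BH-adjusted p-values).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(significant = adjusted <= q, adjusted = adjusted)
}

#' Cohen's d with a percentile-bootstrap confidence interval
#'
#' One-sample (`mean / sd`, against zero) when `b` is `NULL`; two-sample
#' with the pooled standard deviation otherwise.
#'
#' @param a,b Samples.
#' @param n_boot Bootstrap resamples (0 skips the interval).
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @return A list with `d` and `ci` (length 2; `NA` when `n_boot = 0`).
#' @export
cohens_d_ci <- function(a, b = NULL, n_boot = 2000, conf = 0.95, seed = NULL) {
  d_of <- function(x, y) {
    if (is.null(y)) {
      s <- stats::sd(x)
      if (s == 0) stop("zero standard deviation: d undefined")
      mean(x) / s
    } else {
      nx <- length(x); ny <- length(y)
      sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
                   (nx + ny - 2))
      if (sp == 0) stop("zero pooled standard deviation: d undefined")
      (mean(x) - mean(y)) / sp
    }
  }
  d <- d_of(a, b)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        xa <- sample(a, replace = TRUE)
        xb <- if (is.null(b)) NULL else sample(b, replace = TRUE)
        tryCatch(d_of(xa, xb), error = function(e) NA_real_)
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(d = d, ci = ci)
}

#' Directional sampling histogram
#'
#' Time spent facing each direction, in percent of the logged duration,
#' binned at `bin_width` degrees (36 bins by default). Optionally restricted
#' to locomotion or stationary samples.
#'
#' @param log A behavior log.
#' @param bin_width Bin width in degrees (must divide 360).
#' @param state_labels Optional [label_states()] labels.
#' @param state `"none"`, `"locomotion"`, or `"stationary"`.
#' @return Named numeric vector of per-bin percentages (names are bin lower
#'   edges in degrees); sums to 100.
#' @export
directional_sampling <- function(log, bin_width = 10, state_labels = NULL,
                                 state = c("none", "locomotion", "stationary")) {
  state <- match.arg(state)
  if (360 %% bin_width != 0) stop("`bin_width` must divide 360")
  vhd <- log$samples$vhd
  if (state != "none") {
    if (is.null(state_labels)) state_labels <- label_states(log)
    vhd <- vhd[state_labels == state]
  }
  n_bins <- 360 / bin_width
  bins <- factor(floor(wrap_deg(vhd) / bin_width),
                 levels = 0:(n_bins - 1))
  counts <- table(bins)
  pct <- 100 * as.numeric(counts) / length(vhd)
  stats::setNames(pct, (0:(n_bins - 1)) * bin_width)
}

#' Within-TR direction histograms, aligned on the modal direction
#'
#' Bins the vHD within every TR (percent of within-TR time), circularly
#' shifts each histogram so the most-sampled bin lines up at the first
#' position (ties towards the lowest bin index), and averages across TRs.
#' The first entry of the average -- the predominant fraction -- is the mean
#' percentage of within-TR time spent facing the single predominant
#' direction. TRs without samples are skipped with a warning.
#'
#' @param log A behavior log.
#' @param bin_width Bin width in degrees.
#' @return A list of class `"aligned_histogram"` with `bins` (average
#'   aligned percentages, summing to 100), `predominant_fraction`,
#'   `modal_direction` (per-TR modal bin lower edge in degrees), and
#'   `n_skipped`.
#' @export
within_tr_alignment <- function(log, bin_width = 10) {
  if (360 %% bin_width != 0) stop("`bin_width` must divide 360")
  n_bins <- 360 / bin_width
  n_trs <- log$n_runs * log$trs_per_run
  s <- log$samples
  tr_idx <- floor(s$t / log$tr) + 1
  keep <- tr_idx >= 1 & tr_idx <= n_trs
  tab <- table(factor(tr_idx[keep], levels = seq_len(n_trs)),
               factor(floor(wrap_deg(s$vhd[keep]) / bin_width),
                      levels = 0:(n_bins - 1)))
  counts <- matrix(as.numeric(tab), n_trs, n_bins)
  totals <- rowSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warning(sum(empty), " TR(s) without samples were skipped")
    counts <- counts[!empty, , drop = FALSE]
    totals <- totals[!empty]
  }
  pct <- counts / totals * 100
  modal <- max.col(pct, ties.method = "first")
  aligned <- t(vapply(seq_len(nrow(pct)), function(i) {
    pct[i, ((seq_len(n_bins) - 1 + modal[i] - 1) %% n_bins) + 1]
  }, numeric(n_bins)))
  avg <- colMeans(aligned)
  out <- list(bins = stats::setNames(avg, (0:(n_bins - 1)) * bin_width),
              predominant_fraction = avg[1],
              modal_direction = (modal - 1) * bin_width,
              n_skipped = sum(empty))
  class(out) <- "aligned_histogram"
  out
}
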