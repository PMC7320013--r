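# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Signed circular difference a - b mapped into (-180, 180].
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Wrap angles into [0, 360).
wrap_deg <- function(a) a %% 360

# Column-wise Pearson correlation between a vector y and each column of A.
# Columns with zero variance yield NA.
col_cor <- function(A, y) {
  A <- as.matrix(A)
  yc <- y - mean(y)
  Ac <- sweep(A, 2, colMeans(A))
  num <- as.vector(crossprod(Ac, yc))
  den <- sqrt(colSums(Ac^2) * sum(yc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Pairwise column correlation between matched columns of A and B.
paired_col_cor <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  num <- colSums(Ac * Bc)
  den <- sqrt(colSums(Ac^2) * colSums(Bc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
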