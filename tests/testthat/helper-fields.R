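# Small in-code fixtures shared across tests.

rmse <- function(x, y) sqrt(mean((x - y)^2))

# Deterministic exact rank-r field on an nr x nc grid: sum of r separable
# outer products with orthogonal-ish factors, shifted non-negative.
make_lowrank_field <- function(nr = 5, nc = 4, n_times = 30, r = 1,
                               amplitudes = 10 * seq(r, 1), shift = 50) {
  P <- nr * nc
  tt <- seq_len(n_times) / n_times
  vals <- matrix(0, P, n_times)
  for (k in seq_len(r)) {
    u <- cos(2 * pi * k * seq_len(P) / P) + (k == 1) * 0.5
    v <- sin(2 * pi * k * tt)
    vals <- vals + amplitudes[k] * outer(u, v)
  }
  space_time_field(vals + shift, grid_shape = c(nr, nc))
}

# Mask a given fraction of cells at random, never emptying a row/column.
mask_random <- function(field, fraction, seed) {
  set.seed(seed)
  m <- matrix(runif(length(field$values)) < fraction, nrow(field$values))
  for (i in which(rowSums(!m) == 0)) m[i, sample(ncol(m), 1)] <- FALSE
  for (j in which(colSums(!m) == 0)) m[sample(nrow(m), 1), j] <- FALSE
  vals <- field$values
  space_time_field(vals, grid_shape = field$grid_shape, mask = m,
                   times = field$times, pixel_size = field$pixel_size)
}

# Matrix-row indices of a grid-row/grid-column block (row-major unravel),
# recomputed independently of the package's internals.
pixel_rows_for_test <- function(grid_shape, rows, cols) {
  sort(as.vector(outer((rows - 1) * grid_shape[2], cols, `+`)))
}

# Brute-force truncated reconstruction via an independent eigendecomposition
# of the Gram matrix t(Ac) %*% Ac (never touches svd()).
eigen_reconstruct <- function(A, k) {
  m <- rowMeans(A)
  Ac <- A - m
  eg <- eigen(crossprod(Ac), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  keep <- which(lam > 1e-12 * max(lam, 1e-300))[seq_len(min(k, sum(lam > 1e-12 * max(lam, 1e-300))))]
  R <- matrix(m, nrow(A), ncol(A))
  for (j in keep) {
    v <- eg$vectors[, j]
    u <- Ac %*% v / sqrt(lam[j])
    R <- R + sqrt(lam[j]) * u %*% t(v)
  }
  R
}
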