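test_that("delay embedding builds per-pixel Hankel blocks", {
  # single pixel series 1..4, W = 2 -> the hand-built Hankel block
  dm <- delay_embed(matrix(1:4, 1), W = 2)
  expect_equal(unclass(dm)[, ], matrix(c(1, 2, 2, 3, 3, 4), 2, 3),
               ignore_attr = TRUE)

  # Hankel constraint on a two-pixel field: entry (lag i, col j) = a[j+i-1]
  A <- rbind(sin(1:9), cos(1:9))
  dm <- delay_embed(A, W = 3)
  for (p in 1:2) for (i in 1:3) for (j in 1:7)
    expect_identical(dm[(p - 1) * 3 + i, j], A[p, j + i - 1])

  # shape formula (P*W) x (N-W+1) at the reference configuration
  f <- make_lowrank_field(10, 10, 46, r = 2)
  expect_identical(dim(delay_embed(f, W = 4)), c(400L, 43L))

  # W = 1 returns the source matrix unchanged
  expect_equal(unclass(delay_embed(f, W = 1))[, ], f$values,
               ignore_attr = TRUE)

  expect_error(delay_embed(matrix(1:4, 1), W = 5), "window")
  gappy <- mask_random(f, 0.1, seed = 1)
  expect_error(delay_embed(gappy, W = 4), "gap-fill")
  expect_silent(delay_embed(gappy, W = 1))
})

test_that("de-embedding inverts the embedding and averages anti-diagonals", {
  # hand-checked anti-diagonal averaging
  blk <- structure(matrix(c(1, 2, 2, 3, 3, 4), 2, 3), W = 2L, P = 1L, N = 4L)
  expect_equal(de_embed(blk), matrix(c(1, 2, 3, 4), 1))

  f <- make_lowrank_field(4, 5, 20, r = 3)
  for (W in c(1, 2, 4))
    expect_equal(de_embed(delay_embed(f, W)), f$values)

  expect_error(de_embed(matrix(1, 2, 2)), "metadata")
  expect_error(de_embed(matrix(1, 3, 3), W = 2, P = 2, N = 4), "validation")
})

test_that("EOF decomposition satisfies the SVD identities", {
  set.seed(42)
  A <- matrix(rnorm(35), 5, 7)
  dec <- eof_decompose(A)
  # descending non-negative spectrum, orthonormal factors
  expect_true(all(diff(dec$S) <= 1e-12) && all(dec$S >= 0))
  expect_equal(crossprod(dec$Z), diag(ncol(dec$Z)), tolerance = 1e-8)
  expect_equal(crossprod(dec$H), diag(ncol(dec$H)), tolerance = 1e-8)
  expect_equal(sum(dec$variance_fraction), 1, tolerance = 1e-10)
  # full reconstruction recovers the input
  R <- eof_reconstruct(dec, seq_along(dec$S))
  expect_equal(R, A, tolerance = 1e-8)
  # energy conservation and the column-count variance normalisation
  Ac <- A - rowMeans(A)
  expect_equal(sum(dec$S^2), sum(Ac^2), tolerance = 1e-8)
  expect_equal(dec$total_variance, sum(Ac^2) / ncol(A), tolerance = 1e-10)
  # squared singular values match an independent eigensolver on t(Ac) Ac
  lam <- sort(pmax(eigen(crossprod(Ac), symmetric = TRUE)$values, 0),
              decreasing = TRUE)
  expect_equal(sort(dec$S^2, decreasing = TRUE), lam[seq_along(dec$S)],
               tolerance = 1e-8)
  expect_error(eof_decompose(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("a rank-1 matrix yields a single mode carrying all variance", {
  A <- outer(1:6, c(2, -1, 3)) + 5  # rank 1 after row-mean removal
  dec <- eof_decompose(A)
  expect_gt(dec$S[1], 1e-10)
  expect_lt(dec$S[2] / dec$S[1], 1e-10)
  expect_equal(dec$variance_fraction[1], 1, tolerance = 1e-10)
})

test_that("component selection counts modes up to the cumulative threshold", {
  dec <- structure(list(variance_fraction = c(0.5, 0.3, 0.1, 0.1),
                        S = c(2, 1, 0.5, 0.5)),
                   class = "eof_decomposition")
  expect_identical(select_components(dec, 0.8), 2L)
  expect_identical(select_components(dec, 0.81), 3L)
  expect_identical(select_components(dec, 1.0), 4L)
  expect_error(select_components(dec, 0), "parameter")
  expect_error(select_components(dec, 1.2), "parameter")
})

test_that("truncated reconstruction obeys the mean/empty/rank contracts", {
  set.seed(7)
  # exact rank-2 plus mean structure is recovered by two components
  A <- outer(rnorm(6), rnorm(8)) + outer(rnorm(6), rnorm(8)) + 3
  dec <- eof_decompose(A)
  expect_equal(eof_reconstruct(dec, 1:2), A, tolerance = 1e-6)
  # empty set returns the mean field
  expect_equal(eof_reconstruct(dec, integer(0)),
               matrix(rowMeans(A), 6, 8), tolerance = 1e-12)
  expect_error(eof_reconstruct(dec, 99), "parameter")
})

test_that("truncated reconstructions match a brute-force eigendecomposition oracle", {
  set.seed(123)
  for (rep in 1:50) {
    nr <- sample(2:6, 1); nc <- sample(2:8, 1)
    A <- matrix(sample(-3:3, nr * nc, replace = TRUE), nr, nc) + 0
    dec <- eof_decompose(A)
    for (k in unique(c(1, min(nr, nc)))) {
      expect_equal(eof_reconstruct(dec, seq_len(k)), eigen_reconstruct(A, k),
                   tolerance = 1e-8)
    }
  }
})

test_that("reconstruction error is non-increasing in the number of modes", {
  set.seed(5)
  A <- matrix(rnorm(20 * 15), 20, 15)
  dec <- eof_decompose(A)
  errs <- vapply(seq_along(dec$S), function(k)
    sqrt(mean((eof_reconstruct(dec, seq_len(k)) - A)^2)), numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("W = 1 embedded pipeline equals the plain EOF pipeline", {
  f <- make_lowrank_field(5, 5, 18, r = 3)
  plain <- eof_decompose(f$values)
  emb <- eof_decompose(delay_embed(f, W = 1))
  k <- length(plain$S)
  expect_identical(de_embed(eof_reconstruct(emb, seq_len(k))),
                   eof_reconstruct(plain, seq_len(k)))
})
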