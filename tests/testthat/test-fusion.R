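test_that("fusing a field with itself reproduces it when all modes are kept", {
  # shift keeps every cell positive so no negative-replacement fires
  f <- make_lowrank_field(6, 6, 20, r = 3, amplitudes = c(30, 20, 10),
                          shift = 100)
  cfg <- fusion_config(W = 1, tau_primary = 0.999999, tau_secondary = 0,
                       tile_rows = 200, tile_cols = 200)
  fit <- eof_fuse(f, f, cfg)
  expect_lt(rmse(fitted(fit)$values, f$values) / sd(f$values), 1e-6)
  expect_false(any(fitted(fit)$mask))
})

test_that("negative cells in the primary reconstruction take the secondary's value", {
  # primary: exact rank-1 with a known negative dip; secondary: constant +12,
  # whose main pattern (its mean field) is the fallback everywhere
  u <- c(2, 1, 1.5, 1.2, 0.8, 1.1, 1.4, 0.9, 1.3)
  v <- c(5, 4, -6, 3, 6, 5, 4, 6)
  a <- space_time_field(outer(u, v), grid_shape = c(3, 3))
  b <- space_time_field(matrix(12, 9, 8), grid_shape = c(3, 3))
  fit <- eof_fuse(a, b, fusion_config(W = 1, tau_primary = 0.8,
                                      tau_secondary = 0.2))
  fused <- fitted(fit)$values
  neg <- outer(u, v) < 0
  expect_true(all(fused[neg] == 12))
  expect_true(all(abs(fused[!neg] - outer(u, v)[!neg]) < 1e-8))
  expect_equal(fit$diagnostics$n_negative_replaced, sum(neg))
})

test_that("replace_negatives obeys its three contracts", {
  ok <- matrix(c(1, 2, 3, 4), 2)
  out <- replace_negatives(ok, matrix(9, 2, 2))
  expect_equal(out, ok, ignore_attr = TRUE)
  expect_identical(attr(out, "n_replaced"), 0L)

  allneg <- replace_negatives(matrix(-5, 2, 2), matrix(3, 2, 2))
  expect_true(all(allneg == 3))
  expect_identical(attr(allneg, "n_replaced"), 4L)

  dbl <- replace_negatives(matrix(c(-5, 1, 2, 3), 2), matrix(c(-1, 1, 1, 1), 2))
  expect_identical(dbl[1, 1], 0)
  expect_identical(attr(dbl, "n_clamped"), 1L)

  expect_error(replace_negatives(matrix(1, 2, 2), matrix(1, 3, 3)),
               "validation")
})

test_that("simple average blends, borrows across gaps, and validates weight", {
  f <- make_lowrank_field(4, 4, 10, r = 1)
  expect_equal(simple_average(f, f, 0.5)$values, f$values)
  zero <- space_time_field(matrix(0, 16, 10), grid_shape = c(4, 4))
  expect_equal(simple_average(zero, f, 0.5)$values, f$values / 2)

  a <- space_time_field(matrix(10, 4, 3), grid_shape = c(2, 2))
  b <- space_time_field(matrix(20, 4, 3), grid_shape = c(2, 2))
  a$mask[1, 1] <- TRUE          # missing in a -> take b
  b$mask[2, 2] <- TRUE          # missing in b -> take a
  a$mask[3, 3] <- b$mask[3, 3] <- TRUE  # missing in both -> stays missing
  avg <- simple_average(a, b, 0.5)
  expect_equal(avg$values[1, 1], 20)
  expect_equal(avg$values[2, 2], 10)
  expect_true(avg$mask[3, 3])
  expect_equal(avg$values[4, 1], 15)
  expect_error(simple_average(a, b, 1.5), "parameter")
})

test_that("fusion is deterministic and validates co-registration", {
  cfg <- synthetic_config(grid_shape = c(12, 12), n_times = 24)
  syn <- synthetic_benchmark(cfg, seed = 5)
  fc <- fusion_config(W = 2)
  f1 <- eof_fuse(syn$product_a, syn$product_b, fc)
  f2 <- eof_fuse(syn$product_a, syn$product_b, fc)
  expect_identical(fitted(f1)$values, fitted(f2)$values)

  other <- synthetic_benchmark(synthetic_config(grid_shape = c(10, 10),
                                                n_times = 24), seed = 5)
  expect_error(eof_fuse(syn$product_a, other$product_b, fc),
               "co-registered")
})

test_that("fused output is gap-free and non-negative on the benchmark", {
  syn <- synthetic_benchmark(synthetic_config(), seed = 3)
  fit <- eof_fuse(syn$product_a, syn$product_b, fusion_config())
  fused <- fitted(fit)
  expect_false(any(fused$mask))
  expect_true(all(fused$values >= 0))
})

test_that("fusion summary and print expose the component bookkeeping", {
  syn <- synthetic_benchmark(synthetic_config(grid_shape = c(10, 10),
                                              n_times = 24), seed = 2)
  fit <- eof_fuse(syn$product_a, syn$product_b, fusion_config(W = 2))
  expect_output(print(fit), "EOF component-mixing fusion")
  s <- summary(fit)
  expect_output(print(s), "per-tile diagnostics")
  expect_true(all(c("k_primary", "k_secondary", "n_negative_replaced") %in%
                  names(fit$diagnostics)))
})
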