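test_that("closure correction matches the worked budget and its algebra", {
  # closure factor (100 - 10) / (40 + 40) = 9/8 -> 40 * 9/8 = 45
  expect_equal(closure_correct(Rn = 100, G = 10, H_ori = 40, LE_ori = 40), 45)
  # a closed budget is left unchanged
  expect_equal(closure_correct(Rn = 90, G = 10, H_ori = 40, LE_ori = 40), 40)
})

test_that("closure correction restores closure and preserves the Bowen ratio", {
  set.seed(8)
  n <- 1000
  Rn <- runif(n, 80, 200); G <- runif(n, 5, 30)
  H <- runif(n, 10, 80); LE <- runif(n, 10, 120)
  le_c <- closure_correct(Rn, G, H, LE)
  h_c <- closure_correct(Rn, G, LE, H)  # symmetric correction of H
  expect_equal(h_c + le_c, Rn - G, tolerance = 1e-12)
  expect_equal(h_c / le_c, H / LE, tolerance = 1e-12)
})

test_that("undefined closure corrections are excluded, never zeroed", {
  expect_warning(out <- closure_correct(c(100, 100), c(10, 10),
                                        c(40, 30), c(40, -30)),
                 "excluded")
  expect_equal(out[1], 45)
  expect_true(is.na(out[2]))
  expect_error(closure_correct(100, 10, 30, -30), "undefined")
  # data.frame interface augments the records
  tw <- data.frame(Rn = 100, G = 10, H_ori = 40, LE_ori = 40)
  expect_equal(closure_correct(tw)$LE_corr, 45)
})

test_that("8-day compositing averages blocks and keeps short final blocks", {
  expect_equal(unname(composite_8day(rep(50, 16))), c(50, 50))
  expect_equal(unname(composite_8day(c(rep(10, 8), rep(30, 8)))), c(10, 30))
  # 12-day series: blocks over days 1-8 and 9-12
  x <- c(rep(2, 8), rep(6, 4))
  expect_equal(unname(composite_8day(x)), c(2, 6))
  # missing days are skipped; a fully missing block is NA
  y <- c(rep(NA, 8), 1:8)
  expect_equal(unname(composite_8day(y)), c(NA, 4.5))
  expect_error(composite_8day(numeric(0)), "empty")
  # compositing an already-composite-resolution constant series: identity
  expect_equal(unname(composite_8day(c(7, 7, 7), block = 1)), c(7, 7, 7))
})

test_that("MODIS-calendar anchoring follows day-of-year 1, 9, 17, ...", {
  dates <- seq(as.Date("2005-01-05"), by = "day", length.out = 10)
  out <- composite_8day(seq_len(10), dates = dates, modis_calendar = TRUE)
  # days 5-8 of the year fall in the DOY-1 block, days 9-14 in the DOY-9 block
  expect_equal(unname(out), c(mean(1:4), mean(5:10)))
  expect_identical(names(out), c("2005-001", "2005-009"))
})

test_that("metrics report r-squared, bias and rmse with missing pairs excluded", {
  m <- compute_metrics(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(c(m$r_squared, m$bias, m$rmse), c(1, 0, 0))
  m <- compute_metrics(c(1, 2, 3) + 7, c(1, 2, 3))
  expect_equal(c(m$r_squared, m$bias, m$rmse), c(1, 7, 7))
  # hand arithmetic; constant observed series has undefined correlation
  m <- compute_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$bias, 0)
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_true(is.na(m$r_squared))
  # NA pairs dropped from n
  m <- compute_metrics(c(1, NA, 3, 4), c(1, 2, NA, 5))
  expect_equal(m$n, 2L)
  expect_error(compute_metrics(c(1, NA), c(1, 2)), "insufficient")
  # rmse symmetric, bias antisymmetric under argument swap
  set.seed(2)
  p <- rnorm(20); o <- rnorm(20)
  expect_equal(compute_metrics(p, o)$rmse, compute_metrics(o, p)$rmse)
  expect_equal(compute_metrics(p, o)$bias, -compute_metrics(o, p)$bias)
  expect_gte(compute_metrics(p, o)$rmse, abs(compute_metrics(p, o)$bias))
})

test_that("biome grouping pools counts and n-weighted biases", {
  set.seed(3)
  n <- 60
  biome <- rep(c("CRO", "GRA", "ENF"), each = 20)
  o <- runif(n, 20, 120)
  p <- o + rnorm(n, mean = rep(c(2, -4, 6), each = 20), sd = 3)
  rep_all <- group_metrics(p, o, biome)
  expect_setequal(rep_all$group, c("CRO", "GRA", "ENF", "all"))
  pooled <- rep_all[rep_all$group == "all", ]
  groups <- rep_all[rep_all$group != "all", ]
  expect_equal(pooled$n, sum(groups$n))
  expect_equal(pooled$bias, sum(groups$bias * groups$n) / sum(groups$n))
  # single biome: group row and pooled row agree
  one <- group_metrics(p[1:20], o[1:20], biome[1:20])
  expect_equal(nrow(one), 2L)
  expect_equal(one$rmse[1], one$rmse[2])
})
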