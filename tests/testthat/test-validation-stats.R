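# Statistics battery: correlations, cross-classification, Bland-Altman, ICC.

test_that("correlation coefficients respect their invariance classes", {
  x <- c(0.2, 1.5, 0.9, 3.2, 2.1, 0.4, 1.1)
  expect_equal(correlate(x, exp(x), "spearman")$coefficient, 1)
  expect_equal(correlate(x, 2 * x + 3, "pearson")$coefficient, 1)
  y <- 0.5 * x + c(0.1, -0.2, 0.3, 0, -0.1, 0.2, -0.3)
  expect_equal(correlate(x, y, "spearman")$coefficient,
               correlate(exp(x), y, "spearman")$coefficient)
  # hand-ranked sum-of-squared-differences formula
  got <- correlate(1:5, c(2, 1, 4, 3, 5), "spearman")
  d2 <- sum((1:5 - c(2, 1, 4, 3, 5))^2)
  expect_equal(got$coefficient, 1 - 6 * d2 / (5 * (25 - 1)), tolerance = 1e-12)
  expect_equal(got$n, 5)
  # zero variance yields an undefined coefficient, not an error
  expect_true(is.na(correlate(rep(1, 5), 1:5, "pearson")$coefficient))
  expect_error(correlate(1:2, 1:2, "pearson"), "at least 3")
})

test_that("tertile cross-classification handles identity, antitone and toy cases", {
  v <- c(3, 1, 4, 1.5, 5, 9, 2.6, 5.3, 5.8)
  id <- tertile_cross_classify(v, v)
  expect_equal(id$pct_same, 100)
  expect_equal(id$pct_gross, 0)
  expect_equal(sum(id$table), 9)
  # reversed ranking: every extreme lands in the opposite extreme
  rv <- -v
  anti <- tertile_cross_classify(v, rv)
  expect_equal(anti$table[1, 3], 3)
  expect_equal(anti$table[3, 1], 3)
  expect_equal(anti$pct_same_highest, 0)
  # brute-force assignment oracle on ranks 1..9 with one cross-boundary swap
  ref <- 1:9
  test <- c(1, 2, 4, 3, 5, 6, 7, 8, 9)     # swap ranks 3 and 4
  cc <- tertile_cross_classify(ref, test)
  t_ref <- rep(1:3, each = 3)
  t_test <- rep(1:3, each = 3)[order(order(test))]
  expect_equal(unclass(cc$table),
               unclass(table(factor(t_ref, 1:3), factor(t_test, 1:3))),
               ignore_attr = TRUE)
  expect_equal(cc$pct_same, 100 * 7 / 9)
  expect_equal(cc$pct_same + cc$pct_adjacent + cc$pct_gross, 100)
})

test_that("tied values classify deterministically by stable participant order", {
  v <- c(0, 0, 0, 0, 1, 2, 3, 4, 5)  # zero-inflated food
  a <- tertile_cross_classify(v, v, ids = letters[1:9])
  b <- tertile_cross_classify(v, v, ids = letters[1:9])
  expect_identical(a, b)
  expect_equal(a$pct_same, 100)
})

test_that("Bland-Altman summaries match direct arithmetic", {
  ref <- c(10, 12, 8, 14, 9, 11)
  test <- c(11, 12, 7, 16, 10, 12)
  ba <- bland_altman(ref, test)
  d <- test - ref
  expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa, mean(d) + c(-1.96, 1.96) * sd(d), tolerance = 1e-12)
  expect_equal(ba$ci_mean,
               mean(d) + c(-1, 1) * qt(0.975, 5) * sd(d) / sqrt(6),
               tolerance = 1e-12)
  expect_equal(ba$data$mean, (ref + test) / 2)
  # identical methods: zero bias, zero-width limits, nothing outside
  ba0 <- bland_altman(ref, ref)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$n_above + ba0$n_below, 0)
  # constant shift: limits collapse onto the shift
  bas <- bland_altman(ref, ref + 3)
  expect_equal(bas$mean_diff, 3)
  expect_equal(bas$loa, c(3, 3))
})

test_that("ICC(A,k) matches a hand-computed two-way ANOVA oracle", {
  x <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 6))
  n <- 4; k <- 2
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  sse <- sum((x - outer(rowMeans(x), rep(1, k)) -
                outer(rep(1, n), colMeans(x)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  got <- icc_agreement_average(x)
  expect_equal(got$ms, c(MSR = msr, MSC = msc, MSE = mse), tolerance = 1e-12)
  expect_equal(got$icc, (msr - mse) / (msr + (msc - mse) / n),
               tolerance = 1e-12)
  expect_equal(got$icc_single,
               (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
               tolerance = 1e-12)
  expect_true(got$ci[1] < got$icc && got$icc < got$ci[2])
})

test_that("ICC is 1 for duplicated data and near 0 for independent noise", {
  v <- c(3, 1, 4, 1.5, 9)
  dup <- icc_agreement_average(cbind(v, v))
  expect_equal(dup$icc, 1)
  expect_identical(dup$band, "excellent")
  for (s in 1:3) {
    x <- withr::with_seed(s, matrix(rnorm(4000), 2000, 2))
    expect_lt(abs(icc_agreement_average(x)$icc), 0.1)
  }
  # ICC decreases as independent noise is added (averaged over seeds)
  base <- rep(seq(0, 3, length.out = 60), 2)
  iccs <- sapply(c(0.1, 0.5, 1.5), function(sdn) {
    mean(sapply(1:5, function(s) {
      x <- withr::with_seed(10 * s, matrix(base + rnorm(120, 0, sdn), 60, 2))
      icc_agreement_average(x)$icc
    }))
  })
  expect_true(all(diff(iccs) < 0))
})

test_that("reproducibility bands split at 0.5, 0.75 and 0.9", {
  expect_identical(icc_band(c(0.49, 0.5, 0.74, 0.75, 0.9, 0.91)),
                   c("poor", "moderate", "moderate", "good", "good",
                     "excellent"))
})
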