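test_that("r-squared matches the covariance formula and affine invariance", {
  expect_equal(r_squared(1:10, 1:10), 1)
  expect_equal(r_squared(1:10, -2 * (1:10) + 7), 1)
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  # direct covariance-formula oracle
  oracle <- (sum((x - mean(x)) * (y - mean(y))) /
               sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(r_squared(x, y), oracle)
  set.seed(12)
  a <- rnorm(40)
  b <- a + rnorm(40, sd = 0.4)
  expect_equal(r_squared(3 * a - 5, b), r_squared(a, b))
  expect_equal(r_squared(a, -0.1 * b + 2), r_squared(a, b))
  expect_error(r_squared(rep(1, 5), 1:5), "variance")
  expect_error(r_squared(1:2, 1:2), "3")
})

test_that("Bland-Altman bias and limits follow the mean +/- 1.96 sd construction", {
  x <- rnorm(30, 10)
  ident <- bland_altman(x, x)
  expect_equal(ident$mean_difference, 0)
  expect_equal(ident$loa_low, 0)
  expect_equal(ident$loa_high, 0)
  shift <- bland_altman(x, x + 5)
  expect_equal(shift$mean_difference, -5)
  expect_equal(shift$loa_low, -5)
  expect_equal(shift$loa_high, -5)
  set.seed(13)
  d <- rnorm(200, 2, 3)
  ba <- bland_altman(d, rep(0, 200))
  expect_equal(ba$mean_difference, mean(d))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(d))
  # limits scale linearly with the spread of the differences
  ba2 <- bland_altman(3 * d, rep(0, 200))
  expect_equal(ba2$loa_high - ba2$loa_low, 3 * (ba$loa_high - ba$loa_low))
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("Bland-Altman limits cover ~95% of normal differences", {
  set.seed(14)
  n <- 10000
  x <- rnorm(n, 50, 4)
  y <- x + rnorm(n, 1, 2)
  ba <- bland_altman(x, y)
  inside <- mean(ba$pairs$diff >= ba$loa_low & ba$pairs$diff <= ba$loa_high)
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.96)
})

test_that("tidy, glance and autoplot expose the agreement object", {
  ba <- bland_altman(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  td <- tidy(ba)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("mean", "diff"))
  gl <- glance(ba)
  expect_equal(gl$n, 4)
  expect_true(gl$loa_low <= gl$mean_difference &&
                gl$mean_difference <= gl$loa_high)
  p <- autoplot(ba)
  expect_s3_class(p, "ggplot")
})

test_that("t-test variants match closed forms", {
  a <- c(3.1, 2.8, 3.4, 3.0)
  same <- t_tests(a, a, kind = "paired")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  one <- t_tests(c(1, 2, 3), 2, kind = "one_sample")
  expect_equal(one$statistic, 0)
  # pooled two-sample closed form
  g1 <- c(5.1, 4.9, 6.0, 5.5, 5.3)
  g2 <- c(4.2, 4.8, 4.5, 4.1)
  sp2 <- ((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
    (length(g1) + length(g2) - 2)
  t_oracle <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
  tt <- t_tests(g1, g2, kind = "two_sample")
  expect_equal(tt$statistic, t_oracle)
  expect_equal(tt$df, 7)
  expect_equal(tt$p_value, 2 * stats::pt(-abs(t_oracle), 7))
  expect_error(t_tests(1, 2, kind = "paired"), "2 pairs")
  expect_error(t_tests(c(1, 2), c(1, 2), kind = "one_sample"), "single")
})

test_that("report tables assemble per condition and refuse empty input", {
  # two tiny synthetic cohorts with known structure
  fake <- tidyr::expand_grid(aspect_ratio = c(1, 3), i = 1:12) |>
    dplyr::mutate(
      omega_true = rep(seq(15, 85, length.out = 12), 2),
      theta_true = rep(seq(85, 15, length.out = 12), 2),
      omega_2d = .data$omega_true + ifelse(.data$aspect_ratio == 1, 0.1, -10),
      theta_2d = .data$theta_true,
      omega_3d = .data$omega_true,
      theta_3d = .data$theta_true
    )
  tab <- orientation_agreement_table(fake)
  expect_equal(nrow(tab), 4) # 2 angles x 2 aspect ratios
  expect_true(all(tab$r2_3d > 1 - 1e-9))
  expect_equal(tab$diff_2d[tab$angle == "omega" & tab$aspect_ratio == 3], -10)
  acc <- classification_accuracy_table(fake)
  expect_true(all(acc$pct_correct_3d[acc$n_true > 0] == 100))
  expect_error(build_report(NULL, NULL), "[Aa]t least one")
})
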