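test_that("Pearson correlation handles exact linear relations and edge cases", {
  x <- 1:10
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_with_p(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_with_p(1:2, 2:3), ">= 3")
  expect_error(pearson_with_p(rep(1, 5), 1:5), "zero variance")
  # pairwise deletion of missing values
  res <- pearson_with_p(c(x, NA), c(2 * x, 5))
  expect_equal(res$n, 10)
})

test_that("correlation recovery matches the bivariate-normal sampling error bound", {
  set.seed(314)
  n <- 500; rho <- 0.8
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  r <- pearson_with_p(x, y)$r
  expect_lt(abs(r - rho), 3 * (1 - rho^2) / sqrt(n))
})

test_that("correlation matrix is symmetric, unit-diagonal and self-consistent", {
  db <- generate_cohort(cohort_sim_config(n_liners = 80, seed = 41))
  cols <- c("OI(max,UW)", "OI(ave,UW)", "CI(ave,UW)", "HV(ave,UW)")
  cm <- correlation_matrix(db, cols)
  expect_identical(unname(diag(cm$r)), rep(1, 4))
  expect_identical(cm$r, t(cm$r))
  for (i in 1:3) for (j in (i + 1):4) {
    ref <- pearson_with_p(db$records[[cols[i]]], db$records[[cols[j]]])
    expect_equal(cm$r[i, j], ref$r, tolerance = 1e-12)
    expect_equal(cm$p[i, j], ref$p, tolerance = 1e-12)
  }
  # duplicated column -> off-diagonal 1
  rec <- db$records
  rec$dup <- rec[["OI(max,UW)"]]
  cm2 <- correlation_matrix(rec, c("OI(max,UW)", "dup"))
  expect_equal(cm2$r[1, 2], 1, tolerance = 1e-12)
  # short column flagged undefined, not an error
  rec$sparse <- NA_real_
  rec$sparse[1:2] <- c(1, 2)
  cm3 <- correlation_matrix(rec, c("OI(max,UW)", "sparse"))
  expect_true(is.na(cm3$r[1, 2]))
})

test_that("power-law fit recovers exact and noisy parameters", {
  x <- seq(0.2, 6, length.out = 60)
  fit <- fit_power_law(x, 0.4 * x^0.25)
  expect_equal(fit$k, 0.4, tolerance = 1e-6)
  expect_equal(fit$n, 0.25, tolerance = 1e-6)

  # constant y -> n = 0, k = c
  fit0 <- fit_power_law(x, rep(1.7, length(x)))
  expect_equal(fit0$k, 1.7, tolerance = 1e-8)
  expect_equal(fit0$n, 0, tolerance = 1e-8)

  expect_error(fit_power_law(c(-1, 1, 2), c(1, 2, 3)), "positive")
})

test_that("boxplot statistics follow type-7 quartiles and the 1.5 IQR rule", {
  b <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3); expect_equal(b$q1, 2); expect_equal(b$q3, 4)
  expect_length(b$outliers, 0)

  b2 <- boxplot_stats(c(0, 0, 0, 0, 100))
  expect_equal(b2$outliers, 100)
  expect_equal(b2$whisker_high, 0)

  b3 <- boxplot_stats(rep(7, 4))
  expect_equal(c(b3$min, b3$q1, b3$median, b3$q3, b3$max), rep(7, 5))

  # raw min/max whisker mode
  b4 <- boxplot_stats(c(0, 0, 0, 0, 100), whisker_mode = "minmax")
  expect_equal(b4$whisker_high, 100)
  expect_length(b4$outliers, 0)

  # ordering invariant
  expect_true(with(b2, min <= q1 && q1 <= median && median <= q3 && q3 <= max))
})

test_that("two-group comparison covers Welch, Mann-Whitney and degenerate input", {
  same <- c(1.2, 1.5, 1.7, 2.0)
  res <- compare_groups(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  set.seed(99)
  a <- rnorm(50, 0); b <- rnorm(50, 2)
  expect_lt(compare_groups(a, b)$p, 0.001)
  expect_lt(compare_groups(a, b, method = "mann_whitney")$p, 0.001)

  expect_equal(compare_groups(rep(1, 3), rep(1, 4))$p, 1)
  expect_error(compare_groups(1, c(1, 2)), ">= 2")
})

test_that("Welch p agrees with a permutation oracle on small fixed samples", {
  set.seed(7)
  a <- rnorm(8, 0.4, 1); b <- rnorm(9, 0, 1)
  p_t <- compare_groups(a, b)$p
  pooled <- c(a, b); na <- length(a)
  set.seed(8)
  B <- 20000
  stat_obs <- abs(mean(a) - mean(b))
  perm <- replicate(B, {
    idx <- sample(length(pooled), na)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_perm <- (1 + sum(perm >= stat_obs)) / (B + 1)
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_t - p_perm), 3 * se + 0.02)
})

test_that("scatter-matrix summaries agree with OLS and Pearson building blocks", {
  set.seed(123)
  df <- data.frame(a = runif(40, 1, 5))
  df$b <- df$a                      # exact line
  df$c <- 2 * df$a + rnorm(40, 0, 0.3)
  sm <- scatter_matrix_summary(df, c("a", "b", "c"))
  row_ab <- sm$pairs[sm$pairs$x == "a" & sm$pairs$y == "b", ]
  expect_equal(row_ab$slope, 1, tolerance = 1e-9)
  expect_equal(row_ab$intercept, 0, tolerance = 1e-9)
  expect_equal(row_ab$ci_halfwidth_at_mean, 0, tolerance = 1e-9)

  row_ac <- sm$pairs[sm$pairs$x == "a" & sm$pairs$y == "c", ]
  ref <- pearson_with_p(df$a, df$c)
  expect_equal(row_ac$r, ref$r, tolerance = 1e-12)
  expect_equal(row_ac$p, ref$p, tolerance = 1e-12)

  # CI band half-width is minimal near the mean of x
  band <- sm$ci_bands[["a ~ c"]]
  expect_equal(band$x[which.min(band$halfwidth)],
               band$x[which.min(abs(band$x - mean(band$x)))])

  # histogram summaries cover every column
  expect_named(sm$histograms, c("a", "b", "c"))
  expect_equal(sum(sm$histograms$a$counts), 40)
})

test_that("plot exports are pure functions of their statistics objects", {
  db <- generate_cohort(cohort_sim_config(n_liners = 40, seed = 55))
  cm <- correlation_matrix(db, c("OI(max,UW)", "CI(max,UW)", "HV(ave,UW)"))
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  plot_correlation_heatmap(cm, f1)
  plot_correlation_heatmap(cm, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
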