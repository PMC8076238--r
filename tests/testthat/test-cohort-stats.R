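test_that("identical constant groups give F = 0 and p = 1", {
  g <- list(a = rep(2, 5), b = rep(2, 6), c = rep(2, 4))
  res <- one_way_anova(g)
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 12)
})

test_that("with two groups F equals the square of the pooled t statistic", {
  set.seed(7)
  g <- list(x = rnorm(9), y = rnorm(12, 0.5))
  res <- one_way_anova(g)
  tt <- t.test(g$x, g$y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("a fixed three-group example matches the sum-of-squares oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  # brute-force decomposition
  all_v <- unlist(g)
  gm <- mean(all_v)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - gm)^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  F_oracle <- (ssb / 2) / (ssw / 6)
  res <- one_way_anova(g)
  expect_equal(res$F, F_oracle, tolerance = 1e-12)
  expect_equal(res$F, 3, tolerance = 1e-12)
  expect_equal(res$p_value, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(unname(res$group_means), c(2, 3, 4))
})

test_that("ANOVA rejects groups that are too small", {
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "insufficient")
  expect_error(one_way_anova(list(a = c(1, 2))), "2 groups")
})

test_that("Scheffe on identical group means flags nothing", {
  g <- list(a = c(1, 2, 3), b = c(0, 2, 4), c = c(2, 2, 2))
  res <- scheffe_test(g)
  expect_true(all(res$p_value == 1 | res$p_value > 0.99))
  expect_true(all(res$sig == 0))
  expect_equal(res$p_value, t(res$p_value))
})

test_that("Scheffe pairwise p matches a numerical F-distribution oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- scheffe_test(g)
  msw <- res$ms_within
  k <- 3; dfw <- 6
  for (i in 1:2) for (j in (i + 1):3) {
    Fp <- (mean(g[[i]]) - mean(g[[j]]))^2 / (msw * (2 / 3))
    # oracle: numerical integration of the F density upper tail
    p_oracle <- integrate(function(x) df(x, k - 1, dfw), Fp / (k - 1), Inf,
                          rel.tol = 1e-10)$value
    expect_equal(res$p_value[i, j], p_oracle, tolerance = 1e-7)
  }
})

test_that("Scheffe is conservative relative to the unadjusted pooled t test", {
  set.seed(11)
  for (rep in 1:25) {
    g <- lapply(1:4, function(i) rnorm(21))
    names(g) <- paste0("g", 1:4)
    res <- scheffe_test(g)
    aovr <- one_way_anova(g)
    n <- lengths(g)
    N <- sum(n)
    for (i in 1:3) for (j in (i + 1):4) {
      tstat <- (mean(g[[i]]) - mean(g[[j]])) /
        sqrt(aovr$ms_within * (1 / n[i] + 1 / n[j]))
      p_t <- 2 * pt(-abs(tstat), N - 4)
      expect_gte(res$p_value[i, j], p_t)
    }
  }
})

test_that("Pearson correlation matches hand-computed cases and the formula oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  y <- c(1, 3, 2, 5)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), r_oracle, tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 4)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "length")
})

test_that("box-whisker statistics follow the linear-interpolation convention", {
  b <- box_whisker_stats(1:8)
  expect_equal(b$q25, 2.75)
  expect_equal(b$q75, 6.25)
  expect_equal(b$median, 4.5)
  expect_equal(b$mean, 4.5)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 8)
  expect_length(b$outliers, 0)

  eq <- box_whisker_stats(rep(3, 6))
  expect_equal(eq$q25, 3)
  expect_equal(eq$q75, 3)
  expect_length(eq$outliers, 0)

  with_out <- box_whisker_stats(c(1:10, 100))
  expect_equal(with_out$outliers, 100)
  expect_equal(with_out$whisker_high, 10)
  expect_error(box_whisker_stats(1:3), "insufficient")
})

test_that("group statistics are invariant to input ordering", {
  set.seed(13)
  g <- lapply(1:4, function(i) rnorm(10, i * 0.2))
  names(g) <- paste0("g", 1:4)
  shuffled <- lapply(g, sample)
  expect_equal(one_way_anova(g)$F, one_way_anova(shuffled)$F, tolerance = 1e-12)
  expect_equal(scheffe_test(g)$p_value, scheffe_test(shuffled)$p_value,
               tolerance = 1e-12)
})
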