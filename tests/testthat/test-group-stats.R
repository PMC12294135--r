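test_that("summary-based Welch test matches the reference implementation", {
  set.seed(22)
  for (k in 1:25) {
    x <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -2, 2),
                      sd = stats::runif(1, 0.5, 3))
    y <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -2, 2),
                      sd = stats::runif(1, 0.5, 3))
    ref <- stats::t.test(x, y)
    mine <- welch_t_from_summaries(length(x), mean(x), stats::sd(x),
                                   length(y), mean(y), stats::sd(y))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)

    student <- stats::t.test(x, y, var.equal = TRUE)
    mine2 <- welch_t_from_samples(x, y, var_equal = TRUE)
    expect_equal(mine2$p, student$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and trivial two-group cases behave as stated", {
  r <- welch_t_from_summaries(10, 5, 1, 10, 5, 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(welch_t_from_summaries(10, 1, 0, 10, 2, 0), "degenerate")
  expect_error(welch_t_from_summaries(1, 1, 1, 10, 2, 1), "n >= 2")
  expect_error(welch_t_from_samples(1, c(1, 2)), "sample-size error")
  expect_equal(welch_t_from_samples(c(2, 2, 2), c(2, 2, 2))$p, 1)
})

test_that("pincer-width male summaries separate the morphs", {
  r <- welch_t_from_summaries(32, 22.84, 3.84, 40, 17.59, 2.81)
  expect_lt(r$p, 0.05)
  expect_true(r$significant)
})

test_that("sample path equals summary path and matches a permutation test", {
  set.seed(4)
  x <- stats::rnorm(8, 1, 1)
  y <- stats::rnorm(9, 0, 1)
  a <- welch_t_from_samples(x, y)
  b <- welch_t_from_summaries(8, mean(x), stats::sd(x), 9, mean(y), stats::sd(y))
  expect_identical(a$p, b$p)

  # permutation oracle: two-sided p within Monte-Carlo error
  obs <- abs(a$statistic)
  pooled <- c(x, y)
  perm <- replicate(4000, {
    idx <- sample(length(pooled), length(x))
    abs(welch_t_from_samples(pooled[idx], pooled[-idx])$statistic)
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - a$p), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.02)
})

test_that("one-way ANOVA reduces to the squared pooled t for two groups", {
  set.seed(12)
  g1 <- stats::rnorm(10); g2 <- stats::rnorm(12, 0.5)
  f <- one_way_anova(list(g1, g2))
  t2 <- welch_t_from_samples(g1, g2, var_equal = TRUE)$statistic^2
  expect_equal(f$statistic, t2, tolerance = 1e-10)
  expect_equal(f$df, c(1, 20))
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "degenerate")
})

test_that("null simulations give uniform p-values at the nominal rate", {
  set.seed(90)
  p <- replicate(2000, {
    groups <- lapply(1:4, function(i) stats::rnorm(6))
    one_way_anova(groups)$p
  })
  # type-I error close to alpha and overall uniformity
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

test_that("letter display separates exactly the significantly different groups", {
  same <- list(a = c(1, 1.01, 0.99), b = c(1, 1.02, 0.98),
               c = c(1.01, 1, 0.99))
  expect_true(all(letter_display(same) == "a"))

  apart <- list(lo = c(1, 1.1, 0.9, 1.05), hi = c(9, 9.1, 8.9, 9.05))
  l <- letter_display(apart)
  expect_equal(unname(l["hi"]), "a")
  expect_equal(unname(l["lo"]), "b")

  # four-group pattern a/b/b/b from one elevated group
  set.seed(7)
  hits <- replicate(40, {
    gs <- list(r = stats::rnorm(32, 51.7, 4.5), g1 = stats::rnorm(40, 47.9, 5.0),
               g2 = stats::rnorm(33, 46.3, 4.5), g3 = stats::rnorm(31, 44.3, 2.9))
    l <- letter_display(gs)
    !grepl("a", l[["g3"]]) && grepl("a", l[["r"]])
  })
  expect_gte(mean(hits), 0.9)
})
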