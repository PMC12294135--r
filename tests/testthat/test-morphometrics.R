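test_that("ratio standardization divides every trait by the row's CW", {
  t <- as_trait_table(small_trait_df())
  rt <- compute_ratios(t)
  expect_equal(rt$CL_CW, t$CL / t$CW)
  expect_equal(rt$BW_CW[1L], 111.6 / 77.9)
  # CW/CW would be identically 1, so it is not emitted as a ratio
  expect_false("CW_CW" %in% names(rt))
  # originals retained
  expect_equal(rt$CL, t$CL)
})

test_that("group summaries agree with a brute-force two-pass computation", {
  set.seed(14)
  df <- data.frame(
    individual_id = sprintf("i%02d", 1:24),
    sex = rep(c("M", "F"), each = 12),
    morph = rep(c("red", "green"), 12),
    matrix(stats::runif(24 * 9, 10, 100), 24,
           dimnames = list(NULL, c("CL", "CW", "CH", "BW", "FOMW",
                                   "FFLC", "MLC", "PW", "ST"))))
  s <- summarize_groups(df, by = c("morph", "sex"), variables = c("CL", "PW"))
  for (i in seq_len(nrow(s))) {
    rows <- df[df$morph == s$morph[i] & df$sex == s$sex[i], s$variable[i]]
    mu <- sum(rows) / length(rows)
    expect_equal(s$mean[i], mu)
    expect_equal(s$sd[i], sqrt(sum((rows - mu)^2) / (length(rows) - 1)))
  }
  expect_equal(summarize_groups(data.frame(g = c("a", "a", "a"),
                                           v = c(1, 2, 3)), by = "g")$sd, 1)
  expect_error(summarize_groups(data.frame(g = c("a", "b", "b"), v = 1:3),
                                by = "g"), "n >= 2")
})

test_that("coefficient of difference reproduces the male BW/CW anchor", {
  r <- coefficient_of_difference(1.40, 0.33, 1.10, 0.25)
  expect_equal(r$cd, 0.30 / 0.58)
  expect_equal(round(r$cd, 2), 0.52)
  expect_false(r$exceeds_subspecies_threshold)
})

test_that("CD is symmetric, non-negative and scale invariant", {
  set.seed(3)
  for (k in 1:50) {
    m1 <- stats::runif(1, 0.1, 5); m2 <- stats::runif(1, 0.1, 5)
    s1 <- stats::runif(1, 0.01, 1); s2 <- stats::runif(1, 0.01, 1)
    cd <- coefficient_of_difference(m1, s1, m2, s2)$cd
    expect_gte(cd, 0)
    expect_equal(coefficient_of_difference(m2, s2, m1, s1)$cd, cd)
    c0 <- stats::runif(1, 0.5, 20)
    expect_equal(coefficient_of_difference(c0 * m1, c0 * s1,
                                           c0 * m2, c0 * s2)$cd, cd)
  }
  expect_equal(coefficient_of_difference(2, 0, 2, 0)$cd, 0)
  expect_error(coefficient_of_difference(2, 0, 3, 0), "degenerate-dispersion")
})

test_that("summary-statistic screen flags the three discriminating ratios", {
  scr <- subspecies_screen_from_summaries(crab_male_ratio_summaries())
  expect_true(all(c("CL_CW", "PW_CW", "BW_CW") %in% names(scr$results)))
  # ratios with identical printed summaries never reach the CD stage
  expect_true(all(c("FFLC_CW", "MLC_CW", "ST_CW") %in% scr$screened_out))
  expect_lt(scr$max_cd, 1.28)
  expect_false(scr$subspecies_level)
})

test_that("screen on identical groups yields an empty CD list", {
  g <- crab_group_params()$red_M
  g2 <- g; g2$morph <- "green"
  cfg <- trait_sim_config(list(g, g2), seed = 2)
  rt <- compute_ratios(simulate_trait_table(cfg))
  # same generating distribution: occasional false positives are possible,
  # so screen at a tiny alpha where the null holds almost surely
  scr <- subspecies_screen(rt, alpha = 1e-6)
  expect_length(scr$results, 0L)
  expect_equal(scr$max_cd, 0)
})

test_that("lowering alpha never adds ratios to the CD list", {
  rt <- compute_ratios(simulate_trait_table(crab_trait_config(seed = 5,
                                                              sexes = "M")))
  alphas <- c(0.2, 0.05, 0.01, 0.001)
  picked <- lapply(alphas, function(a)
    names(subspecies_screen(rt, alpha = a)$results))
  for (k in seq_len(length(alphas) - 1L))
    expect_true(all(picked[[k + 1L]] %in% picked[[k]]))
})

test_that("screen requires exactly two morph groups in the stratum", {
  rt <- compute_ratios(simulate_trait_table(crab_trait_config(seed = 5)))
  one <- rt[rt$morph == "red", ]
  expect_error(subspecies_screen(one), "stratification error")
})
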