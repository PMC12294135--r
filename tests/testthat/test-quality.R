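test_that("amino-acid quantitation follows unit algebra", {
  # 10 mg/L over 20 mL at dilution 1 from a 0.2 g sample -> 1000 mg/kg
  expect_equal(aa_content(m = 0.2, C = 10, C0 = 0, V = 20, N = 1), 1000)
  # verbatim legacy product on the same input
  expect_equal(aa_content(m = 0.2, C = 10, C0 = 0, V = 20, N = 1,
                          formula = "as_printed"), 40)
  expect_equal(aa_content(m = 0.2, C = 5, C0 = 5, V = 20, N = 1), 0)
  expect_equal(aa_content(m = 0.2, C = 5, C0 = 5, V = 20, N = 1,
                          formula = "as_printed"), 0)
  expect_warning(w <- aa_content(m = 0.2, C = 1, C0 = 5, V = 20, N = 1),
                 "floored")
  expect_equal(w, 0)
  expect_error(aa_content(m = 0, C = 1, C0 = 0, V = 20, N = 1), "positive")

  # linearity in net concentration, volume and dilution under both forms
  base <- aa_content(m = 0.5, C = 4, C0 = 1, V = 10, N = 2)
  expect_equal(aa_content(m = 0.5, C = 7, C0 = 1, V = 10, N = 2), 2 * base)
  expect_equal(aa_content(m = 0.5, C = 4, C0 = 1, V = 20, N = 2), 2 * base)
  expect_equal(aa_content(m = 0.5, C = 4, C0 = 1, V = 10, N = 4), 2 * base)
})

test_that("category sums reproduce the red-morph anchor values", {
  tab <- crab_aa_table()
  sums <- aa_category_sums(setNames(tab$red_mean, tab$amino_acid))
  expect_equal(round(sums[["EAA"]], 2), 4.11)
  expect_equal(round(sums[["DAA"]], 2), 4.29)
  expect_equal(round(sums[["total"]], 2), 11.66)
  expect_equal(sums[["total"]], sums[["EAA"]] + sums[["SEAA"]] + sums[["NEAA"]])
})

test_that("category sums validate completeness and additivity", {
  tab <- crab_aa_table()
  zero <- setNames(rep(0, nrow(tab)), tab$amino_acid)
  expect_true(all(aa_category_sums(zero) == 0))
  expect_error(aa_category_sums(zero[-1]), "completeness error.*Leucine")
  set.seed(19)
  for (k in 1:10) {
    prof <- setNames(stats::runif(nrow(tab), 0, 2), tab$amino_acid)
    s <- aa_category_sums(prof)
    expect_equal(s[["total"]], s[["EAA"]] + s[["SEAA"]] + s[["NEAA"]])
    expect_equal(s[["DAA"]], sum(prof[c("Phenylalanine", "Glutamic Acid",
                                        "Aspartic Acid", "Alanine",
                                        "Tyrosine")]))
  }
})

test_that("color summaries average points per crab then crabs per group", {
  pts <- data.frame(crab_id = c("c1", "c1", "c2", "c2"),
                    group = "red",
                    L = c(30, 40, 20, 20), a = c(10, 10, 12, 14),
                    b = c(5, 7, 6, 6))
  cs <- color_summary(pts)
  expect_equal(sort(cs$per_crab$L), c(20, 35))
  expect_equal(cs$per_group$L, 27.5)

  single <- color_summary(data.frame(crab_id = "c1", group = "g",
                                     L = 50, a = 1, b = 2))
  expect_equal(single$per_crab$L, 50)
  expect_error(color_summary(data.frame(crab_id = character(0),
                                        group = character(0),
                                        L = numeric(0), a = numeric(0),
                                        b = numeric(0))), "empty")
  expect_error(color_summary(transform(pts, L = L + 200)), "L\\*")
})

test_that("simulated color groups separate with the red morph darker", {
  col <- color_scenario()
  mk <- function(gp, seed0) do.call(rbind, lapply(1:6, function(ci) {
    mu <- simulate_replicates(
      if (gp == "red") col$red_mean[1] else col$green_mean[1],
      if (gp == "red") col$red_sd[1] else col$green_sd[1], 1, seed0 + ci)
    data.frame(crab_id = paste0(gp, ci), group = gp,
               L = simulate_replicates(mu, col$point_sd[1], 8, seed0 + 50 + ci),
               a = 0, b = 0)
  }))
  cs <- color_summary(rbind(mk("red", 100), mk("green", 200)))
  x <- cs$per_crab$L[cs$per_crab$group == "red"]
  y <- cs$per_crab$L[cs$per_crab$group == "green"]
  tt <- welch_t_from_samples(x, y)
  expect_true(tt$significant)
  expect_lt(mean(x), mean(y))
})

test_that("texture comparison stars follow the significance convention", {
  expect_equal(significance_stars(c(0.04, 0.006, 0.3)), c("*", "**", "ns"))
  same <- data.frame(hardness = c(8, 9, 10), gumminess = c(3, 4, 5))
  expect_true(all(texture_compare(same, same)$stars == "ns"))

  tex <- texture_scenario()
  i <- which(tex$parameter == "gumminess")
  red <- data.frame(gumminess = simulate_replicates(tex$red_mean[i],
                                                    tex$red_sd[i], 3, 71))
  green <- data.frame(gumminess = simulate_replicates(tex$green_mean[i],
                                                      tex$green_sd[i], 3, 72))
  res <- texture_compare(red, green)
  expect_lt(res$p, 0.05)
})

test_that("gumminess consistency flags departures from hardness x cohesiveness", {
  h <- c(10, 12); c0 <- c(0.4, 0.5)
  ok <- gumminess_consistency(h, c0, h * c0)
  expect_true(all(ok$ok))
  bad <- gumminess_consistency(h, c0, h * c0 * 1.5)
  expect_false(any(bad$ok))
})
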