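test_that("zero-variance trait simulation reproduces group means exactly", {
  g <- list(morph = "red", sex = "M", n = 5, CW_mean = 80, CW_sd = 0,
            ratio_mean = setNames(c(0.66, 0.38, 0.5, 0.34, 0.39, 0.29, 1.4, 0.01),
                                  c("CL", "CH", "FOMW", "FFLC", "MLC", "PW", "BW", "ST")),
            ratio_sd = setNames(rep(0, 8),
                                c("CL", "CH", "FOMW", "FFLC", "MLC", "PW", "BW", "ST")))
  t <- simulate_trait_table(trait_sim_config(list(g), seed = 3))
  expect_equal(t$CW, rep(80, 5))
  expect_equal(t$CL / t$CW, rep(0.66, 5))
  expect_equal(t$BW / t$CW, rep(1.4, 5))
})

test_that("trait simulation is deterministic and recovers configured ratios", {
  cfg <- crab_trait_config(seed = 9)
  t1 <- simulate_trait_table(cfg)
  t2 <- simulate_trait_table(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 32 + 40 + 33 + 31)

  # law-of-large-numbers: at n = 4000 per group, sample ratio means sit
  # within 3 SE of the configured means
  big <- crab_group_params()$red_M
  big$n <- 4000L
  tb <- simulate_trait_table(trait_sim_config(list(big), seed = 21))
  for (trait in c("CL", "PW", "BW")) {
    ratio <- tb[[trait]] / tb$CW
    se <- big$ratio_sd[[trait]] / sqrt(big$n)
    expect_lt(abs(mean(ratio) - big$ratio_mean[[trait]]), 3 * se)
  }
})

test_that("haplotype simulation realizes the configured variant structure", {
  cfg <- coi_scenario(seed = 5)
  s <- simulate_haplotype_set(cfg)
  expect_equal(length(s), 12L)
  expect_equal(nchar(s$seqs[1L]), 673L)

  red <- collapse_haplotypes(
    aligned_seq_set(s$ids[s$groups == "red"], s$groups[s$groups == "red"],
                    s$seqs[s$groups == "red"], "COI"))
  expect_equal(nrow(red), 2L)
  expect_equal(sort(red$count), c(1L, 5L))

  green_seqs <- s$seqs[s$groups == "green"]
  expect_equal(length(unique(green_seqs)), 4L)

  # the single red variant is a T->C change at the configured site
  m <- strsplit(s$seqs[s$groups == "red"], "")
  col <- vapply(m, `[`, character(1L), 101L)
  expect_equal(sort(unique(col)), c("C", "T"))
  expect_equal(sum(col == "C"), 1L)
})

test_that("haplotype count equals distinct carrier signatures plus one", {
  cfg <- haplo_sim_config(
    L = 60, base_freqs = c(A = 0.25, T = 0.25, C = 0.25, G = 0.25),
    groups = c(x = 5L),
    variant_sites = list(
      list(position = 3L, from = "A", to = "G", carriers = c("x1", "x2")),
      list(position = 9L, from = "A", to = "C", carriers = "x2")),
    seed = 8)
  s <- simulate_haplotype_set(cfg)
  # signatures: {}, {site3}, {site3+site9} -> 3 haplotypes
  expect_equal(nrow(collapse_haplotypes(s)), 3L)

  none <- haplo_sim_config(L = 30,
                           base_freqs = c(A = .25, T = .25, C = .25, G = .25),
                           groups = c(x = 4L), seed = 2)
  expect_equal(nrow(collapse_haplotypes(simulate_haplotype_set(none))), 1L)
})

test_that("haplotype config rejects degenerate variant specs", {
  freqs <- c(A = .25, T = .25, C = .25, G = .25)
  expect_error(haplo_sim_config(10, freqs, c(x = 2L),
                                variant_sites = list(list(position = 3L,
                                                          from = "T", to = "T",
                                                          carriers = "x1")),
                                seed = 1),
               "to_state equals from_state")
  expect_error(haplo_sim_config(10, freqs, c(x = 2L),
                                variant_sites = list(list(position = 11L,
                                                          from = "T", to = "C",
                                                          carriers = "x1")),
                                seed = 1),
               "out of")
})

test_that("simulated base composition matches the configured frequencies", {
  cfg <- coi_scenario(seed = 4)
  s <- simulate_haplotype_set(cfg)
  comp <- base_composition(s)
  # multinomial tolerance at L = 673: 3 * sqrt(p(1-p)/L) is < 2.3 points
  for (b in c("A", "T", "C", "G")) {
    p <- cfg$base_freqs[[b]]
    expect_lt(abs(comp[[b]] / 100 - p), 3 * sqrt(p * (1 - p) / cfg$L))
  }
  expect_gt(comp$AT_content, comp$CG_content)
})

test_that("outgroup simulation hits its target K2P distance", {
  ref <- random_seq(673, seed = 31)
  expect_identical(simulate_outgroup(ref, 0, seed = 1), ref)

  out <- simulate_outgroup(ref, 0.15, seed = 1)
  d <- k2p_distance(ref, out)$d
  expect_gte(d, 0.14)
  expect_lte(d, 0.16)

  # monotone sweep: increasing targets give non-decreasing realized distance
  targets <- c(0.05, 0.1, 0.2, 0.35, 0.5)
  realized <- vapply(targets, function(td)
    k2p_distance(ref, simulate_outgroup(ref, td, seed = 7))$d, numeric(1L))
  expect_true(all(diff(realized) >= 0))

  expect_error(simulate_outgroup(ref, 5, seed = 1), "domain error")
})

test_that("replicate simulation is exact at sd 0 and converges in mean", {
  expect_equal(simulate_replicates(3.5, 0, 4, seed = 1), rep(3.5, 4))
  x <- simulate_replicates(10, 2, 1e5, seed = 6)
  expect_lt(abs(mean(x) - 10), 4 * 2 / sqrt(1e5))
  expect_identical(simulate_replicates(1, 1, 10, seed = 9),
                   simulate_replicates(1, 1, 10, seed = 9))
})
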