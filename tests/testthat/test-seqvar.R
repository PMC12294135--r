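test_that("base composition counts unambiguous ungapped sites only", {
  c1 <- base_composition("ATCG")
  expect_equal(c(c1$A, c1$T, c1$C, c1$G), c(25, 25, 25, 25))
  c2 <- base_composition("AATT")
  expect_equal(c(c2$A, c2$T, c2$C, c2$G), c(50, 50, 0, 0))
  c3 <- base_composition("AA--NN")
  expect_equal(c3$A, 100)
  expect_equal(c3$sites_used, 2L)
  expect_error(base_composition("--NN"), "empty-composition")
  # proportions always close to 100
  expect_equal(c2$AT_content + c2$CG_content, 100, tolerance = 1e-9)
})

test_that("pairwise identity handles gaps per policy", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  expect_equal(pairwise_identity("AC-T", "ACGT"), 100)
  expect_equal(pairwise_identity("AC-T", "ACGT", gap_policy = "gap_mismatch"), 75)
  # 673 columns with 666 matches and no gaps -> 98.96 at 2 dp
  a <- strrep("A", 673)
  b <- paste0(strrep("A", 666), strrep("C", 7))
  expect_equal(round(pairwise_identity(a, b), 2), 98.96)
  expect_error(pairwise_identity("----", "AC-T"), "undefined-identity")
  expect_error(pairwise_identity("ACG", "ACGT"), "unequal")
})

test_that("identity is symmetric and exclude_gaps dominates gap_mismatch", {
  set.seed(17)
  for (k in 1:30) {
    a <- random_seq(60, gaps = sample(0:6, 1))
    b <- random_seq(60, gaps = sample(0:6, 1))
    i1 <- pairwise_identity(a, b)
    expect_equal(pairwise_identity(b, a), i1)
    expect_gte(i1, pairwise_identity(a, b, gap_policy = "gap_mismatch"))
    expect_equal(pairwise_identity(a, a), 100)
  }
})

test_that("site classification matches a brute-force column classifier", {
  brute <- function(col) {
    if (any(col == "-")) return("gapped")
    if (any(col == "N")) return("ambiguous")
    tab <- table(col)
    if (length(tab) == 1) "invariant"
    else if (sum(tab >= 2) >= 2) "parsimony_informative"
    else if (length(tab) == 2 && min(tab) == 1) "singleton"
    else "variable_other"
  }
  set.seed(23)
  for (k in 1:10) {
    s <- random_aligned_set(6, 50, seed = k, mut_rate = 0.15)
    m <- do.call(rbind, strsplit(s$seqs, ""))
    cl <- classify_sites(s)
    expect_equal(cl$sites$category,
                 apply(m, 2, brute))
    expect_equal(cl$counts[["variable"]],
                 cl$counts[["singleton"]] + cl$counts[["parsimony_informative"]] +
                   sum(cl$sites$category == "variable_other"))
    expect_true(all(cl$counts <= 50))
  }
})

test_that("change types follow the purine/pyrimidine definition", {
  s <- aligned_seq_set(c("a", "b", "c", "d", "e", "f"),
                       rep("g", 6),
                       c("TAC", "TAC", "TAT", "TAC", "TCC", "CAC"),
                       "toy")
  cl <- classify_sites(s)
  # column 1: TTTTTC singleton transition (T<->C)
  expect_equal(cl$sites$category[1L], "singleton")
  expect_equal(cl$sites$change_type[1L], "transition")
  # column 2: A/C singleton transversion
  expect_equal(cl$sites$change_type[2L], "transversion")
  # column 3: C/T singleton transition
  expect_equal(cl$sites$change_type[3L], "transition")
})

test_that("haplotype collapsing equals distinct-string cardinality", {
  set.seed(29)
  for (k in 1:10) {
    s <- random_aligned_set(sample(4:12, 1), 30, seed = 100 + k,
                            mut_rate = 0.03)
    h <- collapse_haplotypes(s)
    expect_equal(nrow(h), length(unique(s$seqs)))
    expect_equal(sum(h$count), length(s))
    members <- unlist(strsplit(h$members, ","))
    expect_setequal(members, s$ids)
    expect_false(anyDuplicated(members) > 0)
  }
  five_one <- aligned_seq_set(sprintf("r%d", 1:6), rep("red", 6),
                              c(rep("ACGTACGT", 5), "ACGTACAT"), "m")
  h <- collapse_haplotypes(five_one)
  expect_equal(h$count, c(5L, 1L))
  expect_equal(h$haplotype, c("hap1", "hap2"))
})

test_that("group identity via consensus tolerates minority variants", {
  cfg <- coi_scenario(seed = 77)
  s <- simulate_haplotype_set(cfg)
  id <- group_identity(s, "red", "green")
  expect_equal(id, 100)  # consensuses are both the shared reference
  idp <- group_identity(s, "red", "green", method = "mean_pair")
  expect_lt(idp, 100)
  expect_gt(idp, 99)
  expect_error(group_identity(s, "red", "blue"), "not present")
})
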