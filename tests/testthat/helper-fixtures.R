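# Shared fixture builders: everything is generated in code at test time.

random_seq <- function(L, gaps = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (gaps > 0) ch[sample(L, gaps)] <- "-"
  paste(ch, collapse = "")
}

# Pair of sequences at a bounded divergence (below K2P saturation).
random_diverged_pair <- function(L, max_div = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  b <- a
  k <- stats::rbinom(1L, L, stats::runif(1, 0, max_div))
  if (k > 0) {
    pos <- sample(L, k)
    b[pos] <- vapply(b[pos], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1L))
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

random_aligned_set <- function(n, L, seed, mut_rate = 0.05, marker = "sim") {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- ref
    k <- stats::rbinom(1L, L, mut_rate)
    if (k > 0) {
      pos <- sample(L, k)
      s[pos] <- vapply(s[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
    }
    paste(s, collapse = "")
  }, character(1L))
  aligned_seq_set(sprintf("s%02d", seq_len(n)),
                  rep(c("red", "green"), length.out = n), seqs, marker)
}

# Additive distance matrix from a random binary tree with positive branch
# lengths; returns both for oracle comparisons.
random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

# Ultrametric (clock-like) matrix from a random coalescent tree.
random_ultrametric_case <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n_taxa)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

small_trait_df <- function() {
  data.frame(
    individual_id = c("r1", "g1"), sex = c("M", "M"),
    morph = c("red", "green"),
    CL = c(51.7, 48.0), CW = c(77.9, 71.3), CH = c(29.5, 28.6),
    BW = c(111.6, 80.5), FOMW = c(39.0, 36.4), FFLC = c(26.9, 24.3),
    MLC = c(30.4, 27.5), PW = c(22.8, 17.6), ST = c(0.71, 0.62),
    stringsAsFactors = FALSE)
}
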