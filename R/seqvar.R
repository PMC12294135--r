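# Alignment-level descriptive statistics: base composition, percent
# identity, variable-site classification and haplotype collapsing.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Base composition of a sequence or aligned set
#'
#' Percentages of A, T, C, G over unambiguous, ungapped sites (gaps and N
#' excluded from the denominator). For an [aligned_seq_set()] the result is
#' the per-record mean of percentages, matching how per-group compositions
#' are usually reported.
#'
#' @param s a sequence string or an [aligned_seq_set()].
#' @return A `composition_profile` list: percentages `A`, `T`, `C`, `G`,
#'   `AT_content`, `CG_content` and `sites_used` (total unambiguous sites).
#' @examples
#' base_composition("ATCG")  # 25/25/25/25
#' @export
base_composition <- function(s) {
  seqs <- if (inherits(s, "aligned_seq_set")) s$seqs else as.character(s)
  per_rec <- lapply(toupper(seqs), function(sq) {
    ch <- strsplit(sq, "", fixed = TRUE)[[1L]]
    ch <- ch[ch %in% c("A", "T", "C", "G")]
    if (length(ch) == 0L)
      stop("empty-composition error: no unambiguous bases")
    counts <- vapply(c("A", "T", "C", "G"), function(b) sum(ch == b), numeric(1L))
    list(pct = 100 * counts / length(ch), used = length(ch))
  })
  pct <- colMeans(do.call(rbind, lapply(per_rec, `[[`, "pct")))
  structure(list(A = pct[["A"]], T = pct[["T"]], C = pct[["C"]], G = pct[["G"]],
                 AT_content = pct[["A"]] + pct[["T"]],
                 CG_content = pct[["C"]] + pct[["G"]],
                 sites_used = sum(vapply(per_rec, `[[`, numeric(1L), "used"))),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("A %.1f%%  T %.1f%%  C %.1f%%  G %.1f%%  (A+T %.1f%%, C+G %.1f%%)\n",
              x$A, x$T, x$C, x$G, x$AT_content, x$CG_content))
  invisible(x)
}

#' Percent identity between two aligned sequences
#'
#' `100 * matches / comparable columns`. Under the default policy
#' `"exclude_gaps"`, columns with a gap or N in either record are removed
#' from both numerator and denominator; `"gap_mismatch"` keeps gap columns
#' and counts them as mismatches (N columns are always excluded as missing
#' data).
#'
#' @param a,b aligned sequence strings of equal length.
#' @param gap_policy `"exclude_gaps"` (default) or `"gap_mismatch"`.
#' @return Percent identity (0-100).
#' @examples
#' pairwise_identity("AC-T", "ACGT")                         # 100
#' pairwise_identity("AC-T", "ACGT", gap_policy = "gap_mismatch")  # 75
#' @export
pairwise_identity <- function(a, b, gap_policy = c("exclude_gaps", "gap_mismatch")) {
  gap_policy <- match.arg(gap_policy)
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb))
    stop("alignment error: sequences have unequal aligned lengths")
  missing_n <- ca == "N" | cb == "N"
  gapped <- ca == "-" | cb == "-"
  if (gap_policy == "exclude_gaps") {
    keep <- !missing_n & !gapped
    matches <- sum(ca[keep] == cb[keep])
  } else {
    keep <- !missing_n
    matches <- sum(ca[keep] == cb[keep] & !gapped[keep])
  }
  if (sum(keep) == 0L)
    stop("undefined-identity error: zero comparable columns")
  100 * matches / sum(keep)
}

#' Identity between two groups of an aligned set
#'
#' The single identity value reported for a pair of population samples.
#' `method = "consensus"` (default) compares the two groups' majority-rule
#' consensus sequences; `method = "mean_pair"` averages all between-group
#' pairwise identities.
#'
#' @param s an [aligned_seq_set()] containing both groups.
#' @param group1,group2 group labels present in `s`.
#' @param method `"consensus"` or `"mean_pair"`.
#' @inheritParams pairwise_identity
#' @return Percent identity (0-100).
#' @export
group_identity <- function(s, group1, group2,
                           method = c("consensus", "mean_pair"),
                           gap_policy = "exclude_gaps") {
  method <- match.arg(method)
  i1 <- which(s$groups == group1)
  i2 <- which(s$groups == group2)
  if (!length(i1) || !length(i2))
    stop("group label(s) not present in the sequence set")
  if (method == "consensus") {
    pairwise_identity(consensus_sequence(seq_subset(s, i1)),
                      consensus_sequence(seq_subset(s, i2)),
                      gap_policy = gap_policy)
  } else {
    grid <- expand.grid(a = i1, b = i2)
    mean(mapply(function(a, b) {
      pairwise_identity(s$seqs[a], s$seqs[b], gap_policy = gap_policy)
    }, grid$a, grid$b))
  }
}

#' Classify every alignment column
#'
#' Columns are labelled `invariant`, `singleton` (exactly two states, minor
#' count 1), `parsimony_informative` (at least two states each carried by at
#' least two records), `variable_other` (more than two states, only one of
#' them repeated), `gapped` (any gap in the column, excluded from variable
#' counts) or `ambiguous` (N present, no gap). Change type is assigned by
#' purine/pyrimidine classes: A-G and C-T are transitions, cross-class
#' changes transversions, columns mixing both `mixed`.
#'
#' @param s an [aligned_seq_set()] with at least two records.
#' @return A `site_classification` list: `sites` (data.frame with `column`,
#'   `category`, `states`, `change_type`) and `counts` (named vector with
#'   `invariant`, `singleton`, `parsimony_informative`, `variable`,
#'   `gapped`, `ambiguous`).
#' @export
classify_sites <- function(s) {
  if (length(s) < 2L) stop("need at least 2 records to classify sites")
  m <- seq_matrix(s)
  site <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == "-"))
      return(list(category = "gapped", states = paste(sort(unique(col)), collapse = "/"),
                  change_type = "none"))
    has_n <- any(col == "N")
    bases <- col[col != "N"]
    tab <- table(bases)
    states <- paste(names(tab), collapse = "/")
    if (length(tab) <= 1L) {
      cat_base <- if (has_n) "ambiguous" else "invariant"
      return(list(category = cat_base, states = states, change_type = "none"))
    }
    category <- if (has_n) "ambiguous"
      else if (sum(tab >= 2L) >= 2L) "parsimony_informative"
      else if (length(tab) == 2L && min(tab) == 1L) "singleton"
      else "variable_other"
    pairs <- utils::combn(names(tab), 2)
    kinds <- apply(pairs, 2L, function(p) {
      same_class <- (all(p %in% PURINES)) || (all(p %in% PYRIMIDINES))
      if (same_class) "transition" else "transversion"
    })
    change <- if (all(kinds == "transition")) "transition"
      else if (all(kinds == "transversion")) "transversion"
      else "mixed"
    list(category = category, states = states, change_type = change)
  })
  sites <- data.frame(
    column = seq_len(ncol(m)),
    category = vapply(site, `[[`, character(1L), "category"),
    states = vapply(site, `[[`, character(1L), "states"),
    change_type = vapply(site, `[[`, character(1L), "change_type"),
    stringsAsFactors = FALSE)
  counts <- c(
    invariant = sum(sites$category == "invariant"),
    singleton = sum(sites$category == "singleton"),
    parsimony_informative = sum(sites$category == "parsimony_informative"),
    variable = sum(sites$category %in%
                     c("singleton", "parsimony_informative", "variable_other")),
    gapped = sum(sites$category == "gapped"),
    ambiguous = sum(sites$category == "ambiguous"))
  structure(list(sites = sites, counts = counts), class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("Site classification:",
      paste(sprintf("%s %d", names(x$counts), x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Collapse an aligned set into haplotypes
#'
#' Records are grouped by exact string equality of their full aligned
#' sequences; haplotype ids (`hap1`, `hap2`, ...) are assigned in order of
#' first occurrence, which makes the table deterministic for a given input
#' order. With `gap_policy = "exclude_gaps"`, fully gapped-identical
#' comparison is still exact string equality; the policy is reserved for
#' future partial-matching variants and currently only recorded.
#'
#' @param s an [aligned_seq_set()].
#' @param gap_policy recorded on the result (default `"exact"`).
#' @return A `haplotype_table` data.frame: `haplotype`, `sequence`,
#'   `members` (comma-joined ids), `count`.
#' @export
collapse_haplotypes <- function(s, gap_policy = "exact") {
  first <- !duplicated(s$seqs)
  reps <- s$seqs[first]
  idx <- match(s$seqs, reps)
  out <- data.frame(
    haplotype = paste0("hap", seq_along(reps)),
    sequence = reps,
    members = vapply(seq_along(reps), function(h)
      paste(s$ids[idx == h], collapse = ","), character(1L)),
    count = as.integer(tabulate(idx, nbins = length(reps))),
    stringsAsFactors = FALSE)
  attr(out, "gap_policy") <- gap_policy
  class(out) <- c("haplotype_table", "data.frame")
  out
}
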