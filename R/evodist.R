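# Evolutionary distances: uncorrected p-distance and the Kimura
# two-parameter correction, plus pairwise matrices and group summaries.

# Comparable columns between two aligned char vectors under pairwise
# deletion: both unambiguous bases (no gap, no N).
comparable_columns <- function(ca, cb) {
  ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
}

site_change_kind <- function(a, b) {
  # "same", "transition" (A<->G, C<->T) or "transversion"
  ifelse(a == b, "same",
         ifelse((a %in% PURINES) == (b %in% PURINES), "transition",
                "transversion"))
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites over comparable columns (pairwise deletion
#' of gaps and N).
#'
#' @param a,b aligned sequence strings of equal length.
#' @param gap_policy only `"pairwise_deletion"` is implemented.
#' @return Distance in substitutions/site.
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
#' @export
p_distance <- function(a, b, gap_policy = "pairwise_deletion") {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb))
    stop("alignment error: sequences have unequal aligned lengths")
  keep <- comparable_columns(ca, cb)
  if (!any(keep)) stop("no comparable columns between sequences")
  sum(ca[keep] != cb[keep]) / sum(keep)
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` the transition and
#' `Q` the transversion proportion over comparable columns (pairwise
#' deletion). Transitions are the within-class changes A-G and C-T;
#' transversions cross the purine/pyrimidine boundary.
#'
#' @inheritParams p_distance
#' @return A `k2p_distance` list: `d`, `P`, `Q`, `n_sites`. Arithmetic on
#'   the plain distance can use `$d` or `as.numeric()`.
#' @examples
#' k2p_from_pq(0.1, 0)$d  # -0.5 * log(0.8)
#' @export
k2p_distance <- function(a, b, gap_policy = "pairwise_deletion") {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb))
    stop("alignment error: sequences have unequal aligned lengths")
  keep <- comparable_columns(ca, cb)
  if (!any(keep)) stop("no comparable columns between sequences")
  kind <- site_change_kind(ca[keep], cb[keep])
  P <- sum(kind == "transition") / sum(keep)
  Q <- sum(kind == "transversion") / sum(keep)
  out <- k2p_from_pq(P, Q)
  out$n_sites <- sum(keep)
  out
}

#' Kimura two-parameter distance from P and Q proportions
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @return A `k2p_distance` list with `d`, `P`, `Q`.
#' @export
k2p_from_pq <- function(P, Q) {
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    stop("saturation error: K2P undefined for P = ", P, ", Q = ", Q)
  structure(list(d = -0.5 * log(arg1 * sqrt(arg2)), P = P, Q = Q),
            class = "k2p_distance")
}

#' @export
as.numeric.k2p_distance <- function(x, ...) x$d

#' @export
print.k2p_distance <- function(x, ...) {
  cat(sprintf("K2P distance %.6f (P = %.4f, Q = %.4f)\n", x$d, x$P, x$Q))
  invisible(x)
}

distance_matrix_obj <- function(d, model, gap_policy, groups = NULL) {
  structure(list(labels = rownames(d), d = d, model = model,
                 gap_policy = gap_policy, groups = groups),
            class = "distance_matrix")
}

#' Pairwise distance matrix for an aligned set
#'
#' @param s an [aligned_seq_set()] with at least two records.
#' @param model `"k2p"` (default) or `"p"`.
#' @return A `distance_matrix`: `labels`, symmetric matrix `d` (zero
#'   diagonal), `model`, `gap_policy` and the records' `groups`.
#' @export
distance_matrix <- function(s, model = c("k2p", "p")) {
  model <- match.arg(model)
  n <- length(s)
  if (n < 2L) stop("need at least two records")
  d <- matrix(0, n, n, dimnames = list(s$ids, s$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- tryCatch(
        if (model == "k2p") k2p_distance(s$seqs[i], s$seqs[j])$d
        else p_distance(s$seqs[i], s$seqs[j]),
        error = function(e) stop(sprintf("pair (%s, %s): %s", s$ids[i],
                                         s$ids[j], conditionMessage(e)),
                                 call. = FALSE))
      d[i, j] <- d[j, i] <- dij
    }
  }
  distance_matrix_obj(d, model, "pairwise_deletion",
                      groups = stats::setNames(s$groups, s$ids))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix, %d taxa (%s)\n", toupper(x$model),
              nrow(x$d), x$gap_policy))
  print(round(x$d, 4))
  invisible(x)
}

#' Mean within- or between-group distance
#'
#' Arithmetic mean of pairwise matrix entries inside one group (`within`,
#' self-pairs excluded) or across two groups (`between`).
#'
#' @param dm a `distance_matrix` from [distance_matrix()].
#' @param groups named character vector mapping labels to groups; defaults
#'   to the groups stored on `dm`.
#' @param mode `"between"` (default) or `"within"`.
#' @param group1,group2 group labels (`group2` ignored for `"within"`).
#' @return Mean distance (substitutions/site).
#' @export
group_mean_distance <- function(dm, group1, group2 = NULL,
                                mode = c("between", "within"),
                                groups = NULL) {
  mode <- match.arg(mode)
  if (is.null(groups)) groups <- dm$groups
  if (is.null(groups)) stop("no group labels available")
  g <- groups[dm$labels]
  if (mode == "between") {
    if (is.null(group2)) stop("between-mode needs two group labels")
    i <- which(g == group1); j <- which(g == group2)
    if (!length(i) || !length(j)) stop("empty group")
    mean(dm$d[i, j, drop = FALSE])
  } else {
    i <- which(g == group1)
    if (length(i) < 2L)
      stop("within-mode needs at least two members in the group")
    mean(dm$d[i, i][upper.tri(diag(length(i)))])
  }
}
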