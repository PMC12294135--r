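# Distance-based tree construction: Saitou-Nei Neighbor-Joining and UPGMA
# (average-linkage) agglomeration. Trees are returned as ape "phylo"
# objects so the usual plotting/IO ecosystem applies downstream.

as_dist_input <- function(dm) {
  if (inherits(dm, "distance_matrix")) dm$d
  else as.matrix(dm)
}

check_square <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("matrix error: need a square distance matrix")
  if (any(!is.finite(d)))
    stop("matrix error: non-finite distance entries")
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  d
}

# Deterministic pair choice: among pairs minimizing `crit` (within tol),
# pick the one whose sorted (name_i, name_j) is lexicographically smallest.
# Cluster names are the smallest tip label each cluster contains.
pick_pair <- function(crit, names, tol = 1e-12) {
  n <- nrow(crit)
  best <- Inf; pick <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- crit[i, j]
      if (v < best - tol) {
        best <- v; pick <- c(i, j)
      } else if (abs(v - best) <= tol) {
        a <- sort(c(names[i], names[j]))
        b <- sort(c(names[pick[1L]], names[pick[2L]]))
        if (a[1L] < b[1L] || (a[1L] == b[1L] && a[2L] < b[2L]))
          pick <- c(i, j)
      }
    }
  }
  pick
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration by the minimum-Q criterion. Ties are broken
#' deterministically towards the lexicographically smallest pair of cluster
#' labels. Negative branch lengths are clamped to zero; the total clamped
#' deficit is stored in the `clamped_deficit` attribute. The result is the
#' standard unrooted NJ tree, represented with a trifurcating root node
#' (for n = 2, a cherry whose two branches sum to the input distance).
#'
#' @param dm a [distance_matrix()] or plain symmetric matrix with dimnames.
#' @return An ape `phylo` object.
#' @export
nj_build <- function(dm) {
  d <- check_square(as_dist_input(dm))
  n <- nrow(d)
  labels <- rownames(d)
  if (n < 2L) stop("need at least 2 labels")
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  if (n == 2L) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1L], fmt_len(d[1, 2] / 2),
                   labels[2L], fmt_len(d[1, 2] / 2))
    return(finish_tree(nwk, deficit))
  }
  sub <- labels                 # newick fragment per active cluster
  nm <- labels                  # smallest tip label per cluster
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    ij <- pick_pair(q, nm)
    i <- ij[1L]; j <- ij[2L]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt_len(li), sub[j], fmt_len(lj))
    new_nm <- min(nm[i], nm[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], new_nm)
    d <- d2
    sub <- c(sub[keep], new_sub)
    nm <- c(nm[keep], new_nm)
  }
  # terminal trifurcation
  l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1L], fmt_len(l1),
                 sub[2L], fmt_len(l2), sub[3L], fmt_len(l3))
  finish_tree(nwk, deficit)
}

finish_tree <- function(nwk, deficit) {
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with cluster-size weighting; node heights
#' are half the distance between the merged clusters, so the result is
#' rooted and ultrametric. Ties are broken as in [nj_build()].
#'
#' @param dm a [distance_matrix()] or plain symmetric matrix with dimnames.
#' @return A rooted, ultrametric ape `phylo` object.
#' @export
upgma_build <- function(dm) {
  d <- check_square(as_dist_input(dm))
  n <- nrow(d)
  labels <- rownames(d)
  if (n < 2L) stop("need at least 2 labels")
  sub <- labels
  nm <- labels
  size <- rep(1L, n)
  height <- rep(0, n)
  while (nrow(d) > 1L) {
    m <- nrow(d)
    crit <- d
    diag(crit) <- Inf
    ij <- pick_pair(crit, nm)
    i <- ij[1L]; j <- ij[2L]
    h <- d[i, j] / 2
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt_len(h - height[i]),
                       sub[j], fmt_len(h - height[j]))
    new_nm <- min(nm[i], nm[j])
    dk <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(m), c(i, j))
    if (length(keep)) {
      d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                  c(dk[keep], 0))
      rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], new_nm)
      d <- d2
    } else {
      d <- matrix(0, 1, 1, dimnames = list(new_nm, new_nm))
    }
    sub <- c(sub[keep], new_sub)
    nm <- c(nm[keep], new_nm)
    size <- c(size[keep], size[i] + size[j])
    height <- c(height[keep], h)
  }
  tree <- ape::read.tree(text = paste0(sub[1L], ";"))
  attr(tree, "clamped_deficit") <- 0
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' Count of non-trivial bipartitions present in exactly one of the two
#' trees (0 means identical unrooted topology). Delegated to
#' `phangorn::RF.dist()`.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @return Integer symmetric-difference count.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf-set mismatch between trees")
  if (!requireNamespace("phangorn", quietly = TRUE))
    stop("robinson_foulds requires the phangorn package")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

#' Test whether a set of tips forms a clade
#'
#' TRUE when the given tips are exactly the leaves of some edge-defined
#' subtree once the tree is rooted at an outgroup-side node; for unrooted
#' trees this asks whether `tips` versus the rest is a bipartition of the
#' tree (monophyly relative to everything else).
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic_group <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  if (length(tips) <= 1L) return(TRUE)
  if (length(tips) == length(tree$tip.label)) return(TRUE)
  want <- sort(match(tips, tree$tip.label))
  all_tips <- seq_along(tree$tip.label)
  parts <- ape::prop.part(tree)
  any(vapply(parts, function(p) {
    identical(sort(p), want) || identical(sort(setdiff(all_tips, p)), want)
  }, logical(1L)))
}
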