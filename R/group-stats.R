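# Two-group and multi-group comparison machinery shared by the
# morphometric screen and the muscle-quality module.

test_result <- function(method, statistic, df, p, alpha) {
  structure(list(method = method, statistic = statistic, df = df,
                 p = p, alpha = alpha, significant = p < alpha),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %.2f, p = %.4g (%s at alpha = %g)\n",
              x$method, x$statistic, x$df, x$p,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Welch two-sample t-test from summary statistics
#'
#' Computes the Welch statistic and Satterthwaite degrees of freedom from
#' group sizes, means and standard deviations, as needed when only printed
#' summaries (mean +/- SD tables) are available. A pooled-variance Student
#' variant is available via `var_equal = TRUE`.
#'
#' @param n1,m1,s1 size, mean and standard deviation of group 1.
#' @param n2,m2,s2 size, mean and standard deviation of group 2.
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return A `test_result` with fields `statistic`, `df`, `p`, `significant`.
#' @examples
#' welch_t_from_summaries(32, 22.84, 3.84, 40, 17.59, 2.81)
#' @export
welch_t_from_summaries <- function(n1, m1, s1, n2, m2, s2,
                                   alpha = 0.05, var_equal = FALSE) {
  if (n1 < 2 || n2 < 2) stop("sample-size error: need n >= 2 per group")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  if (s1 == 0 && s2 == 0) stop("degenerate error: both group SDs are zero")
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Student t (summaries)"
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch t (summaries)"
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  test_result(method, t, df, p, alpha)
}

#' Welch two-sample t-test from raw samples
#'
#' Identical to [welch_t_from_summaries()] applied to the samples' own
#' sizes, means and standard deviations.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @inheritParams welch_t_from_summaries
#' @return A `test_result`.
#' @export
welch_t_from_samples <- function(x, y, alpha = 0.05, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("sample-size error: need at least 2 observations per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    # identical constant groups: no evidence of difference
    return(test_result("Welch t (samples)", 0, length(x) + length(y) - 2, 1, alpha))
  }
  welch_t_from_summaries(length(x), mean(x), stats::sd(x),
                         length(y), mean(y), stats::sd(y),
                         alpha = alpha, var_equal = var_equal)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA over k groups, delegated to
#' [stats::oneway.test()] with equal variances assumed, returning the F
#' statistic with (k-1, N-k) degrees of freedom.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @param alpha significance level.
#' @return A `test_result`; `df` is the vector `c(df1, df2)`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("sample-size error: each group needs n >= 2")
  if (all(vapply(groups, stats::sd, numeric(1L)) == 0))
    stop("degenerate error: zero within-group variance in every group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  test_result("one-way ANOVA", unname(ft$statistic),
              unname(c(ft$parameter[1L], ft$parameter[2L])),
              ft$p.value, alpha)
}

#' Compact letter display for group comparisons
#'
#' Runs all pairwise Welch tests with Holm correction and assigns
#' superscript letters by greedy insert-and-absorb so that two groups share
#' a letter if and only if they are not significantly different, mirroring
#' the lettering convention of summary tables.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level after Holm correction.
#' @return Named character vector mapping group name to its letters.
#' @export
letter_display <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  p <- apply(pairs, 2L, function(ij) {
    x <- groups[[ij[1L]]]; y <- groups[[ij[2L]]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    welch_t_from_samples(x, y)$p
  })
  p <- stats::p.adjust(p, method = "holm")
  differ <- matrix(FALSE, k, k)
  for (j in seq_len(ncol(pairs))) {
    if (p[j] < alpha) {
      differ[pairs[1L, j], pairs[2L, j]] <- TRUE
      differ[pairs[2L, j], pairs[1L, j]] <- TRUE
    }
  }
  # Insert-and-absorb: start from one class holding every group; each
  # significant pair splits any class containing both; classes that become
  # subsets of another are absorbed. Letters 'a', 'b', ... are assigned with
  # 'a' containing the largest group mean (table convention).
  classes <- list(seq_len(k))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    if (!differ[i1, i2]) next
    hit <- vapply(classes, function(cl) i1 %in% cl && i2 %in% cl, logical(1L))
    if (!any(hit)) next
    new_classes <- classes[!hit]
    for (cl in classes[hit])
      new_classes <- c(new_classes, list(setdiff(cl, i1)), list(setdiff(cl, i2)))
    new_classes <- new_classes[lengths(new_classes) > 0L]
    keep <- vapply(seq_along(new_classes), function(a) {
      !any(vapply(seq_along(new_classes), function(b) {
        a != b && all(new_classes[[a]] %in% new_classes[[b]]) &&
          (length(new_classes[[a]]) < length(new_classes[[b]]) || a > b)
      }, logical(1L)))
    }, logical(1L))
    classes <- new_classes[keep]
  }
  means <- vapply(groups, mean, numeric(1L))
  classes <- classes[order(-vapply(classes, function(cl) max(means[cl]),
                                   numeric(1L)))]
  letters_out <- stats::setNames(rep("", k), nm)
  for (ci in seq_along(classes)) {
    members <- classes[[ci]]
    letters_out[members] <- paste0(letters_out[members], letters[ci])
  }
  letters_out
}

#' Significance stars for a p-value
#'
#' `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of the same length.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}
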