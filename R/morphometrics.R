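# Morphometric core: size standardization by carapace width and Mayr's
# coefficient-of-difference screen for subspecies-level divergence.

# Traits expressed as ratios to carapace width.
RATIO_TRAITS <- c("CL", "CH", "FOMW", "FFLC", "MLC", "PW", "BW", "ST")

#' Standardize traits as ratios to carapace width
#'
#' Each measurement except carapace width (CW) is divided by the same
#' individual's CW, removing most of the body-size signal before group
#' comparison. Original columns are retained; ratio columns are named
#' `<trait>_CW` (e.g. `CL_CW` for CL/CW).
#'
#' @param t a `trait_table` from [read_trait_csv()] or
#'   [simulate_trait_table()].
#' @return A `ratio_table` (data.frame) with one added column per ratio.
#' @export
compute_ratios <- function(t) {
  t <- as_trait_table(as.data.frame(t))
  if (any(t$CW == 0))
    stop("division error: CW = 0 for individual ",
         t$individual_id[which(t$CW == 0)[1L]])
  for (trait in RATIO_TRAITS)
    t[[paste0(trait, "_CW")]] <- t[[trait]] / t$CW
  class(t) <- c("ratio_table", "trait_table", "data.frame")
  t
}

#' Group summaries (n, mean, SD) per variable
#'
#' Sample mean and sample standard deviation (n - 1 denominator) for every
#' numeric variable, per group defined by the grouping keys.
#'
#' @param t a data.frame (trait or ratio table).
#' @param by character vector of grouping columns (default morph and sex).
#' @param variables variables to summarize; defaults to all numeric columns.
#' @return Data.frame with columns `group` keys, `variable`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(t, by = c("morph", "sex"), variables = NULL) {
  t <- as.data.frame(t)
  if (!all(by %in% names(t))) stop("grouping column(s) not found")
  if (is.null(variables))
    variables <- names(t)[vapply(t, is.numeric, logical(1L))]
  key <- interaction(t[by], drop = TRUE, sep = ":")
  if (any(table(key) < 2))
    stop("summary error: every group needs n >= 2")
  out <- do.call(rbind, lapply(levels(key), function(g) {
    rows <- t[key == g, , drop = FALSE]
    do.call(rbind, lapply(variables, function(v) {
      data.frame(rows[1L, by, drop = FALSE], variable = v,
                 n = nrow(rows), mean = mean(rows[[v]]),
                 sd = stats::sd(rows[[v]]), row.names = NULL)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Mayr's coefficient of difference between two groups
#'
#' `CD = |M1 - M2| / (S1 + S2)` where M are group means and S group standard
#' deviations of the same variable. `CD >= 1.28` corresponds to roughly 90%
#' joint non-overlap of the two distributions and is the conventional
#' threshold for subspecies-level divergence.
#'
#' @param m1,s1 mean and SD of group 1.
#' @param m2,s2 mean and SD of group 2.
#' @param variable optional variable name carried into the result.
#' @param threshold subspecies threshold (default 1.28).
#' @return A `cd_result` list with fields `variable`, `cd` and
#'   `exceeds_subspecies_threshold`.
#' @examples
#' coefficient_of_difference(1.40, 0.33, 1.10, 0.25)  # cd = 0.517...
#' @export
coefficient_of_difference <- function(m1, s1, m2, s2, variable = NA_character_,
                                      threshold = 1.28) {
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  if (s1 + s2 == 0) {
    if (m1 != m2)
      stop("degenerate-dispersion error: zero total SD with unequal means")
    cd <- 0
  } else {
    cd <- abs(m1 - m2) / (s1 + s2)
  }
  structure(list(variable = variable, cd = cd,
                 exceeds_subspecies_threshold = cd >= threshold,
                 threshold = threshold),
            class = "cd_result")
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf("CD(%s) = %.2f (%s subspecies threshold %.2f)\n",
              x$variable, x$cd,
              if (x$exceeds_subspecies_threshold) "reaches" else "below",
              x$threshold))
  invisible(x)
}

#' Subspecies screen over morphometric ratios
#'
#' Within one sex stratum holding exactly two morph groups, every ratio is
#' compared between morphs with a two-group Welch test; the coefficient of
#' difference is then computed only for ratios whose difference is
#' significant at `alpha`, following the convention of testing first and
#' applying the subspecies criterion to the discriminating ratios only.
#'
#' @param rt a `ratio_table` from [compute_ratios()], already restricted to
#'   one sex.
#' @param alpha significance level for the screening test (default 0.05).
#' @param threshold subspecies CD threshold (default 1.28).
#' @return A `subspecies_screen` list: `results` (list of `cd_result`),
#'   `screened_out` (ratio names failing the significance screen),
#'   `max_cd`, and `subspecies_level` (TRUE if any CD >= threshold).
#' @export
subspecies_screen <- function(rt, alpha = 0.05, threshold = 1.28) {
  rt <- as.data.frame(rt)
  morphs <- sort(unique(rt$morph))
  if (length(morphs) != 2)
    stop("stratification error: need exactly two morph groups, got ",
         length(morphs))
  ratios <- grep("_CW$", names(rt), value = TRUE)
  ratios <- setdiff(ratios, "CW_CW")
  results <- list()
  screened_out <- character(0)
  for (v in ratios) {
    x <- rt[[v]][rt$morph == morphs[1L]]
    y <- rt[[v]][rt$morph == morphs[2L]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      screened_out <- c(screened_out, v)
      next
    }
    tt <- welch_t_from_samples(x, y, alpha = alpha)
    if (tt$significant) {
      results[[v]] <- coefficient_of_difference(
        mean(x), stats::sd(x), mean(y), stats::sd(y),
        variable = v, threshold = threshold)
    } else {
      screened_out <- c(screened_out, v)
    }
  }
  screen_result(results, screened_out, threshold)
}

#' Subspecies screen from printed group summaries
#'
#' Same decision path as [subspecies_screen()] but starting from published
#' per-group summary statistics (n, mean, SD per ratio) instead of raw
#' individuals, using the summary form of the Welch test.
#'
#' @param summaries data.frame with columns `variable`, `n1`, `m1`, `s1`,
#'   `n2`, `m2`, `s2`: one row per ratio, the two groups side by side.
#' @inheritParams subspecies_screen
#' @return A `subspecies_screen` object.
#' @export
subspecies_screen_from_summaries <- function(summaries, alpha = 0.05,
                                             threshold = 1.28) {
  results <- list()
  screened_out <- character(0)
  for (i in seq_len(nrow(summaries))) {
    r <- summaries[i, ]
    if (r$s1 == 0 && r$s2 == 0) {
      screened_out <- c(screened_out, r$variable)
      next
    }
    tt <- welch_t_from_summaries(r$n1, r$m1, r$s1, r$n2, r$m2, r$s2,
                                 alpha = alpha)
    if (tt$significant) {
      results[[r$variable]] <- coefficient_of_difference(
        r$m1, r$s1, r$m2, r$s2, variable = r$variable, threshold = threshold)
    } else {
      screened_out <- c(screened_out, r$variable)
    }
  }
  screen_result(results, screened_out, threshold)
}

screen_result <- function(results, screened_out, threshold) {
  cds <- vapply(results, function(r) r$cd, numeric(1L))
  structure(list(results = results, screened_out = screened_out,
                 max_cd = if (length(cds)) max(cds) else 0,
                 subspecies_level = any(vapply(
                   results, function(r) r$exceeds_subspecies_threshold,
                   logical(1L))),
                 threshold = threshold),
            class = "subspecies_screen")
}

#' @export
print.subspecies_screen <- function(x, ...) {
  cat(sprintf("Subspecies screen: %d ratio(s) significant, max CD = %.2f\n",
              length(x$results), x$max_cd))
  for (r in x$results) print(r)
  cat(sprintf("Verdict: %s subspecies-level divergence (threshold %.2f)\n",
              if (x$subspecies_level) "" else "no", x$threshold))
  invisible(x)
}
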