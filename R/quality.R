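# Muscle-quality computations: HPLC-style amino-acid quantitation,
# category sums, texture two-group comparison and CIELAB color summaries.

#' Amino-acid content from HPLC quantitation inputs
#'
#' Computes the content `W` of one amino acid from sample mass `m` (g),
#' measured concentration `C` and control concentration `C0` (mg/L), final
#' volume `V` (mL) and dilution factor `N`. The conventional printed
#' formula `W = m * (C - C0) * V * N` is dimensionally inconsistent with
#' its stated mg/kg output, so the default `"mass_normalized"` form
#' computes `(C - C0) * V * N / m` with litres and kilograms made explicit,
#' which is the dimensionally consistent mg/kg quantity; the
#' `"as_printed"` form evaluates the verbatim product for fidelity with
#' legacy reports. Negative `C - C0` is floored at zero with a warning.
#'
#' @param m sample mass in g (> 0).
#' @param C sample concentration in mg/L (>= 0).
#' @param C0 control concentration in mg/L (>= 0).
#' @param V final volume in mL (> 0).
#' @param N dilution factor (>= 1).
#' @param formula `"mass_normalized"` (default) or `"as_printed"`.
#' @return Content `W`: mg/kg under `"mass_normalized"`, the raw product
#'   under `"as_printed"`.
#' @examples
#' aa_content(m = 0.2, C = 10, C0 = 0, V = 20, N = 1)  # 1000 mg/kg
#' @export
aa_content <- function(m, C, C0 = 0, V, N = 1,
                       formula = c("mass_normalized", "as_printed")) {
  formula <- match.arg(formula)
  if (m <= 0) stop("sample mass m must be positive")
  stopifnot(C >= 0, C0 >= 0, V > 0, N >= 1)
  net <- C - C0
  if (net < 0) {
    warning("negative net concentration floored at 0")
    net <- 0
  }
  if (formula == "as_printed") {
    m * net * V * N
  } else {
    # mg/L * L * dilution / kg -> mg/kg
    net * (V / 1000) * N / (m / 1000)
  }
}

#' Amino-acid category sums
#'
#' Sums a complete 16-acid profile into essential (EAA), semi-essential
#' (SEAA), non-essential (NEAA) and delicious (DAA: Phe, Glu, Asp, Ala,
#' Tyr) categories, plus the grand total EAA + SEAA + NEAA.
#'
#' @param profile named numeric vector: content (g/100 g dry matter) per
#'   amino acid, covering all 16 acids of the fixed category map.
#' @return Named numeric vector `c(EAA, SEAA, NEAA, DAA, total)`.
#' @examples
#' tab <- crab_aa_table()
#' aa_category_sums(setNames(tab$red_mean, tab$amino_acid))
#' @export
aa_category_sums <- function(profile) {
  required <- c(AA_EAA, AA_SEAA, AA_NEAA)
  missing <- setdiff(required, names(profile))
  if (length(missing))
    stop("completeness error: missing amino acid(s): ",
         paste(missing, collapse = ", "))
  if (any(profile[required] < 0)) stop("contents must be non-negative")
  c(EAA = sum(profile[AA_EAA]),
    SEAA = sum(profile[AA_SEAA]),
    NEAA = sum(profile[AA_NEAA]),
    DAA = sum(profile[AA_DAA]),
    total = sum(profile[required]))
}

#' Summarize CIELAB point measurements
#'
#' Per-crab means over measurement points, then per-group means of the
#' per-crab means, for each of L*, a*, b*. Per-crab means are the units
#' that feed group comparisons ([welch_t_from_samples()]).
#'
#' @param points data.frame with columns `crab_id`, `group`, `L`, `a`, `b`:
#'   one row per measurement point.
#' @return List with `per_crab` (data.frame: crab_id, group, mean L/a/b)
#'   and `per_group` (data.frame: group, mean L/a/b).
#' @export
color_summary <- function(points) {
  stopifnot(all(c("crab_id", "group", "L", "a", "b") %in% names(points)))
  if (nrow(points) == 0L) stop("empty point list")
  if (any(points$L < 0 | points$L > 100))
    stop("L* must lie in [0, 100]")
  per_crab <- do.call(rbind, lapply(split(points, points$crab_id), function(p) {
    data.frame(crab_id = p$crab_id[1L], group = p$group[1L],
               L = mean(p$L), a = mean(p$a), b = mean(p$b),
               stringsAsFactors = FALSE)
  }))
  rownames(per_crab) <- NULL
  per_group <- do.call(rbind, lapply(split(per_crab, per_crab$group), function(p) {
    data.frame(group = p$group[1L], L = mean(p$L), a = mean(p$a),
               b = mean(p$b), stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  list(per_crab = per_crab, per_group = per_group)
}

#' Two-group texture comparison
#'
#' Welch test per texture parameter between the red and green replicate
#' tables, with significance stars (`**` p < 0.01, `*` p < 0.05, `ns`
#' otherwise).
#'
#' @param red,green data.frames with one numeric column per texture
#'   parameter (same columns, >= 2 rows each).
#' @param alpha significance level.
#' @return Data.frame with `parameter`, `red_mean`, `green_mean`,
#'   `statistic`, `p`, `stars`.
#' @export
texture_compare <- function(red, green, alpha = 0.05) {
  params <- intersect(names(red), names(green))
  params <- params[vapply(red[params], is.numeric, logical(1L))]
  if (!length(params)) stop("no shared numeric texture parameters")
  out <- do.call(rbind, lapply(params, function(pp) {
    tt <- welch_t_from_samples(red[[pp]], green[[pp]], alpha = alpha)
    data.frame(parameter = pp, red_mean = mean(red[[pp]]),
               green_mean = mean(green[[pp]]),
               statistic = tt$statistic, p = tt$p,
               stars = significance_stars(tt$p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Consistency check: gumminess = hardness x cohesiveness
#'
#' Texture-profile convention defines gumminess as the product of hardness
#' and cohesiveness; when all three are supplied this reports the relative
#' deviation per replicate.
#'
#' @param hardness,cohesiveness,gumminess numeric vectors of equal length.
#' @param tol relative tolerance for flagging (default 0.05).
#' @return Data.frame with `expected`, `observed`, `rel_error`, `ok`.
#' @export
gumminess_consistency <- function(hardness, cohesiveness, gumminess,
                                  tol = 0.05) {
  expected <- hardness * cohesiveness
  rel <- abs(gumminess - expected) / pmax(abs(expected), .Machine$double.eps)
  data.frame(expected = expected, observed = gumminess,
             rel_error = rel, ok = rel <= tol)
}
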