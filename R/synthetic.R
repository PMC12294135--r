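# Synthetic-data generators. These emulate the statistical structure of a
# two-morph field sample (group-specific trait distributions, low-diversity
# haplotype sets, divergent outgroups) so the whole pipeline runs and is
# testable without specimens or downloads.

#' Configuration for trait-table simulation
#'
#' Each group (one morph x sex cell) draws carapace width from a normal
#' distribution and every other trait as an independently drawn trait/CW
#' ratio times the individual's CW. This ratio parameterization makes the
#' configured ratio means directly recoverable from the simulated table.
#'
#' @param groups list of group specs, each a list with `morph`, `sex`, `n`
#'   (>= 2), `CW_mean`, `CW_sd` (mm) and named numeric vectors `ratio_mean`,
#'   `ratio_sd` over the traits `CL, CH, FOMW, FFLC, MLC, PW, BW, ST`.
#' @param seed mandatory integer seed.
#' @return A validated `trait_sim_config`.
#' @export
trait_sim_config <- function(groups, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  for (g in groups) {
    stopifnot(g$n >= 2, g$CW_mean > 0, g$CW_sd >= 0)
    stopifnot(setequal(names(g$ratio_mean), RATIO_TRAITS),
              setequal(names(g$ratio_sd), RATIO_TRAITS))
    if (any(g$ratio_mean <= 0)) stop("ratio means must be positive")
    if (any(g$ratio_sd < 0)) stop("ratio sds must be non-negative")
  }
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "trait_sim_config")
}

#' Simulate a morphometric trait table
#'
#' @param cfg a [trait_sim_config()].
#' @param max_redraws bound on redraws for non-positive carapace widths.
#' @return A `trait_table` with ids `<morph>_<sex>_<i>`.
#' @export
simulate_trait_table <- function(cfg, max_redraws = 100L) {
  stopifnot(inherits(cfg, "trait_sim_config"))
  set.seed(cfg$seed)
  rows <- lapply(cfg$groups, function(g) {
    cw <- stats::rnorm(g$n, g$CW_mean, g$CW_sd)
    tries <- 0L
    while (any(cw <= 0)) {
      tries <- tries + 1L
      if (tries > max_redraws)
        stop("simulation error: could not draw positive CW after ",
             max_redraws, " redraws")
      bad <- cw <= 0
      cw[bad] <- stats::rnorm(sum(bad), g$CW_mean, g$CW_sd)
    }
    out <- data.frame(
      individual_id = sprintf("%s_%s_%02d", g$morph, g$sex, seq_len(g$n)),
      sex = g$sex, morph = g$morph, CW = cw, stringsAsFactors = FALSE)
    for (trait in RATIO_TRAITS) {
      ratio <- stats::rnorm(g$n, g$ratio_mean[[trait]], g$ratio_sd[[trait]])
      out[[trait]] <- ratio * cw
    }
    out
  })
  as_trait_table(do.call(rbind, rows))
}

#' Configuration for haplotype-set simulation
#'
#' Describes one aligned marker for several groups of individuals: a single
#' reference sequence drawn from the given base frequencies, plus a short
#' list of variant substitution sites and deletion intervals carried by
#' named individuals. Individual ids are `<group><i>` (e.g. `red1`).
#'
#' @param L alignment length.
#' @param base_freqs named proportions over `A`, `T`, `C`, `G` summing to 1.
#' @param groups named integer vector: individuals per group.
#' @param variant_sites list of `list(position, from, to, carriers)`; the
#'   reference is forced to `from` at `position`, and each carrier id gets
#'   `to` there.
#' @param indels list of `list(start, end, carriers)`: carriers get `-`
#'   over the 1-based inclusive interval.
#' @param seed mandatory integer seed.
#' @param marker marker name for the resulting set.
#' @return A validated `haplo_sim_config`.
#' @export
haplo_sim_config <- function(L, base_freqs, groups, variant_sites = list(),
                             indels = list(), seed, marker = "marker") {
  stopifnot(L >= 1, is.numeric(seed))
  stopifnot(setequal(names(base_freqs), c("A", "T", "C", "G")))
  if (abs(sum(base_freqs) - 1) > 0.01)
    stop("base_freqs must sum to 1")
  base_freqs <- base_freqs / sum(base_freqs)  # absorb rounding in printed %
  ids <- unlist(lapply(names(groups), function(g) paste0(g, seq_len(groups[[g]]))))
  for (v in variant_sites) {
    if (v$position < 1 || v$position > L)
      stop("variant position out of [1, L]")
    if (v$from == v$to)
      stop("config error: to_state equals from_state at position ", v$position)
    if (length(v$carriers) == 0L) stop("carrier set must be non-empty")
    if (!all(v$carriers %in% ids))
      stop("unknown carrier id(s): ",
           paste(setdiff(v$carriers, ids), collapse = ", "))
  }
  for (dd in indels) {
    if (dd$start < 1 || dd$end > L || dd$start > dd$end)
      stop("indel interval out of bounds")
    if (length(dd$carriers) == 0L || !all(dd$carriers %in% ids))
      stop("invalid indel carriers")
  }
  structure(list(L = as.integer(L), base_freqs = base_freqs,
                 groups = groups, ids = ids,
                 variant_sites = variant_sites, indels = indels,
                 seed = as.integer(seed), marker = marker),
            class = "haplo_sim_config")
}

#' Simulate an aligned haplotype set
#'
#' Draws the reference sequence from the configured base frequencies,
#' forces each variant site's `from` state into the reference, then applies
#' the configured substitutions and deletions to their carriers. All
#' columns not named in the config are identical across records, so the
#' number of distinct haplotypes equals the number of distinct carrier
#' signatures plus one (the reference class, when any non-carrier remains).
#'
#' @param cfg a [haplo_sim_config()].
#' @return An [aligned_seq_set()].
#' @export
simulate_haplotype_set <- function(cfg) {
  stopifnot(inherits(cfg, "haplo_sim_config"))
  set.seed(cfg$seed)
  bases <- c("A", "T", "C", "G")
  ref <- sample(bases, cfg$L, replace = TRUE,
                prob = cfg$base_freqs[bases])
  for (v in cfg$variant_sites) ref[v$position] <- v$from
  groups_of <- rep(names(cfg$groups), unlist(cfg$groups))
  seqs <- vapply(cfg$ids, function(id) {
    s <- ref
    for (v in cfg$variant_sites)
      if (id %in% v$carriers) s[v$position] <- v$to
    for (dd in cfg$indels)
      if (id %in% dd$carriers) s[dd$start:dd$end] <- "-"
    paste(s, collapse = "")
  }, character(1L))
  aligned_seq_set(cfg$ids, groups_of, unname(seqs), cfg$marker)
}

# Kimura two-parameter distance as a function of the total difference
# proportion p when transitions outnumber transversions kappa : 1.
k2p_of_p <- function(p, kappa) {
  P <- p * kappa / (kappa + 1)
  Q <- p / (kappa + 1)
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Simulate a divergent outgroup sequence
#'
#' Inverts the Kimura two-parameter formula (for a fixed
#' transition/transversion ratio `kappa`) to find the proportion of sites
#' that must differ to reach the target distance, then substitutes that
#' many uniformly drawn distinct positions, splitting them between
#' transitions and transversions in the `kappa : 1` ratio. The realized
#' K2P distance to the reference is within ~0.01 of the target for
#' alignments of a few hundred sites.
#'
#' @param ref ungapped reference sequence string.
#' @param target_d target K2P distance (substitutions/site, >= 0).
#' @param kappa transition/transversion ratio among introduced differences.
#' @param seed mandatory integer seed.
#' @return The mutated sequence string.
#' @export
simulate_outgroup <- function(ref, target_d, kappa = 2, seed) {
  stopifnot(target_d >= 0, is.numeric(seed))
  if (grepl("[^ACGT]", toupper(ref)))
    stop("reference must be ungapped and unambiguous")
  if (target_d == 0) return(toupper(ref))
  chars <- strsplit(toupper(ref), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  # largest usable p: just inside the K2P saturation boundary
  p_hi <- (kappa + 1) / (2 * kappa + 1) - 1e-4
  d_max <- k2p_of_p(p_hi, kappa)
  if (!is.finite(d_max) || target_d >= d_max)
    stop("domain error: target distance ", target_d,
         " is beyond the K2P-invertible range (< ", round(d_max, 3), ")")
  p <- stats::uniroot(function(x) k2p_of_p(x, kappa) - target_d,
                      c(1e-12, p_hi), tol = 1e-12)$root
  n_sub <- round(p * L)
  if (n_sub == 0L) return(paste(chars, collapse = ""))
  set.seed(seed)
  pos <- sample.int(L, n_sub)
  n_ts <- round(n_sub * kappa / (kappa + 1))
  is_ts <- c(rep(TRUE, n_ts), rep(FALSE, n_sub - n_ts))
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (k in seq_len(n_sub)) {
    b <- chars[pos[k]]
    chars[pos[k]] <- if (is_ts[k]) {
      transition_of[[b]]
    } else {
      tv <- if (b %in% PURINES) PYRIMIDINES else PURINES
      sample(tv, 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate replicate measurements
#'
#' I.i.d. normal draws, deterministic under the seed; used for texture,
#' color and amino-acid replicate emulation.
#'
#' @param mean,sd distribution parameters (`sd >= 0`).
#' @param n number of replicates (>= 1).
#' @param seed mandatory integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_replicates <- function(mean, sd, n, seed) {
  stopifnot(sd >= 0, n >= 1, is.numeric(seed))
  set.seed(seed)
  stats::rnorm(n, mean, sd)
}
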