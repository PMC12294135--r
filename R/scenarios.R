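# Default study scenario: generator configurations and published-style
# summary tables calibrated to a two-morph crab sample (red vs green),
# with a mitochondrial COI-like fragment, a nuclear ITS-1-like fragment
# and divergent congeneric/confamilial outgroups. All outgroup sequences
# produced from these specs are synthetic stand-ins at realistic
# divergences, not database sequences.

#' Published-style morphometric summaries (mean, SD, n) per morph and sex
#'
#' The per-group carapace width and trait/CW ratio summaries used to
#' calibrate [crab_trait_config()]: males n = 32 (red) and 40 (green),
#' females n = 33 (red) and 31 (green).
#'
#' @return Nested list keyed by `"<morph>_<sex>"`, each with `n`, `CW_mean`,
#'   `CW_sd`, `ratio_mean`, `ratio_sd`.
#' @export
crab_group_params <- function() {
  rt <- RATIO_TRAITS  # CL CH FOMW FFLC MLC PW BW ST
  list(
    red_M = list(morph = "red", sex = "M", n = 32,
                 CW_mean = 77.91, CW_sd = 7.50,
                 ratio_mean = stats::setNames(
                   c(0.66, 0.38, 0.50, 0.34, 0.39, 0.29, 1.40, 0.01), rt),
                 ratio_sd = stats::setNames(
                   c(0.01, 0.01, 0.02, 0.02, 0.02, 0.03, 0.33, 0.00), rt)),
    green_M = list(morph = "green", sex = "M", n = 40,
                   CW_mean = 71.27, CW_sd = 8.25,
                   ratio_mean = stats::setNames(
                     c(0.67, 0.40, 0.51, 0.34, 0.39, 0.25, 1.10, 0.01), rt),
                   ratio_sd = stats::setNames(
                     c(0.02, 0.10, 0.02, 0.02, 0.02, 0.02, 0.25, 0.00), rt)),
    red_F = list(morph = "red", sex = "F", n = 33,
                 CW_mean = 68.84, CW_sd = 6.45,
                 ratio_mean = stats::setNames(
                   c(0.67, 0.38, 0.52, 0.28, 0.33, 0.24, 0.95, 0.01), rt),
                 ratio_sd = stats::setNames(
                   c(0.01, 0.01, 0.01, 0.01, 0.02, 0.02, 0.19, 0.00), rt)),
    green_F = list(morph = "green", sex = "F", n = 31,
                   CW_mean = 66.44, CW_sd = 4.39,
                   ratio_mean = stats::setNames(
                     c(0.67, 0.39, 0.52, 0.28, 0.32, 0.23, 0.87, 0.01), rt),
                   ratio_sd = stats::setNames(
                     c(0.01, 0.05, 0.01, 0.01, 0.01, 0.02, 0.11, 0.00), rt)))
}

#' Default trait-simulation configuration
#'
#' @param seed integer seed.
#' @param sexes which sex strata to include (default both).
#' @return A [trait_sim_config()] over the [crab_group_params()] groups.
#' @export
crab_trait_config <- function(seed, sexes = c("M", "F")) {
  groups <- Filter(function(g) g$sex %in% sexes, crab_group_params())
  trait_sim_config(unname(groups), seed = seed)
}

#' Male ratio summaries in two-group (red vs green) layout
#'
#' One row per trait/CW ratio with the red-morph summary as group 1 and the
#' green-morph summary as group 2, ready for
#' [subspecies_screen_from_summaries()].
#'
#' @return Data.frame with columns `variable`, `n1`, `m1`, `s1`, `n2`,
#'   `m2`, `s2`.
#' @export
crab_male_ratio_summaries <- function() {
  p <- crab_group_params()
  red <- p$red_M; green <- p$green_M
  data.frame(
    variable = paste0(RATIO_TRAITS, "_CW"),
    n1 = red$n, m1 = unname(red$ratio_mean), s1 = unname(red$ratio_sd),
    n2 = green$n, m2 = unname(green$ratio_mean), s2 = unname(green$ratio_sd),
    stringsAsFactors = FALSE)
}

#' Default COI-like haplotype scenario
#'
#' 673-site AT-rich mitochondrial fragment (base frequencies 26.3 / 37.1 /
#' 18.4 / 18.1 for A/T/C/G): six red individuals carrying two haplotypes
#' (one individual with a single T-to-C transition) and six green
#' individuals carrying four haplotypes built from two singleton sites and
#' one parsimony-informative site, all T-C transitions.
#'
#' @param seed integer seed.
#' @return A [haplo_sim_config()] for marker `"COI"`.
#' @export
coi_scenario <- function(seed) {
  haplo_sim_config(
    L = 673,
    base_freqs = c(A = 0.263, T = 0.371, C = 0.184, G = 0.181),
    groups = c(red = 6L, green = 6L),
    variant_sites = list(
      list(position = 101L, from = "T", to = "C", carriers = "red6"),
      list(position = 205L, from = "T", to = "C", carriers = "green4"),
      list(position = 310L, from = "T", to = "C", carriers = "green5"),
      list(position = 415L, from = "T", to = "C",
           carriers = c("green5", "green6"))),
    seed = seed, marker = "COI")
}

#' Default ITS-1-like haplotype scenario
#'
#' 360-site nuclear fragment (base frequencies 23.7 / 23.4 / 23.1 / 29.8
#' for A/T/C/G): six red individuals identical except one carrying a 12-bp
#' deletion at positions 205-216, and six green individuals carrying four
#' haplotypes from four variant sites (two A-G changes, two T-G changes).
#'
#' @param seed integer seed.
#' @return A [haplo_sim_config()] for marker `"ITS1"`.
#' @export
its_scenario <- function(seed) {
  haplo_sim_config(
    L = 360,
    base_freqs = c(A = 0.237, T = 0.234, C = 0.231, G = 0.298),
    groups = c(red = 6L, green = 6L),
    variant_sites = list(
      list(position = 50L, from = "A", to = "G", carriers = "green4"),
      list(position = 120L, from = "A", to = "G", carriers = "green5"),
      list(position = 260L, from = "T", to = "G",
           carriers = c("green5", "green6")),
      list(position = 300L, from = "T", to = "G", carriers = "green6")),
    indels = list(list(start = 205L, end = 216L, carriers = "red2")),
    seed = seed, marker = "ITS1")
}

#' Synthetic outgroup divergence targets per marker
#'
#' Target K2P distances from the ingroup reference for each synthetic
#' outgroup: congeners and confamilials at 0.131-0.185 for the COI-like
#' marker and 0.358-0.593 for the faster ITS-1-like marker.
#'
#' @param marker `"COI"` or `"ITS1"`.
#' @return Named numeric vector of target distances.
#' @export
outgroup_targets <- function(marker = c("COI", "ITS1")) {
  marker <- match.arg(marker)
  if (marker == "COI") {
    c(Charybdis_feriatus = 0.131, Charybdis_acuta = 0.140,
      Portunus_pelagicus = 0.158, Portunus_trituberculatus = 0.163,
      Scylla_serrata = 0.170, Callinectes_sapidus = 0.176,
      Eriocheir_sinensis = 0.185)
  } else {
    c(Eriocheir_sinensis = 0.358, Scylla_serrata = 0.430,
      Macrobrachium_nipponense = 0.510, Callinectes_sapidus = 0.593)
  }
}

#' Add synthetic outgroups to a simulated ingroup set
#'
#' Outgroups are generated as a divergence ladder, emulating how related
#' species join a phylogeny sequentially: the closest outgroup is derived
#' from the ingroup reference (the first record's ungapped sequence) by
#' [simulate_outgroup()] at its target distance, and each further outgroup
#' is derived from the previous one by the increment between consecutive
#' targets. This shared ancestry gives the ingroup a long stem edge, so
#' distance-based trees separate the morph complex from the outgroups the
#' way independently star-derived sequences would not.
#'
#' @param s an [aligned_seq_set()] of ingroup records.
#' @param targets named target K2P distances from the ingroup reference,
#'   as from [outgroup_targets()].
#' @param seed integer seed.
#' @param kappa transition/transversion ratio for the outgroup simulator.
#' @return The combined [aligned_seq_set()] with outgroups in group
#'   `"outgroup"`.
#' @export
add_outgroups <- function(s, targets, seed, kappa = 2) {
  L <- nchar(s$seqs[1L])
  targets <- sort(targets)
  current <- gsub("-", "", s$seqs[1L], fixed = TRUE)
  d_prev <- 0
  out_seqs <- character(length(targets))
  for (k in seq_along(targets)) {
    current <- simulate_outgroup(current, targets[[k]] - d_prev,
                                 kappa = kappa, seed = seed + 1000L * k)
    d_prev <- targets[[k]]
    sq <- current
    # pad to the aligned length if the ingroup reference carries gap columns
    if (nchar(sq) < L) sq <- paste0(sq, strrep("-", L - nchar(sq)))
    out_seqs[k] <- sq
  }
  aligned_seq_set(c(s$ids, names(targets)),
                  c(s$groups, rep("outgroup", length(targets))),
                  c(s$seqs, out_seqs), s$marker)
}

# Amino-acid category map (g/100 g dry matter world).
AA_EAA <- c("Leucine", "Isoleucine", "Phenylalanine", "Lysine",
            "Methionine", "Threonine", "Valine")
AA_SEAA <- c("Histidine", "Arginine")
AA_NEAA <- c("Glutamic Acid", "Aspartic Acid", "Glycine", "Alanine",
             "Serine", "Proline", "Tyrosine")
AA_DAA <- c("Phenylalanine", "Glutamic Acid", "Aspartic Acid", "Alanine",
            "Tyrosine")

#' Published-style muscle amino-acid table (g/100 g dry matter)
#'
#' Mean and SD of 16 amino acids per morph (n = 3 each), used as the
#' calibration anchor for category-sum checks and as the default profile
#' source for the pipeline's quality stage.
#'
#' @return Data.frame with `amino_acid`, `red_mean`, `red_sd`,
#'   `green_mean`, `green_sd`.
#' @export
crab_aa_table <- function() {
  data.frame(
    amino_acid = c(AA_EAA, AA_SEAA, AA_NEAA),
    red_mean = c(0.93, 0.53, 0.48, 0.88, 0.18, 0.52, 0.59,
                 0.26, 1.29,
                 1.60, 0.87, 1.08, 0.91, 0.37, 0.74, 0.43),
    red_sd = c(0.23, 0.14, 0.08, 0.29, 0.11, 0.06, 0.15,
               0.06, 0.35,
               0.46, 0.31, 0.24, 0.22, 0.10, 0.07, 0.05),
    green_mean = c(0.89, 0.48, 0.47, 0.85, 0.21, 0.51, 0.54,
                   0.25, 1.04,
                   1.50, 0.84, 1.03, 0.83, 0.36, 0.78, 0.45),
    green_sd = c(0.21, 0.12, 0.09, 0.28, 0.08, 0.05, 0.14,
                 0.07, 0.11,
                 0.50, 0.31, 0.18, 0.21, 0.10, 0.04, 0.13),
    stringsAsFactors = FALSE)
}

#' Default texture-comparison scenario parameters
#'
#' Group means and SDs per texture parameter (n = 3 individuals per morph),
#' chosen so that adhesiveness, springiness and gumminess separate clearly
#' between morphs while hardness, cohesiveness and chewiness do not.
#' Units: hardness and gumminess N, adhesiveness N.mm, springiness mm,
#' chewiness mJ, cohesiveness dimensionless.
#'
#' @return Data.frame with `parameter`, `red_mean`, `red_sd`, `green_mean`,
#'   `green_sd`, `n`.
#' @export
texture_scenario <- function() {
  data.frame(
    parameter = c("hardness", "adhesiveness", "cohesiveness",
                  "springiness", "gumminess", "chewiness"),
    red_mean = c(8.6, 0.50, 0.42, 1.20, 3.00, 9.5),
    red_sd = c(1.2, 0.07, 0.06, 0.10, 0.25, 1.6),
    green_mean = c(9.1, 0.72, 0.45, 1.55, 4.60, 10.4),
    green_sd = c(1.3, 0.06, 0.06, 0.12, 0.30, 1.7),
    n = 3L, stringsAsFactors = FALSE)
}

#' Default carapace color scenario parameters
#'
#' CIELAB group means and SDs (between crabs) per channel, with the red
#' morph darker (lower L*), redder (higher a*) and less yellow (lower b*)
#' than the green morph; 6 crabs per group, 8 measurement points per crab.
#'
#' @return Data.frame with `channel`, `red_mean`, `red_sd`, `green_mean`,
#'   `green_sd`, `point_sd`, `n_crabs`, `n_points`.
#' @export
color_scenario <- function() {
  data.frame(
    channel = c("L", "a", "b"),
    red_mean = c(35, 18, 12), red_sd = c(3, 2.5, 2),
    green_mean = c(48, 6, 20), green_sd = c(3.5, 2, 2.5),
    point_sd = 2, n_crabs = 6L, n_points = 8L,
    stringsAsFactors = FALSE)
}
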