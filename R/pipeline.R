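# End-to-end orchestration: simulate (or load) the two-morph study, run
# the morphometric screen, the sequence statistics, distances and trees
# for each marker, the muscle-quality comparisons, and emit an auditable
# species-call report.

#' Pipeline configuration
#'
#' Collects thresholds, model choices and input sources for [run_full()].
#' With no explicit inputs, the default calibrated synthetic scenario is
#' simulated from the seed.
#'
#' @param seed integer seed driving every simulated input.
#' @param identity_threshold percent identity below which markers argue for
#'   distinct species (default 97).
#' @param cd_threshold coefficient-of-difference threshold for
#'   subspecies-level morphometric divergence (default 1.28).
#' @param alpha significance level for screening tests (default 0.05).
#' @param model distance model, `"k2p"` (default) or `"p"`.
#' @param gap_policy identity gap policy (default `"exclude_gaps"`).
#' @param trait_table optional `trait_table` to use instead of simulating.
#' @param marker_sets optional named list of [aligned_seq_set()] objects
#'   (ingroup + outgroups, outgroups in group `"outgroup"`) to use instead
#'   of simulating.
#' @param out_dir optional directory for artifact files.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(seed, identity_threshold = 97,
                            cd_threshold = 1.28, alpha = 0.05,
                            model = c("k2p", "p"),
                            gap_policy = "exclude_gaps",
                            trait_table = NULL, marker_sets = NULL,
                            out_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stopifnot(identity_threshold > 0, identity_threshold <= 100)
  stopifnot(cd_threshold > 0, alpha > 0, alpha < 1)
  structure(list(seed = as.integer(seed),
                 identity_threshold = identity_threshold,
                 cd_threshold = cd_threshold, alpha = alpha,
                 model = match.arg(model), gap_policy = gap_policy,
                 trait_table = trait_table, marker_sets = marker_sets,
                 out_dir = out_dir),
            class = "pipeline_config")
}

default_marker_sets <- function(seed) {
  coi <- simulate_haplotype_set(coi_scenario(seed + 11L))
  coi <- add_outgroups(coi, outgroup_targets("COI"), seed = seed + 13L)
  its <- simulate_haplotype_set(its_scenario(seed + 17L))
  its <- add_outgroups(its, outgroup_targets("ITS1"), seed = seed + 19L)
  list(COI = coi, ITS1 = its)
}

analyze_marker <- function(s, cfg) {
  ingroup_idx <- which(s$groups != "outgroup")
  ingroup <- seq_subset(s, ingroup_idx)
  morphs <- sort(unique(ingroup$groups))
  identity <- group_identity(ingroup, morphs[1L], morphs[2L],
                             method = "consensus",
                             gap_policy = cfg$gap_policy)
  haps <- lapply(stats::setNames(morphs, morphs), function(g)
    collapse_haplotypes(seq_subset(ingroup, which(ingroup$groups == g))))
  site_counts <- lapply(stats::setNames(morphs, morphs), function(g) {
    sub <- seq_subset(ingroup, which(ingroup$groups == g))
    classify_sites(sub)$counts
  })
  composition <- lapply(stats::setNames(morphs, morphs), function(g)
    base_composition(seq_subset(ingroup, which(ingroup$groups == g))))
  dm <- distance_matrix(s, model = cfg$model)
  between <- group_mean_distance(dm, morphs[1L], morphs[2L], mode = "between")
  g <- dm$groups[dm$labels]
  in_idx <- which(g != "outgroup")
  out_idx <- which(g == "outgroup")
  within_complex <- dm$d[in_idx, in_idx][upper.tri(diag(length(in_idx)))]
  to_outgroup <- as.vector(dm$d[in_idx, out_idx])
  nj <- nj_build(dm)
  up <- upgma_build(dm)
  mono_nj <- is_monophyletic_group(nj, s$ids[ingroup_idx])
  mono_up <- is_monophyletic_group(up, s$ids[ingroup_idx])
  list(marker = s$marker, identity = identity,
       between_distance = between,
       haplotype_counts = vapply(haps, nrow, integer(1L)),
       haplotypes = haps, site_counts = site_counts,
       composition = composition,
       max_within_complex = max(within_complex),
       min_to_outgroup = min(to_outgroup),
       complex_separated = max(within_complex) < min(to_outgroup),
       dm = dm, nj_tree = nj, upgma_tree = up,
       monophyly = c(nj = mono_nj, upgma = mono_up))
}

quality_stage <- function(cfg) {
  seed <- cfg$seed
  aa_tab <- crab_aa_table()
  aa_reps <- lapply(seq_len(nrow(aa_tab)), function(i) {
    list(red = simulate_replicates(aa_tab$red_mean[i], aa_tab$red_sd[i], 3L,
                                   seed + 100L + i),
         green = simulate_replicates(aa_tab$green_mean[i], aa_tab$green_sd[i],
                                     3L, seed + 200L + i))
  })
  aa_p <- vapply(aa_reps, function(r)
    welch_t_from_samples(r$red, r$green)$p, numeric(1L))
  red_profile <- stats::setNames(
    vapply(aa_reps, function(r) mean(r$red), numeric(1L)), aa_tab$amino_acid)
  green_profile <- stats::setNames(
    vapply(aa_reps, function(r) mean(r$green), numeric(1L)), aa_tab$amino_acid)
  tex <- texture_scenario()
  tex_red <- as.data.frame(lapply(stats::setNames(seq_len(nrow(tex)),
                                                  tex$parameter), function(i)
    simulate_replicates(tex$red_mean[i], tex$red_sd[i], tex$n[i],
                        seed + 300L + i)))
  tex_green <- as.data.frame(lapply(stats::setNames(seq_len(nrow(tex)),
                                                    tex$parameter), function(i)
    simulate_replicates(tex$green_mean[i], tex$green_sd[i], tex$n[i],
                        seed + 400L + i)))
  col <- color_scenario()
  pts <- do.call(rbind, lapply(c("red", "green"), function(gp) {
    do.call(rbind, lapply(seq_len(col$n_crabs[1L]), function(ci) {
      chans <- lapply(seq_len(nrow(col)), function(k) {
        mu <- simulate_replicates(
          if (gp == "red") col$red_mean[k] else col$green_mean[k],
          if (gp == "red") col$red_sd[k] else col$green_sd[k],
          1L, seed + 500L + 37L * k + ci + 1000L * (gp == "green"))
        simulate_replicates(mu, col$point_sd[k], col$n_points[1L],
                            seed + 600L + 41L * k + ci + 1000L * (gp == "green"))
      })
      data.frame(crab_id = sprintf("%s_c%d", gp, ci), group = gp,
                 L = pmin(pmax(chans[[1L]], 0), 100),
                 a = chans[[2L]], b = chans[[3L]], stringsAsFactors = FALSE)
    }))
  }))
  colsum <- color_summary(pts)
  color_tests <- do.call(rbind, lapply(c("L", "a", "b"), function(ch) {
    x <- colsum$per_crab[[ch]][colsum$per_crab$group == "red"]
    y <- colsum$per_crab[[ch]][colsum$per_crab$group == "green"]
    tt <- welch_t_from_samples(x, y, alpha = cfg$alpha)
    data.frame(channel = ch, red_mean = mean(x), green_mean = mean(y),
               p = tt$p, stars = significance_stars(tt$p),
               stringsAsFactors = FALSE)
  }))
  list(aa = data.frame(aa_tab, p = aa_p, stars = significance_stars(aa_p)),
       aa_sums = list(red = aa_category_sums(red_profile),
                      green = aa_category_sums(green_profile)),
       texture = texture_compare(tex_red, tex_green, alpha = cfg$alpha),
       color = color_tests)
}

#' Run the full two-morph species assessment
#'
#' Executes every stage — trait simulation (or the supplied table), ratio
#' standardization and the coefficient-of-difference screen per sex
#' stratum, per-marker sequence statistics, distance matrices, NJ and
#' UPGMA trees with outgroups, and the muscle-quality comparisons — and
#' combines the evidence into a species call: `same_species` is TRUE when
#' every marker identity reaches the identity threshold, and
#' `subspecies_level` is TRUE when any screened ratio's CD reaches the CD
#' threshold. When `cfg$out_dir` is set, artifact files (trait CSV,
#' FASTA, PHYLIP matrices, Newick trees, JSON report and a MANIFEST) are
#' written as each stage completes.
#'
#' @param cfg a [pipeline_config()].
#' @return A `species_call_report`.
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$out_dir
  manifest <- character(0)
  emit <- function(writer, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    writer(file.path(out_dir, name))
    manifest <<- c(manifest, name)
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
  }
  stage <- "morphometrics"
  report <- tryCatch({
    traits <- if (is.null(cfg$trait_table))
      simulate_trait_table(crab_trait_config(cfg$seed)) else cfg$trait_table
    emit(function(p) write_trait_csv(traits, p), "traits.csv")
    ratios <- compute_ratios(traits)
    screens <- lapply(stats::setNames(unique(ratios$sex), unique(ratios$sex)),
                      function(sx)
      subspecies_screen(ratios[ratios$sex == sx, ], alpha = cfg$alpha,
                        threshold = cfg$cd_threshold))
    max_cd <- max(vapply(screens, function(s) s$max_cd, numeric(1L)))
    subspecies <- any(vapply(screens, function(s) s$subspecies_level,
                             logical(1L)))

    stage <- "sequence analysis"
    marker_sets <- if (is.null(cfg$marker_sets))
      default_marker_sets(cfg$seed) else cfg$marker_sets
    markers <- lapply(marker_sets, analyze_marker, cfg = cfg)
    for (mk in names(markers)) {
      m <- markers[[mk]]
      emit(function(p) write_fasta_aligned(marker_sets[[mk]], p),
           paste0(tolower(mk), ".fasta"))
      emit(function(p) write_distance_matrix(m$dm, p),
           paste0(tolower(mk), "_dist.phy"))
      emit(function(p) write_newick(m$nj_tree, p),
           paste0(tolower(mk), "_nj.nwk"))
      emit(function(p) write_newick(m$upgma_tree, p),
           paste0(tolower(mk), "_upgma.nwk"))
    }

    stage <- "quality"
    quality <- quality_stage(cfg)

    stage <- "decision"
    identities <- vapply(markers, `[[`, numeric(1L), "identity")
    decision <- species_decision(identities, max_cd,
                                 identity_threshold = cfg$identity_threshold,
                                 cd_threshold = cfg$cd_threshold)
    same_species <- decision$same_species
    subspecies <- decision$subspecies_level
    narrative <- c(
      sprintf("Marker identities: %s (threshold %.0f%%) -> %s",
              paste(sprintf("%s %.2f%%", names(identities), identities),
                    collapse = ", "),
              cfg$identity_threshold,
              if (same_species) "one species" else "distinct species"),
      sprintf("Morphometric screen: max CD %.2f (threshold %.2f) -> %s",
              max_cd, cfg$cd_threshold,
              if (subspecies) "subspecies-level divergence"
              else "no subspecies-level divergence"))
    structure(list(config = cfg, traits = traits, screens = screens,
                   max_cd = max_cd, markers = markers,
                   quality = quality, identities = identities,
                   same_species = same_species,
                   subspecies_level = subspecies,
                   narrative = narrative),
              class = "species_call_report")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  emit(function(p) write_report_json(report, p), "report.json")
  emit(function(p) write_report_tsv(report, p), "report.tsv")
  report
}

#' Combine marker identities and the morphometric screen into a species call
#'
#' `same_species` is TRUE exactly when every marker identity reaches the
#' identity threshold; `subspecies_level` is TRUE exactly when the maximum
#' coefficient of difference reaches the CD threshold. The two axes are
#' reported separately so the evidence stays auditable.
#'
#' @param identities numeric vector of percent identities, one per marker.
#' @param max_cd maximum coefficient of difference over the screened ratios.
#' @param identity_threshold percent identity threshold (default 97).
#' @param cd_threshold CD threshold (default 1.28).
#' @return List with logical fields `same_species` and `subspecies_level`.
#' @export
species_decision <- function(identities, max_cd, identity_threshold = 97,
                             cd_threshold = 1.28) {
  stopifnot(length(identities) >= 1, all(is.finite(identities)),
            is.finite(max_cd))
  list(same_species = all(identities >= identity_threshold),
       subspecies_level = max_cd >= cd_threshold)
}

report_summary_list <- function(x) {
  list(seed = x$config$seed,
       identity_threshold = x$config$identity_threshold,
       cd_threshold = x$config$cd_threshold,
       identities = as.list(x$identities),
       between_distances = lapply(x$markers, `[[`, "between_distance"),
       haplotype_counts = lapply(x$markers, function(m)
         as.list(m$haplotype_counts)),
       max_cd = x$max_cd,
       same_species = x$same_species,
       subspecies_level = x$subspecies_level,
       narrative = x$narrative)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(report_summary_list(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

write_report_tsv <- function(x, path) {
  rows <- data.frame(
    key = c(paste0("identity_", names(x$identities)),
            paste0("between_distance_", names(x$markers)),
            "max_cd", "same_species", "subspecies_level"),
    value = c(sprintf("%.4f", x$identities),
              sprintf("%.6f", vapply(x$markers, `[[`, numeric(1L),
                                     "between_distance")),
              sprintf("%.4f", x$max_cd),
              as.character(x$same_species),
              as.character(x$subspecies_level)),
    stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.species_call_report <- function(x, ...) {
  cat("Two-morph species assessment\n")
  cat("----------------------------\n")
  for (line in x$narrative) cat(line, "\n")
  for (m in x$markers) {
    cat(sprintf(
      "%s: haplotypes %s; between-morph distance %.4f; within-complex max %.4f < outgroup min %.4f: %s; monophyly NJ %s / UPGMA %s\n",
      m$marker,
      paste(sprintf("%s %d", names(m$haplotype_counts), m$haplotype_counts),
            collapse = ", "),
      m$between_distance, m$max_within_complex, m$min_to_outgroup,
      m$complex_separated, m$monophyly[["nj"]], m$monophyly[["upgma"]]))
  }
  cat(sprintf("Verdict: same_species = %s, subspecies_level = %s\n",
              x$same_species, x$subspecies_level))
  invisible(x)
}
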