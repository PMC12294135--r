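# morphotax

Integrated morphometric and molecular species assessment for color morphs
of crustaceans.

When one fishery yields two strikingly different color forms — say a red
and a green morph of a swimming crab — the practical question is whether
they are distinct species, subspecies, or plastic variants of one
population. morphotax implements the standard integrated answer as a
tested, reusable pipeline:

* **Morphometrics.** Traits are standardized as ratios to carapace width,
  compared between morphs per sex stratum (Welch test), and the
  discriminating ratios are screened with Mayr's coefficient of
  difference, CD = |M₁ − M₂| / (S₁ + S₂); CD ≥ 1.28 (≈90% joint
  non-overlap) indicates subspecies-level divergence.
* **Sequences.** For each aligned marker (a mitochondrial COI-like
  barcode and a nuclear ITS-1-like spacer): base composition, percent
  identity between groups, haplotype collapsing, singleton /
  parsimony-informative site classification, p and Kimura two-parameter
  distances (d = −½ ln[(1 − 2P − Q)√(1 − 2Q)]), and Neighbor-Joining plus
  UPGMA trees against outgroup species.
* **Decision.** `same_species` is TRUE when every marker identity reaches
  the identity threshold (default 97%); `subspecies_level` is TRUE when
  any screened CD reaches 1.28. Both evidence lines are reported, not a
  single opaque verdict.
* **Muscle quality.** Amino-acid quantitation and EAA/SEAA/NEAA/DAA
  category sums, texture comparisons with significance stars, and CIELAB
  color summaries — the traits that drive market value even when the
  taxonomic answer is "same species".

A calibrated synthetic-data generator (trait tables, haplotype sets with
configured variant structure, outgroups at target divergences) stands in
for field samples, so the entire pipeline runs and is testable offline.

## Worked example

```r
library(morphotax)

# Mayr's coefficient of difference from printed group summaries
coefficient_of_difference(1.40, 0.33, 1.10, 0.25, variable = "BW_CW")
#> CD(BW_CW) = 0.52 (below subspecies threshold 1.28)

# Full pipeline on the default calibrated synthetic scenario
report <- run_full(pipeline_config(seed = 1))
report
#> Two-morph species assessment
#> ----------------------------
#> Marker identities: COI 100.00%, ITS1 100.00% (threshold 97%) -> one species
#> Morphometric screen: max CD 0.86 (threshold 1.28) -> no subspecies-level divergence
#> COI: haplotypes green 4, red 2; between-morph distance 0.0012; within-complex max 0.0045 < outgroup min 0.1310: TRUE; monophyly NJ TRUE / UPGMA TRUE
#> ITS1: haplotypes green 4, red 2; between-morph distance 0.0023; within-complex max 0.0084 < outgroup min 0.3344: TRUE; monophyly NJ TRUE / UPGMA TRUE
#> Verdict: same_species = TRUE, subspecies_level = FALSE
```

Reading the output: both markers' red/green consensus sequences are
(essentially) identical, far above the 97% identity threshold, so the
morphs are called one species. The red group carries 2 haplotypes and the
green group 4, every within-complex distance is an order of magnitude
below the closest outgroup distance, and the morph complex is
monophyletic in both the NJ and UPGMA trees. The morphometric screen
finds significant ratio differences (as expected for geographically
structured populations) but the largest CD, 0.86, stays below the 1.28
subspecies criterion.

Passing `out_dir =` to `pipeline_config()` additionally writes the trait
CSV, aligned FASTA per marker, PHYLIP distance matrices, Newick trees, a
JSON/TSV report and a MANIFEST; reruns with the same seed are
byte-identical. A thin command-line wrapper with `simulate`, `morpho`,
`seq`, `dist`, `tree` and `run` subcommands is installed at
`inst/cli/morphotax.R`.

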