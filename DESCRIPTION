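Package: morphotax
Title: Integrated Morphometric and Molecular Species Assessment for Color Morphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether two color morphs of a crustacean
    belong to one species by combining morphometric ratio analysis with
    Mayr's coefficient-of-difference subspecies screen, alignment-level
    mitochondrial sequence statistics (base composition, percent identity,
    haplotype collapsing, variable-site classification), evolutionary
    distances (p-distance and Kimura two-parameter), Neighbor-Joining and
    UPGMA tree construction, and muscle-quality summaries (amino-acid
    quantitation, category sums, texture and CIELAB color comparisons).
    Includes a calibrated synthetic-data generator so the full pipeline is
    reproducible without field samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    seqinr,
    jsonlite
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
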