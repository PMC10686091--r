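Package: marshvar
Title: Abundance, Variant, and Diversity-Generating Retroelement Profiling
    for Salt-Marsh Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tidy pipeline for strain-level analysis of sulfur-cycling
    metagenome-assembled genomes (MAGs) from salt-marsh sediments: MAG
    quality screening (completeness minus five times contamination) and
    sulfur-guild classification from marker-gene repertoires, genome
    copies per million reads (GCPM) abundance estimation with
    Bray-Curtis dissimilarities, single-nucleotide variant calling with
    per-gene Shannon entropy and hotspot flagging, detection of
    group-specific genomic regions from coverage breadth, and detection
    plus amino-acid diversity quantification of diversity-generating
    retroelements (DGRs). Includes a seeded synthetic community
    generator that emits every input format with a machine-readable
    truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
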