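Package: pancomp
Title: Base Composition Analysis of Bacterial Core and Accessory Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions bacterial pan-genomes into core, accessory and whole
    coding regions using BLAST-distance complete-linkage gene families,
    computes per-strain base-composition statistics (GC content, GCVAR and
    trinucleotide relative entropy) for each region, and tests region
    differences with taxonomic mixed-effects models, Tukey contrasts and
    phylogenetic generalized least squares with Pagel's lambda. Includes a
    synthetic pan-genome generator with known ground truth so the whole
    pipeline can be exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    nlme,
    lme4,
    lmerTest,
    multcomp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
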