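Package: hortus
Title: Functional and Taxonomic Profiling of Fungus-Garden Style Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the comparative metagenome analysis
    used for insect-associated plant biomass degrading communities: dual-evidence
    carbohydrate-active enzyme (CAZy-style) annotation requiring both a
    family-member hit and a hit to the family's correlated protein domain,
    COG-style functional annotation, top-hit taxonomic binning with
    nucleotide-weighted genus rank tables and GC content summaries, proportion
    profile construction with correlation-based UPGMA clustering across
    metagenomes, and fragment recruitment of reads against concatenated-contig
    pseudogenomes with percent-identity banding. A synthetic community module
    generates reference genomes, diverged strains, planted enzyme families and
    error-bearing reads with full truth tables so every step can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
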