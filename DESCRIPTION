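Package: aptenrich
Title: HT-SELEX Aptamer Enrichment Analysis and Binding Affinity Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput sequencing of SELEX
    (Systematic Evolution of Ligands by EXponential enrichment) experiments.
    Converts per-round FASTQ files into deduplicated random-region count
    tables (primer trimming, length filtering, duplication statistics),
    computes per-round fold enrichment and a composite log-enrichment score
    (compScore) for ranking aptamer candidates, groups enriched sequences by
    greedy sequence-identity clustering, and reports candidates with base
    composition and library coverage statistics. Includes a SELEX round
    simulator with planted high-affinity winners for ground-truth validation,
    and saturation binding isotherm fitting (fluorescence anisotropy and
    affinity probe capillary electrophoresis titrations) to estimate apparent
    dissociation constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
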