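Package: aasd
Title: Genome-Wide Amino Acid Sequence Divergence Atlas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-orthogroup amino acid sequence divergence (AASD)
    across a genome-wide set of single-copy orthogroups. Pairwise distances
    are estimated by maximum likelihood under empirical amino acid
    substitution models (LG, WAG, JTT, Dayhoff, Blosum62, or any PAML-format
    matrix), each orthogroup is summarised by its median pairwise distance,
    and the resulting empirical distribution is partitioned by upper
    quantiles into divergence groups used to flag rapidly evolving genes,
    such as candidate sex-determining genes. Includes alignment trimming and
    occupancy filters, neighbor-joining trees with tip-to-tip (patristic)
    distance validation, and a synthetic orthogroup generator with planted
    fast-evolving genes for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
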