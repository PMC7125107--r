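Package: wgdplacer
Title: Ks-Based Detection, Dating and Phylogenetic Placement of
    Whole-Genome Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds redundancy-corrected synonymous-substitution (Ks) age
    distributions for paralogs (whole paranome and syntenic anchor pairs),
    detects whole-genome-duplication (WGD) peaks by smoothing-spline density
    estimation with bootstrap confidence intervals, corrects ortholog
    divergence peaks for lineage-specific substitution rates via outgroup
    relative-rate tests, estimates species-tree branch lengths in Ks units
    by non-negative least squares, and maps half-Ks peak ages onto the
    phylogeny to classify WGD events as shared or lineage-specific. Includes
    a seeded synthetic-data generator (WGD-derived duplicate pairs, a
    small-scale-duplication background, and rate-heterogeneous ortholog
    samples) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    ape,
    Biostrings,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
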