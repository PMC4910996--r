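Package: aphidweb
Title: Host-Range Indices, Specialist Advantage and Trait Analysis for
    Aphid-Parasitoid Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bipartite aphid-parasitoid rearing webs:
    taxonomy-based host-range indices (host species richness and phylogenetic
    species variability computed on ranked lineages), pairwise relative
    specialist versus generalist host-use scoring stratified by categorical
    host traits, category-size-preserving bootstrap tests for trait-level
    differences, abundance-weighted assemblage specialization, multiple
    correspondence analysis of the host trait matrix with regularized
    iterative imputation of missing categories, hypergeometric v.tests for
    trait-level co-occurrence, and a synthetic web generator with known
    ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
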