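Package: betascale
Title: Multi-Scale Partitioning of Beta Diversity in Hierarchically
    Sampled Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing presence/absence community data sampled
    under a nested spatial design (plots within mountains within mountain
    ranges). Implements the Sorensen-family decomposition of pairwise and
    multiple-site dissimilarity into spatial turnover (Simpson) and
    nestedness-resultant components, subset-resampling distributions of the
    multiple-site measures, additive partitioning of regional richness
    across nested spatial scales with randomization-based significance
    tests, local-versus-regional richness regression, and UPGMA clustering
    of component dissimilarity matrices with Newick export. A seeded
    metacommunity simulator generates plant and host-specific gall
    incidence matrices with a controlled mixture of gradient turnover and
    nested species loss, so every stage of the analysis can be exercised
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
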