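Package: glycoferm
Title: Multi-Donor Fiber Structure-Function Analysis for In Vitro Fecal Fermentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening prebiotic dietary fibers against panels of human
    fecal donor microbiotas. Normalizes glycosidic-linkage profiles to
    monosaccharide composition, clusters fibers into phyloglycomic groups, and
    classifies novel fibers against a fitted grouping. Implements the ecology
    statistics used to score fermentation outcomes from first principles:
    Bray-Curtis, Gower and weighted UniFrac dissimilarities, non-metric
    multidimensional scaling by stress majorization, and distance-based
    PERMANOVA with permutation p-values. Quantifies the determinism of
    donor responses via untreated-normalized ordination displacement vectors
    and mean pairwise cosine similarity, summarizes short-chain fatty acid
    end products (max-scaled heatmap tables, butyrate:propionate ratios,
    donor-penetrance CCDF curves), runs Kruskal-Wallis/Dunn reference
    comparisons with Benjamini-Hochberg correction and random-forest feature
    attribution, and calibrates plate assays (qPCR standard curves, BCECF
    ratiometric pH). A seeded synthetic-data generator emulates the
    multi-donor fermentation design (donor-sparse communities, functionally
    redundant SCFA-producer guilds, tunable glycan-driven vs donor-driven
    response structure) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
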