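Package: fungalsar
Title: Soil Fungal Species-Area Relationships and Countryside-SAR Diversity Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies climate- and land-use-driven change in landscape-scale
    soil fungal diversity. Builds plot-scale species-area relationships (SARs)
    from nested soil-core subsampling with analytic sample-based rarefaction,
    estimates habitat affinities for human-dominated land systems from paired-plot
    diversity ratios, projects pixel-scale richness with the countryside SAR
    S = c(sum h_j A_j)^z, stacks per-species climate-niche distribution models
    thresholded by maximizing sensitivity plus specificity, and classifies
    per-pixel diversity loss/gain and the spatial overlap of climate and
    land-use effects. Includes seeded synthetic-data generators with the
    statistical structure the analysis assumes, so the full pipeline runs and
    is testable without any external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    ranger,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
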