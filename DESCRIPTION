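Package: lisatransect
Title: Local Moran's I Detection of High-Abundance Plant Clusters in
    Transect-Sampled Vegetation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes clusters of high plant abundance in
    quadrat-transect vegetation surveys. Computes local Moran's I (a local
    indicator of spatial association, LISA) on per-quadrat density with
    row-standardized first-order contiguity weights along each transect,
    tests it analytically or by conditional permutation with Bonferroni
    correction, and classifies quadrats into High-High, Low-Low, High-Low,
    Low-High and not-significant classes. Detected High-High clusters are
    then compared with the rest of the sample by growth habit (abundance
    shares, densities with standard errors, density ratios, two-sample
    t-tests) and by rank-abundance tables, and ordinated with Bray-Curtis
    principal coordinate analysis and Hellinger principal component
    analysis. Group structure among cluster quadrats is assessed by
    hierarchical clustering on chord distance with cophenetic model
    selection and multiscale bootstrap support (approximately unbiased
    p-values and bootstrap probabilities). A synthetic-data generator
    reproduces the sampling design (transects of contiguous quadrats,
    sparse multispecies counts, planted high-density runs, transect-level
    lithology effects) with ground truth for power and error-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
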