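Package: ms1stoich
Title: Elemental Stoichiometry of Unidentified LC-MS Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An MS1-only untargeted metabolomics pipeline for elemental
    stoichiometry of soil (and other environmental) extracts analysed by
    negative-mode LC-HRMS. From a feature table (m/z, retention time,
    per-sample intensities) the package enumerates candidate CHNOPS
    molecular formulas under accurate-mass, element-ratio, ring-double-bond
    and isotope-pattern constraints, averages the top-ranked candidates into
    composite formulas, derives C/N, C/P and N/P ratios, and compares
    land-management (or treatment) groups against a reference group with
    Kruskal-Wallis tests, pairwise effect sizes, significant-feature set
    intersections and PLS-DA with VIP scores and k-fold Q2 validation.
    QA/QC gates (blank-based feature retention, internal-standard CV, sample
    mass normalisation) and a seeded synthetic-data generator with known
    ground truth make every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
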