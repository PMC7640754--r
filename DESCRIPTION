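Package: taxideval
Title: Benchmarking Automated Taxonomic Identification Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores ranked taxonomic identifications returned by automated
    identification tools (for example smartphone plant-identification apps)
    against expert reference determinations, using a hierarchical rubric
    (species/genus/family match categories on a 100-point scale), an
    incremental weighted score over the top four suggestions, and a
    replicate-consistency index. Aggregates scores into per-tool and
    per-subset report tables with rankings, accuracy thresholds and error
    rates, and compares tools with the nonparametric suite appropriate for
    such data: Kruskal-Wallis tests with Dunn/Bonferroni post-hoc compact
    letter displays, the (n-1) chi-square test for proportions, and
    Kendall's coefficient of concordance. Includes a seeded synthetic-data
    generator with per-tool multinomial outcome profiles and a
    replicate-dependence parameter, supporting parameter recovery and
    property-based validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), vegan, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
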