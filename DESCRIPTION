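Package: meiomap
Title: Meiotic Crossover Mapping, Interference and Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of meiotic recombination in F2
    populations. Provides a synthetic meiosis generator with interfering
    (Class I, gamma-renewal) and non-interfering (Class II, Poisson)
    crossover pathways whose local rates respond to SNP density and
    heterozygosity-block boundaries; genotyping-by-sequencing style
    marker-table simulation; fluorescent-tagged-line estimators of genetic
    distance from seed and pollen fluorescence classes, including the
    two-interval coefficient-of-coincidence interference statistic; a
    genotype-switch crossover caller with quality, coverage and library-size
    filters; and windowed recombination-landscape summaries with
    SNP-density percentile grouping and differential (delta cM) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
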