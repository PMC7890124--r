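Package: recombscape
Title: Bin-Based Crossover Calling and Recombination Landscapes from
    Low-Coverage F2 Genotyping-by-Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls meiotic crossovers in F2 progenies of a two-parent cross
    from low-coverage genotyping-by-sequencing (GBS) read counts, using
    matched ~1 Mb bin grids over both parental genomes, sliding-window
    smoothing of parent-of-origin read ratios, threshold genotype calls,
    and region-aware double-crossover filtering. Builds population genetic
    maps (cM and cM/Mb), delimits pericentromeric low-recombination
    regions, and compares recombination landscapes between populations
    with chi-square and paired Wilcoxon tests. Includes a synthetic
    F2-meiosis and GBS read-count generator with known crossover truth so
    every pipeline stage can be validated without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
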