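Package: clonescan
Title: Verification of Clonal Reproduction and Ploidy in Hybrid Rice from
    Low-Coverage Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for verifying synthetic
    apomixis in F1 hybrid rice. Forward-simulates parental, F1 and progeny
    genomes under sexual reproduction, apomeiosis (MiMe) and
    apomeiosis-plus-parthenogenesis, together with low-coverage sequencing
    observations at parental SNP markers and flow-cytometry histograms.
    Selects high-confidence parental markers from replicate genotype calls,
    reconstructs genome-wide genotype landscapes with 200 kb sliding
    windows from sparse allele depths, detects crossover breakpoints,
    classifies progeny as clonal versus recombinant and diploid versus
    tetraploid, and summarises percent-diploid per transformation event
    with exact binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
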