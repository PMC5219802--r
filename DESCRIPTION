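Package: paleodup
Title: Detection, Classification and Dating of Duplicate Genes in Plant Genomes
Version: 0.1.0
Authors@R:
    person("paleodup", "developers", email = "paleodup@example.org",
           role = c("aut", "cre"))
Description: A pipeline for studying duplicate-gene retention in plant
    genomes. Detects paralog pairs from all-vs-all protein similarity,
    classifies the duplication mechanism of each pair as whole-genome
    duplication (WGD, via collinear synteny chaining in gene-order space),
    tandem (few intervening genes) or undefined, dates pairs by synonymous
    divergence (Ks) with counting-based codon models (YN00, NG86), reduces
    many-to-many hits to representative pairs, characterises Ks age
    distributions (histograms, goodness of fit against a constant
    birth-death null, SiZer significance maps) and tests paralog groups for
    GO term over-representation. Includes a synthetic-genome simulator with
    known duplication history so that every stage is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
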