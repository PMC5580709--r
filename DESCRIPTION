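Package: bartox
Title: Bar-Seq Screening for Modifiers of Human Gene Toxicity in Yeast
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled barcode-sequencing (Bar-seq)
    screens that identify yeast deletion strains modifying the toxicity of
    heterologously expressed human disease genes. Provides a synthetic-data
    generator emulating the pooled competition experiment (barcoded deletion
    library, exponential competitive growth, multinomial read sampling,
    per-base sequencing error), inline-index FASTQ demultiplexing and
    Hamming-distance barcode counting, divide-by-average count
    normalization, Z-scoring of log abundance ratios with Poisson error
    propagation and corrected Z-score classification of toxicity
    suppressors and enhancers, ortholog mapping of suppressors to human
    genes, construction and export of disease-gene interaction networks,
    and hypergeometric category enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
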