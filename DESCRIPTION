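Package: subgenomics
Title: Subgenome Phasing and Comparative Analysis of Allotetraploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for dissecting allotetraploid genomes into their two
    progenitor subgenomes and characterising their divergent evolution.
    Chromosomes are phased into subgenomes from differentially enriched
    13-mers; genome size is estimated from k-mer depth histograms; syntenic
    blocks and reciprocal-best-hit homoeologous gene pairs are derived from
    tabular homology hits; synonymous and nonsynonymous divergence is
    estimated with the Nei-Gojobori (1986) method and whole-genome
    duplications are dated from Ks-distribution peaks; the allopolyploidy
    window is bounded from the segregation region of transposable-element
    divergence landscapes; homoeolog expression bias and subgenome dominance
    are tested from replicated expression tables; and gene-body CG
    methylation is classified with exact binomial tests, including the
    DmCG/C epimutation rate compared against Ks. A synthetic-data generator
    emulates an allotetraploid with known ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
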