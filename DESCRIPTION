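Package: cladeMotifs
Title: Promoter Motif Conservation Across a Yeast Clade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for characterizing short regulatory motifs in upstream
    promoter fragments across a clade of related yeast species. From a
    differential-expression gene list, per-species genome sequences and
    annotations, and an ortholog table, the package extracts strand-aware
    promoter fragments, scans them for short motifs on both strands with
    start-codon-anchored coordinates, applies a clade-conservation criterion
    (presence in at least a configurable fraction of collected ortholog
    promoters at a similar position relative to the start codon), discovers
    conserved k-mers seeded from a gene cluster, and builds summary tables of
    motif presence, conservation and majority occurrence. A synthetic-data
    generator with planted motifs and known ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cladeMotifs-package.R'
    'cli.R'
    'conservation.R'
    'demo.R'
    'discover.R'
    'errors.R'
    'expression.R'
    'io.R'
    'motif.R'
    'pipeline.R'
    'synthetic.R'
    'utils.R'
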