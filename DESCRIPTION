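Package: ligrkit
Title: RNA-RNA Interactome Inference from Proximity-Ligation Chimeric Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling RNA-RNA interactions from crosslink/proximity-
    ligation sequencing (LIGR-seq style) chimeric reads in bacteria: chimeric
    read classification against a GFF3 annotation (with auto-generated
    unannotated-region features), replicate-merged interaction count matrices,
    exact one-sided hypergeometric enrichment tests with Benjamini-Hochberg
    false discovery rate control, and hybridization-prediction input windows.
    Also implements the accompanying bench kinetics computations: rifampicin
    chase half-life fitting (mono- and biphasic, log10 scale), gel migration
    size estimation and absolute sRNA quantification from standard curves,
    plate-reader promoter activity, and competition-assay fitness testing.
    A synthetic-data generator with planted interactions, a toy exact-match
    split aligner and truth tables make the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
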