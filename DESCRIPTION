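Package: epimsap
Title: Methylation-Sensitive Amplification Polymorphism (MSAP) Analysis of
    Epimutation and Its Intergenerational Inheritance
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for methylation-sensitive amplification polymorphism (MSAP)
    experiments that read CCGG methylation from EcoRI+MspI / EcoRI+HpaII
    digestion band patterns. Implements band-type coding (types I-IV),
    the twelve-transition mutation/epimutation classification model,
    peak-table filtering, locus binning and replicate-consensus scoring,
    methylation-ratio statistics, differentially amplified/methylated locus
    (DAL/DML) tallies, and the partition of changed loci into offspring-shared
    and offspring-private classes used to assess intergenerational inheritance
    of sperm DNA methylation changes. Includes an in-silico simulator of the
    whole assay (genomes, methylomes, isoschizomer digestion, selective
    amplification, noisy capillary-electrophoresis peak tables), bisulfite
    clone calling for cross-validation of MSAP calls, and genomic feature
    annotation of changed loci.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
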