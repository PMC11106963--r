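Package: diurnalTE
Title: Diurnal Rhythms in Translation Efficiency from Ribosome Profiling
    Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of diurnal post-transcriptional and translational
    regulation from matched ribosome-profiling (RPF), exonic mRNA and
    intronic pre-mRNA count time courses, modelled on the regulation of
    iron-responsive-element (IRE) containing transcripts by the iron
    regulatory proteins IRP1/IRP2 in mouse liver. Provides upper-quartile
    normalization, RPKM and translation-efficiency (TE) computation,
    24-h cosinor rhythm fitting with rhythm-layer classification
    (transcriptional, post-transcriptional, translational), timepoint by
    genotype knockout contrasts with derepression-pattern calls, western
    blot quantification, z-scored TE-profile k-means and hierarchical
    clustering, and a negative-binomial synthetic-data generator that
    encodes the regulatory model (clock- versus feeding-driven rhythms,
    knockout effects, feeding-regime modulation) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: RiboSeq, Transcriptomics, Normalization, Clustering,
    TimeCourse, GeneRegulation
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'clustering.R'
    'differential.R'
    'diurnalTE-package.R'
    'io.R'
    'pipeline.R'
    'quantify.R'
    'rhythm.R'
    'simulate.R'
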