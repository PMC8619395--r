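Package: ssrsurvey
Title: Genome-Wide Survey of Microsatellites and Compound Microsatellites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines perfect microsatellites (SSRs, motif length 1-6 bp) from
    nucleotide assemblies under per-motif-length minimum repeat thresholds,
    chains adjacent loci into compound microsatellites (CSSRs) under a
    maximum-interruption (dmax) rule, standardizes motifs under cyclic
    rotation and reverse complementation, classifies loci as coding or
    non-coding from GFF3 CDS features, and computes the per-genome and
    cross-genome statistics used in comparative repeat surveys: relative
    abundance and density, compound percentage, panel mean complexity, the
    Z index of compound-microsatellite representation, motif relative
    abundance matrices and Pearson correlations. A seeded synthetic-genome
    generator with planted repeats provides ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
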