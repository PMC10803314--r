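Package: picmiscan
Title: Detection and Characterization of PICMI Phage Satellites in Bacterial Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects PICMI (phage-inducible chromosomal minimalist island)
    satellite loci in annotated bacterial genomes using a gene co-localization
    model (integrase, alpA, primase, fis) with explicit exclusion filters,
    extracts element boundaries from flanking direct repeats, scans large
    non-coding regions for small open reading frames, clusters elements into
    subfamilies by global pairwise nucleotide identity, builds gene families by
    reciprocal best hit, types the gene neighboring the integrase (iolg/icg),
    and quantifies satellite hitchhiking in phage particle sequencing data:
    coverage-normalized hitchhiker fraction, headful concatemer copy number,
    and a chi-square test for random concatemer extremities. A seeded
    synthetic-data generator plants elements, decoys and read sets with full
    truth bookkeeping for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SequenceMatching, Annotation, MobileElements
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'genome-io.R'
    'detect.R'
    'simulate.R'
    'packaging.R'
    'compare.R'
    'cli.R'
    'picmiscan-package.R'
    'utils.R'
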