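Package: spliceretain
Title: Intron Retention Quantification from Splice-Junction Read Classes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intron retention from spliced RNA-seq alignments by
    classifying reads at each annotated intron into five junction classes
    (exon-intron, intron-exon, canonical splicing, and alternative 5'/3'
    splice-site reads), computing per-intron intron retention scores (IRS),
    proportions of canonical splicing (PCS), and replicate-based two-sample
    Z-scores between conditions. Provides splice-site sequence
    characterization (information-content logos, Jensen-Shannon difference
    logos, positional Fisher exact enrichment, grouping of introns by the
    fourth intron nucleotide and by the 5'-exon terminal triplet),
    splicing-adjusted gene counts for downstream differential expression,
    and a synthetic-data generator producing genomes, annotations, junction
    counts, and spliced SAM reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
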