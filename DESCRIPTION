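Package: intronsig
Title: Intronic Probe-Set Signatures of Unspliced Pre-mRNA in Expression Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and interpreting unspliced pre-mRNA signal in
    expression microarray data. Re-annotates probe sets by exact 25-mer matching
    against transcript and genomic gene-span sequences (mRNA, intronic, repeat,
    ambiguous, unmapped), filters and tests paired differential expression,
    measures enrichment of intronic probe sets over the array background with a
    continuity-corrected chi-square test, evaluates probe-set signatures by
    correlation-based hierarchical clustering against a randomization null, and
    quantifies spliced versus unspliced transcript ratios from qRT-PCR Ct values
    by the 2^-ddCt method, including a protein-abundance prediction that corrects
    total mRNA for its untranslatable unspliced fraction. A synthetic-data
    generator produces gene models, genomes, probe sets, expression matrices and
    Ct tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
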