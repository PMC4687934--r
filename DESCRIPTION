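Package: readthroughr
Title: Genome-Wide Transcription Readthrough Analysis for Yeast Tiling Arrays and CRAC Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and characterizes transcription termination readthrough in
    budding yeast from strand-specific tiling-array probe intensities and
    CRAC/CLIP-style mapped reads. Implements a windowed readthrough score
    (median log2 probe intensity downstream of the 3' end minus the transcript
    body median), mutant-vs-wild-type readthrough ratios tested against a
    replicate-derived empirical null with Benjamini-Hochberg FDR control,
    stringent expression and inclusion filters, CRAC read-class assignment,
    non-templated oligo(A) tail detection, metagene and Pol II 3'-end profiles,
    snoRNA flank readthrough ratios, 6-mer motif enrichment between readthrough
    quartiles near polyadenylation sites, and convergent/tandem transcriptional
    interference classification of down-regulated genes. Includes a synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rsamtools,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
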