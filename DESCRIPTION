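Package: foottrack
Title: Transcription Factor Footprinting from Cytosine-Deaminase Conversion Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of double-stranded-DNA cytosine deaminase footprinting
    experiments, in which accessible cytosines are converted to uracil (read
    out as C-to-T on the deaminated strand) while nucleosomes and bound
    transcription factors protect their DNA. Provides strand-aware extraction
    of per-cytosine conversion tracks from alignments, sequence-context bias
    correction fitted on naked-DNA controls, footprint occupancy scores (FOS)
    and TF-level occupancy scores (TFOS) at known binding sites, de novo
    footprint detection by motif scoring against positional nulls or by
    binomial depletion tests followed by motif scanning, differential TF
    binding between conditions, single-molecule bound/unbound classification
    with co-occupancy statistics, per-cell tracks with window smoothing, and a
    generative simulator of converted reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    limma,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
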