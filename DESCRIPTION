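Package: tagtss
Title: Transcription Start Site Detection and Classification from
    Bacterial tagRNA-Seq 5'-End Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of bacterial transcription start sites
    (TSSs) from stranded 5'-triphosphate-tagged read-end tracks, using a
    sliding-window peak caller with library-size-normalized thresholds and
    coverage-weighted positions. Detected TSSs are classified into primary,
    secondary, internal, antisense, and orphan classes relative to coding
    sequences, with 5'UTR and leaderless-mRNA analysis, CDS re-annotation
    support, orphan-TSS triage into small-RNA candidates, per-TSS
    differential expression, positional profiles, and Fisher-exact
    functional-class enrichment with Benjamini-Hochberg correction. Includes
    a synthetic-data generator with a planted truth set for validating the
    full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
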