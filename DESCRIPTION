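Package: antisensr
Title: Antisense Transcription Detection in Strand-Specific Metatranscriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and profiles antisense transcription in strand-specific
    (meta)transcriptomic data. Assigns aligned reads to annotated genes as
    sense or antisense, calls per-gene antisense transcription with a
    one-tailed binomial test corrected for the library's strandedness
    artifact rate, summarises antisense transcription per species, tests COG
    functional enrichment among antisense-transcribed genes (binomial and
    one-tailed Fisher's exact tests with Benjamini-Hochberg FDR), and
    analyses cross-individual dynamics (gene sharing, profile correlation,
    expression versus strand dominance). Includes a synthetic multi-species
    community generator with known ground truth for validation and power
    analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    withr,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
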