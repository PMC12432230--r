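Package: lineprimer
Title: Subfamily-Selective PCR Primer Design for Repeat Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design and in-silico validation of PCR primers that preferentially
    amplify individual subfamilies within highly homologous repeat lineages such
    as the human LINE1 L1PA series. Aligns subfamily consensus sequences, finds
    subfamily-discriminating bases, enumerates candidate amplicon regions whose
    primer footprints cover discriminating bases at both ends, designs primer
    pairs under GC and melting-temperature constraints, predicts amplicons by
    mismatch-tolerant 3'-anchored in-silico PCR, and scores predicted amplicons
    and sequenced fragment sets against repeat annotation (per-subfamily
    selectivity reports, amplified-locus calling, annotation-track algebra, and
    per-subfamily FPKM summaries). Includes a seeded simulator of repeat
    lineages and genomes with planted diverged copies so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    GenomeInfoDb,
    ggplot2,
    IRanges,
    S4Vectors,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
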