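Package: consensusvc
Title: Multi-Caller Consensus for Somatic Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combines somatic variant calls from multiple variant callers by
    k-of-n minimum-intersection voting. Normalizes heterogeneous caller VCFs
    (allele trimming, left-alignment, multi-allelic and MNV decomposition),
    extracts allele depth and variant allele frequency across caller FORMAT
    dialects, applies low-stringency retention filters and germline
    VAF-window noise partitioning for amplicon panels, and benchmarks every
    caller subset at every intersection threshold against a truth set with
    precision, sensitivity and F1. Ships a synthetic multi-caller dataset
    generator with exact bookkeeping for end-to-end validation, and a
    command-line interface (combine, evaluate, sweep, noise, simulate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils
Suggests:
    Biostrings,
    VariantAnnotation,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
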