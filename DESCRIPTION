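Package: snvpure
Title: Heuristic Somatic Point-Mutation Calling for Low-Purity Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint tumor/normal somatic single-nucleotide-variant calling
    built for samples with low tumor cellularity. Reads are screened with a
    configurable filter expression language, stacked into stranded per-position
    allele pileups with novel-read-start tracking, genotyped with
    coverage-banded minimum-evidence rules, jointly classified as germline or
    somatic by a rule table, and annotated with post-processing flags that
    assign three confidence tiers. Includes a synthetic tumor/normal read
    generator with planted truth, a purity-mixture benchmark harness, amplicon
    and cross-platform verification rules, and VCF/tab-delimited output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
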