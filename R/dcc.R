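# Tab-delimited somatic-mutation export shaped after the ICGC DCC
# simple-somatic-mutation open tier (column names versioned here; no
# particular DCC release is targeted). Somatic calls only.

.dcc_cols <- c(
  "chromosome", "chromosome_start", "chromosome_end", "mutation_type",
  "reference_genome_allele", "mutated_to_allele", "classification",
  "confidence", "filter", "tumor_depth", "normal_depth", "mutant_reads",
  "novel_starts"
)

#' Write somatic calls in DCC-style tab-delimited format
#'
#' One row per somatic call; germline calls are excluded. Columns follow
#' the ICGC simple-somatic-mutation open-tier layout.
#'
#' @param calls Annotated calls.
#' @param path Output path.
#' @return The written tibble, invisibly.
#' @export
write_dcc <- function(calls, path) {
  som <- calls[calls$classification == "Somatic", , drop = FALSE]
  out <- tibble(
    chromosome = som$chrom,
    chromosome_start = som$pos,
    chromosome_end = som$pos,
    mutation_type = "single base substitution",
    reference_genome_allele = som$ref,
    mutated_to_allele = som$mutant_allele,
    classification = som$classification,
    confidence = som$confidence,
    filter = som$filter,
    tumor_depth = som$tumor_cov,
    normal_depth = som$normal_cov,
    mutant_reads = som$mutant_reads,
    novel_starts = som$novel_starts
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' @rdname write_dcc
#' @export
read_dcc <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chromosome = "c", chromosome_start = "i", chromosome_end = "i",
    mutation_type = "c", reference_genome_allele = "c",
    mutated_to_allele = "c", classification = "c", confidence = "c",
    filter = "c", tumor_depth = "i", normal_depth = "i",
    mutant_reads = "i", novel_starts = "i"
  ), progress = FALSE)
}
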