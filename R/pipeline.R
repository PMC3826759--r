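#' Call somatic and germline variants from a tumor/normal pair
#'
#' The full joint-calling pipeline: build filtered pileups for tumor and
#' normal (plus the unfiltered non-duplicate normal pileup used by the
#' MIUN check), trigger candidate positions wherever a non-reference
#' allele meets the minimum-evidence rules in either sample, genotype both
#' samples, classify each position as germline or somatic with the rule
#' table, and attach post-processing flags and confidence tiers.
#'
#' @param tumor_reads,normal_reads Reads tables ([reads_tbl()],
#'   [read_reads_tsv()], [read_alignments()]).
#' @param reference Named character vector of chromosome sequences
#'   ([read_reference()]).
#' @param filter A `filter_spec`, filter expression string, platform name
#'   (`"solid"`/`"illumina"` selects the preset), or `NULL` for
#'   non-duplicate-only filtering.
#' @param platform Sequencing platform, used for the strand-bias check and
#'   as the default filter preset.
#' @param rules [evidence_rules()].
#' @param thresholds [annotation_thresholds()].
#' @param germline_db Optional germline database tibble.
#' @param region Optional `list(chrom =, start =, end =)` restriction.
#' @return A tibble of annotated calls (see [annotate_calls()]), sorted by
#'   chromosome and position, carrying the normal and tumor genotypes,
#'   classification, flags, `filter` string and confidence tier.
#' @examples
#' sim <- simulate_pair(sim_params(purity = 0.8, n_somatic = 5,
#'                                 n_germline_het = 5, n_germline_hom = 2,
#'                                 n_background = 5, seed = 1))
#' calls <- call_somatic(sim$tumor, sim$normal, sim$reference)
#' table(calls$classification, calls$confidence)
#' @export
call_somatic <- function(tumor_reads, normal_reads, reference,
                         filter = NULL,
                         platform = c("solid", "illumina"),
                         rules = evidence_rules(),
                         thresholds = annotation_thresholds(),
                         germline_db = NULL, region = NULL) {
  platform <- match.arg(platform)
  if (is.null(filter)) {
    filter <- filter_preset(platform)
  } else if (is.character(filter) && length(filter) == 1L &&
             filter %in% c("solid", "illumina")) {
    filter <- filter_preset(filter)
  }

  tum_pile <- build_pileup(tumor_reads, reference, region, filter)
  nrm_pile <- build_pileup(normal_reads, reference, region, filter)
  nrm_unf <- build_pileup(normal_reads, reference, region, filter = NULL)

  # candidate positions: a non-reference allele meeting the evidence rules
  # in either sample
  candidates <- bind_rows(tum_pile, nrm_pile)
  if (nrow(candidates) == 0L) return(.empty_calls())
  ev <- .evidence_vec(candidates$n_reads, candidates$n_fwd, candidates$n_rev,
                      candidates$qual_sum, candidates$coverage,
                      candidates$qual_total, rules)
  candidates <- candidates[ev$pass & candidates$allele != candidates$ref,
                           c("chrom", "pos")] |> distinct()
  if (nrow(candidates) == 0L) return(.empty_calls())

  tum_gt <- call_genotypes(
    dplyr::semi_join(tum_pile, candidates, by = c("chrom", "pos")), rules)
  nrm_gt <- call_genotypes(
    dplyr::semi_join(nrm_pile, candidates, by = c("chrom", "pos")), rules)

  joint <- classify_somatic(nrm_gt, tum_gt)
  if (nrow(joint) == 0L) return(.empty_calls())

  annotate_calls(joint, tum_pile, nrm_pile, nrm_unf,
                 germline_db = germline_db, platform = platform,
                 thresholds = thresholds) |>
    arrange(chrom, pos)
}

.empty_calls <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(),
    normal_gt = character(), tumor_gt = character(),
    classification = character(), mutant_allele = character(),
    second_mutant_allele = character(), note = character(),
    variant_allele = character(), mutant_reads = integer(),
    mutant_fwd = integer(), mutant_rev = integer(),
    novel_starts = integer(), tumor_cov = integer(),
    normal_cov = integer(), normal_variant_fwd = integer(),
    normal_variant_rev = integer(), normal_variant_reads = integer(),
    flags = list(), filter = character(), confidence = character()
  )
}
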