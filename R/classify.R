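# Joint germline/somatic classification.
#
# With N = set of normal alleles and T = set of tumor alleles, the rule
# table reduces to:
#
#   - tumor introduces no allele absent from the normal  -> Germline
#     (covers identical genotypes and het -> hom allele loss; the latter
#      is noted as possible LOH)
#   - hom -> het where the single new tumor allele IS the reference base
#     -> Germline, noted as possible LOH (the normal was homozygous for a
#     variant; the tumor regained reference, typically by losing the
#     variant haplotype)
#   - any other new tumor allele -> Somatic, with the mutant allele the
#     tumor allele absent from the normal genotype
#
# A somatic mutant allele that equals the reference (e.g. hom variant ->
# hom reference) is legal here and is flagged MER downstream.

#' Classify joint tumor/normal genotypes
#'
#' Applies the germline/somatic rule table to paired genotype calls.
#' Inputs are the tibbles returned by [call_genotypes()] for the normal
#' and tumor samples; positions present in both are classified.
#'
#' @param normal_gt,tumor_gt Genotype tibbles ([call_genotypes()]). For a
#'   single position these can also be one-row tibbles built by hand.
#' @return A tibble of joint calls: `chrom`, `pos`, `ref`, `normal_gt`,
#'   `tumor_gt`, `classification` (`"Germline"`/`"Somatic"`),
#'   `mutant_allele` (`NA` for germline), `second_mutant_allele` (only when
#'   a het-to-het change introduces two novel alleles), and `note`
#'   (`"possible-LOH"` where the allele pattern suggests loss of
#'   heterozygosity). Positions where either sample is a no-call are
#'   dropped with a message.
#' @examples
#' nrm <- call_genotypes(pileup_column(ref = "A", allele = "A", n_fwd = 30))
#' tum <- call_genotypes(pileup_column(ref = "A", allele = c("A", "G"),
#'                                     n_fwd = c(20, 10)))
#' classify_somatic(nrm, tum)
#' @export
classify_somatic <- function(normal_gt, tumor_gt) {
  joint <- inner_join(
    normal_gt |>
      select(chrom, pos, ref, n_a1 = allele1, n_a2 = allele2,
             n_zyg = zygosity, normal_gt = gt),
    tumor_gt |>
      select(chrom, pos, ref, t_a1 = allele1, t_a2 = allele2,
             t_zyg = zygosity, tumor_gt = gt),
    by = c("chrom", "pos", "ref")
  )
  nocall <- is.na(joint$n_zyg) | is.na(joint$t_zyg)
  if (any(nocall)) {
    message(sum(nocall), " position(s) skipped: no-call in one sample")
    joint <- joint[!nocall, , drop = FALSE]
  }
  if (nrow(joint) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  normal_gt = character(), tumor_gt = character(),
                  classification = character(), mutant_allele = character(),
                  second_mutant_allele = character(), note = character()))
  }

  res <- pmap(
    list(joint$ref, joint$n_a1, joint$n_a2, joint$n_zyg,
         joint$t_a1, joint$t_a2, joint$t_zyg),
    .classify_one
  ) |> list_rbind()

  tibble(
    chrom = joint$chrom, pos = joint$pos, ref = joint$ref,
    normal_gt = joint$normal_gt, tumor_gt = joint$tumor_gt,
    classification = res$classification,
    mutant_allele = res$mutant_allele,
    second_mutant_allele = res$second_mutant_allele,
    note = res$note
  )
}

.classify_one <- function(ref, n1, n2, n_zyg, t1, t2, t_zyg) {
  n_set <- unique(.gt_alleles(n1, n2))
  t_alleles <- .gt_alleles(t1, t2)
  t_set <- unique(t_alleles)
  novel <- setdiff(t_set, n_set)

  out <- function(classification, mutant = NA_character_,
                  second = NA_character_, note = NA_character_) {
    tibble(classification = classification, mutant_allele = mutant,
           second_mutant_allele = second, note = note)
  }

  if (length(novel) == 0L) {
    # tumor adds nothing; het -> hom allele loss hints at LOH
    note <- if (n_zyg == "het" && t_zyg == "hom") "possible-LOH"
            else NA_character_
    return(out("Germline", note = note))
  }
  if (n_zyg == "hom" && t_zyg == "het" && length(novel) == 1L &&
      novel == ref) {
    # variant-homozygous normal gains the reference allele in tumor
    return(out("Germline", note = "possible-LOH"))
  }
  # somatic: report the novel allele; with two novel alleles the caller
  # ordered tumor alleles by evidence, so keep that order and log the other
  novel_ordered <- t_alleles[t_alleles %in% novel]
  novel_ordered <- novel_ordered[!duplicated(novel_ordered)]
  # prefer a non-reference novel allele as the reported mutant
  if (length(novel_ordered) > 1L && novel_ordered[1] == ref) {
    novel_ordered <- c(novel_ordered[-1], novel_ordered[1])
  }
  out("Somatic",
      mutant = novel_ordered[1],
      second = if (length(novel_ordered) > 1L) novel_ordered[2]
               else NA_character_)
}
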