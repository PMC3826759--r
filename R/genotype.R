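# Minimum-evidence genotype rules.
#
# An allele is "supported" at a position when both a coverage-banded read
# count requirement and a base-quality-fraction requirement hold:
#
#   coverage <= 20 : >= 3 reads of the allele
#   20 < cov <= 50 : >= 4 reads
#   coverage >  50 : >= 5% of reads, or >= 2.5% when the allele is seen on
#                    both strands; an absolute floor of 3 reads always
#                    applies (the global trigger)
#
#   quality fraction (allele qual sum / position qual sum) >= 10%, relaxed
#   to >= 5% when the allele is on both strands AND coverage > 50.
#
# The two most common alleles are then examined: if both are supported the
# position is heterozygous, otherwise homozygous for the single supported
# allele.

#' Evidence-rule thresholds
#'
#' Bundles every tunable threshold of the minimum-evidence check. Defaults
#' implement the standard calling mode; override individual values (e.g.
#' through the `[thresholds]` section of a run configuration) to tighten
#' calling for high-purity samples.
#'
#' @param min_reads_low Minimum allele reads at coverage `<= low_band_max`.
#' @param min_reads_mid Minimum allele reads in the middle band.
#' @param low_band_max,mid_band_max Band edges; "over 20x" and "above 50x"
#'   are strict, so coverage 20 and 50 still use the lower band's rule.
#' @param min_frac_single Minimum allele read fraction above `mid_band_max`
#'   when all allele reads sit on one strand.
#' @param min_frac_both The relaxed fraction when both strands carry the
#'   allele.
#' @param min_reads_floor Absolute read floor applied in the fraction band.
#' @param min_qual_frac Minimum allele share of the position's summed base
#'   quality.
#' @param min_qual_frac_both The relaxed quality share (both strands and
#'   coverage above `mid_band_max` only).
#' @return A list of class `evidence_rules`.
#' @export
evidence_rules <- function(min_reads_low = 3L, min_reads_mid = 4L,
                           low_band_max = 20L, mid_band_max = 50L,
                           min_frac_single = 0.05, min_frac_both = 0.025,
                           min_reads_floor = 3L,
                           min_qual_frac = 0.10, min_qual_frac_both = 0.05) {
  rules <- list(
    min_reads_low = as.integer(min_reads_low),
    min_reads_mid = as.integer(min_reads_mid),
    low_band_max = as.integer(low_band_max),
    mid_band_max = as.integer(mid_band_max),
    min_frac_single = min_frac_single,
    min_frac_both = min_frac_both,
    min_reads_floor = as.integer(min_reads_floor),
    min_qual_frac = min_qual_frac,
    min_qual_frac_both = min_qual_frac_both
  )
  stopifnot(rules$min_reads_low >= 1L, rules$min_reads_mid >= 1L,
            rules$min_frac_single > 0, rules$min_frac_single < 1,
            rules$min_frac_both > 0, rules$min_frac_both < 1,
            rules$min_qual_frac > 0, rules$min_qual_frac < 1)
  structure(rules, class = "evidence_rules")
}

# vectorized core shared by evidence_check() and call_genotypes()
.evidence_vec <- function(n_reads, n_fwd, n_rev, qual_sum, coverage,
                          qual_total, rules) {
  both <- n_fwd > 0L & n_rev > 0L
  frac <- ifelse(coverage > 0L, n_reads / coverage, 0)
  qfrac <- ifelse(qual_total > 0L, qual_sum / qual_total, 0)

  band <- cut(coverage, c(-Inf, rules$low_band_max, rules$mid_band_max, Inf),
              labels = c("low", "mid", "high"))

  count_ok <- ifelse(
    band == "low", n_reads >= rules$min_reads_low,
    ifelse(band == "mid", n_reads >= rules$min_reads_mid,
           n_reads >= rules$min_reads_floor &
             frac >= ifelse(both, rules$min_frac_both, rules$min_frac_single))
  )
  qual_needed <- ifelse(both & band == "high",
                        rules$min_qual_frac_both, rules$min_qual_frac)
  qual_ok <- qfrac >= qual_needed

  reason <- dplyr::case_when(
    n_reads == 0L ~ "no reads of allele",
    !count_ok & band == "low" ~
      sprintf("fewer than %d reads at coverage <= %d",
              rules$min_reads_low, rules$low_band_max),
    !count_ok & band == "mid" ~
      sprintf("fewer than %d reads at coverage > %d",
              rules$min_reads_mid, rules$low_band_max),
    !count_ok ~ sprintf(
      "allele fraction below %s%% at coverage > %d",
      ifelse(both, rules$min_frac_both * 100, rules$min_frac_single * 100),
      rules$mid_band_max),
    !qual_ok ~ sprintf("base-quality fraction below %s%%", qual_needed * 100),
    TRUE ~ NA_character_
  )
  tibble(pass = count_ok & qual_ok, reason = reason,
         band = as.character(band))
}

#' Check minimum evidence for one allele
#'
#' Applies the coverage-banded read-count rule and the base-quality-fraction
#' rule to one allele of a single pileup position.
#'
#' @param column A one-position pileup tibble ([build_pileup()] or
#'   [pileup_column()]).
#' @param allele The allele (A/C/G/T) to test; an allele absent from the
#'   column fails with zero counts.
#' @param rules An [evidence_rules()] object.
#' @return A one-row tibble with `pass`, `reason` (`NA` when passing) and
#'   `band` (`"low"`, `"mid"` or `"high"`).
#' @examples
#' col <- pileup_column(ref = "A", allele = c("A", "G"),
#'                      n_fwd = c(12, 3), n_rev = c(0, 0))
#' evidence_check(col, "G")
#' @export
evidence_check <- function(column, allele, rules = evidence_rules()) {
  stopifnot(is.data.frame(column), length(unique(column$pos)) <= 1L)
  if (!allele %in% c("A", "C", "G", "T")) abort("allele must be A, C, G or T")
  coverage <- if (nrow(column)) column$coverage[1] else 0L
  qual_total <- if (nrow(column)) column$qual_total[1] else 0L
  row <- column[column$allele == allele, , drop = FALSE]
  if (nrow(row) == 0L) {
    row <- tibble(n_reads = 0L, n_fwd = 0L, n_rev = 0L, qual_sum = 0L)
  }
  .evidence_vec(row$n_reads[1], row$n_fwd[1], row$n_rev[1], row$qual_sum[1],
                coverage, qual_total, rules)
}

#' Call genotypes from a pileup
#'
#' For every position, the two most common alleles (ties broken by summed
#' base quality, then alphabetically) are tested with [evidence_check()].
#' Both passing makes the position heterozygous; exactly one passing makes
#' it homozygous for that allele. When no allele passes, the position is
#' homozygous reference if the reference base was observed, else a no-call
#' (`zygosity = NA`, dropped when `drop_nocall = TRUE`).
#'
#' @param pileup A pileup tibble; must carry a `ref` column (build with a
#'   reference, or supply `ref` via [pileup_column()]).
#' @param rules An [evidence_rules()] object.
#' @param drop_nocall Drop no-call positions (default) or keep them with
#'   `NA` zygosity.
#' @return A tibble with one row per position: `chrom`, `pos`, `ref`,
#'   `allele1`, `allele2` (`NA` for homozygous), `zygosity` (`"hom"`/
#'   `"het"`), `gt` (e.g. `"A/G"`, homozygous written `"G/G"`), and the
#'   supporting read counts `n_reads1`/`n_reads2` of the genotype alleles.
#' @examples
#' col <- pileup_column(ref = "A", allele = c("A", "G"),
#'                      n_fwd = c(15, 15), n_rev = 0)
#' call_genotypes(col)
#' @export
call_genotypes <- function(pileup, rules = evidence_rules(),
                           drop_nocall = TRUE) {
  stopifnot(is.data.frame(pileup))
  if (!"ref" %in% names(pileup)) {
    abort("pileup must have a ref column to call genotypes")
  }
  if (nrow(pileup) == 0L) return(.empty_genotypes())

  ev <- .evidence_vec(pileup$n_reads, pileup$n_fwd, pileup$n_rev,
                      pileup$qual_sum, pileup$coverage, pileup$qual_total,
                      rules)
  pileup$pass <- ev$pass

  gt <- pileup |>
    arrange(chrom, pos, desc(n_reads), desc(qual_sum), allele) |>
    group_by(chrom, pos) |>
    summarise(
      ref = ref[1],
      a1 = allele[1],
      a1_pass = pass[1],
      a1_n = n_reads[1],
      a2 = if (n() >= 2L) allele[2] else NA_character_,
      a2_pass = if (n() >= 2L) pass[2] else FALSE,
      a2_n = if (n() >= 2L) n_reads[2] else 0L,
      ref_seen = any(allele == ref[1] & n_reads > 0L),
      ref_n = sum(n_reads[allele == ref[1]]),
      .groups = "drop"
    )

  out <- gt |>
    mutate(
      zygosity = dplyr::case_when(
        a1_pass & a2_pass ~ "het",
        a1_pass | a2_pass ~ "hom",
        ref_seen ~ "hom",
        TRUE ~ NA_character_
      ),
      allele1 = dplyr::case_when(
        a1_pass ~ a1,
        a2_pass ~ a2,
        ref_seen ~ ref,
        TRUE ~ NA_character_
      ),
      allele2 = dplyr::if_else(zygosity == "het", a2, NA_character_),
      gt = dplyr::case_when(
        zygosity == "het" ~ paste0(pmin(allele1, allele2), "/",
                                   pmax(allele1, allele2)),
        zygosity == "hom" ~ paste0(allele1, "/", allele1),
        TRUE ~ NA_character_
      ),
      n_reads1 = dplyr::case_when(
        is.na(allele1) ~ NA_integer_,
        allele1 == a1 ~ a1_n,
        !is.na(a2) & allele1 == a2 ~ a2_n,
        allele1 == ref ~ ref_n,
        TRUE ~ 0L
      ),
      n_reads2 = dplyr::if_else(zygosity == "het", a2_n, NA_integer_)
    ) |>
    select(chrom, pos, ref, allele1, allele2, zygosity, gt,
           n_reads1, n_reads2)

  if (drop_nocall) out <- out[!is.na(out$zygosity), , drop = FALSE]
  out
}

.empty_genotypes <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         allele1 = character(), allele2 = character(), zygosity = character(),
         gt = character(), n_reads1 = integer(), n_reads2 = integer())
}

# alleles of a genotype as a character vector (helper used downstream)
.gt_alleles <- function(allele1, allele2) {
  if (is.na(allele2)) c(allele1, allele1) else c(allele1, allele2)
}
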