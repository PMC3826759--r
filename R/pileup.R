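# Pileups are long-format tibbles: one row per (chrom, pos, allele) with
# stranded counts, a base-quality sum, the novel-start count and the total
# position coverage repeated on every allele row of the position.
#
# The novel-start key of a read is (strand, 5'-most aligned position):
# reads amplified from one PCR molecule share their 5' start, so distinct
# keys proxy independent source molecules. Mate information is deliberately
# ignored — duplicate pairs whose mates were scattered across chromosomes
# by mis-mapping (and therefore escape duplicate marking) still collapse to
# one key.

#' Build a stranded allele pileup
#'
#' Stacks aligned reads into per-position, per-allele counts. Only reads
#' passing `filter` contribute; with `filter = NULL` the pileup is
#' "unfiltered" but still excludes duplicate-marked reads, matching the
#' unfiltered non-duplicate check applied to the normal sample. Bases
#' called `N` or with Phred quality 0 contribute neither to allele counts
#' nor to coverage.
#'
#' @param reads A reads table ([reads_tbl()]).
#' @param reference Optional named character vector of sequences; when
#'   given, a `ref` column is attached and positions are checked to lie
#'   within bounds.
#' @param region Optional `list(chrom =, start =, end =)` (or a vector
#'   `c(chrom, start, end)`) restricting the pileup.
#' @param filter A `filter_spec`, a filter expression string, or `NULL`
#'   for the unfiltered non-duplicate mode.
#' @return A tibble with columns `chrom`, `pos`, (`ref`,) `allele`,
#'   `n_fwd`, `n_rev`, `n_reads`, `qual_sum`, `novel_starts`, `coverage`,
#'   `qual_total`, sorted by position; positions with no contributing
#'   reads are absent.
#' @examples
#' rd <- reads_tbl(chrom = "chr1", start = 1, strand = rep(c("+", "-"), 5),
#'                 bases = "C", quals = "I")
#' build_pileup(rd)
#' @export
build_pileup <- function(reads, reference = NULL, region = NULL,
                         filter = NULL) {
  reads <- validate_reads(reads)
  if (!is.null(filter)) {
    reads <- reads[passes_filter(reads, filter), , drop = FALSE]
  } else {
    reads <- reads[!reads$is_duplicate, , drop = FALSE]
  }
  if (!is.null(region)) {
    region <- as.list(region)
    if (is.null(names(region)) || !all(c("chrom", "start", "end") %in% names(region))) {
      names(region) <- c("chrom", "start", "end")
    }
    rs <- as.integer(region$start); re <- as.integer(region$end)
    if (!is.null(reference)) {
      if (!region$chrom %in% names(reference) ||
          rs < 1L || re > nchar(reference[[region$chrom]])) {
        abort("region outside reference bounds")
      }
    }
    reads <- reads[reads$chrom == region$chrom &
                     reads$start <= re &
                     reads$start + reads$align_len - 1L >= rs, , drop = FALSE]
  }
  if (nrow(reads) == 0L) return(.empty_pileup(!is.null(reference)))

  # expand each read to one row per informative base; N placeholders are
  # located and skipped up front so sparse-footprint reads stay cheap
  hits <- gregexpr("[ACGTacgt]", reads$bases)
  lens <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h),
                 integer(1))
  idx <- rep.int(seq_len(nrow(reads)), lens)
  off <- unlist(lapply(hits, function(h) if (h[1] == -1L) integer() else h),
                use.names = FALSE) - 1L
  base <- substring(reads$bases[idx], off + 1L, off + 1L)
  qual <- utf8ToInt(paste0(reads$quals, collapse = ""))
  qual_off <- rep.int(cumsum(c(0L, head(reads$align_len, -1L))), lens)
  qual <- qual[qual_off + off + 1L] - 33L
  per <- tibble(
    chrom = reads$chrom[idx],
    pos = reads$start[idx] + off,
    allele = toupper(base),
    qual = qual,
    strand = reads$strand[idx],
    start5 = ifelse(reads$strand[idx] == "+", reads$start[idx],
                    reads$start[idx] + reads$align_len[idx] - 1L)
  )
  per <- per[per$qual > 0L, , drop = FALSE]
  if (!is.null(region)) {
    per <- per[per$pos >= as.integer(region$start) &
                 per$pos <= as.integer(region$end), , drop = FALSE]
  }
  if (nrow(per) == 0L) return(.empty_pileup(!is.null(reference)))

  pile <- per |>
    group_by(chrom, pos, allele) |>
    summarise(
      n_fwd = sum(strand == "+"),
      n_rev = sum(strand == "-"),
      qual_sum = sum(qual),
      novel_starts = n_distinct(paste0(strand, ":", start5)),
      .groups = "drop_last"
    ) |>
    mutate(
      n_reads = n_fwd + n_rev,
      coverage = sum(n_reads),
      qual_total = sum(qual_sum)
    ) |>
    ungroup() |>
    arrange(chrom, pos, desc(n_reads), desc(qual_sum), allele)

  if (!is.null(reference)) {
    pile$ref <- ref_base_at(reference, pile$chrom, pile$pos)
  }
  pile[, .pileup_cols(!is.null(reference))]
}

.pileup_cols <- function(with_ref) {
  c("chrom", "pos", if (with_ref) "ref", "allele", "n_fwd", "n_rev",
    "n_reads", "qual_sum", "novel_starts", "coverage", "qual_total")
}

.empty_pileup <- function(with_ref = TRUE) {
  out <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    allele = character(), n_fwd = integer(), n_rev = integer(),
    n_reads = integer(), qual_sum = integer(), novel_starts = integer(),
    coverage = integer(), qual_total = integer()
  )
  out[, .pileup_cols(with_ref)]
}

#' Construct a single pileup column directly
#'
#' Convenience constructor for rule exploration and tests: builds the
#' one-position pileup tibble that [evidence_check()], [call_genotypes()]
#' and the verification rules consume, from bare per-allele counts.
#'
#' @param ref Reference base at the position.
#' @param allele Vector of observed alleles.
#' @param n_fwd,n_rev Stranded read counts per allele.
#' @param qual_sum Summed Phred base quality per allele; defaults to 30 per
#'   read.
#' @param novel_starts Distinct (strand, 5' start) keys per allele;
#'   defaults to the read count.
#' @param chrom,pos Coordinates.
#' @return A one-position pileup tibble.
#' @examples
#' pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(10, 3),
#'               n_rev = c(12, 0))
#' @export
pileup_column <- function(ref, allele, n_fwd, n_rev = 0L, qual_sum = NULL,
                          novel_starts = NULL, chrom = "chr1", pos = 100L) {
  n <- length(allele)
  n_fwd <- rep_len(as.integer(n_fwd), n)
  n_rev <- rep_len(as.integer(n_rev), n)
  n_reads <- n_fwd + n_rev
  if (is.null(qual_sum)) qual_sum <- 30L * n_reads
  if (is.null(novel_starts)) novel_starts <- n_reads
  out <- tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref,
    allele = as.character(allele),
    n_fwd = n_fwd, n_rev = n_rev, n_reads = n_reads,
    qual_sum = as.integer(rep_len(qual_sum, n)),
    novel_starts = as.integer(rep_len(novel_starts, n)),
    coverage = sum(n_reads), qual_total = sum(as.integer(rep_len(qual_sum, n)))
  )
  out[out$n_reads > 0L | out$allele == ref, ] |>
    arrange(desc(n_reads), desc(qual_sum), allele)
}

#' Count novel read starts
#'
#' Number of distinct (strand, 5'-most aligned position) keys among a set
#' of variant-carrying reads, ignoring all mate information. This is the
#' NNS statistic attached to every putative somatic call: PCR siblings
#' share their 5' start even when mis-mapped mates let them escape
#' duplicate marking.
#'
#' @param variant_reads Reads carrying the variant allele.
#' @param pos The variant position (unused in the computation; documents
#'   the contract that all reads cover and support the variant there).
#' @return Integer count, at most `nrow(variant_reads)`.
#' @examples
#' rd <- reads_tbl(chrom = "chr1", start = c(5, 5, 7), strand = "+",
#'                 bases = "ACGTACGT", quals = "IIIIIIII")
#' count_novel_starts(rd)  # 2
#' @export
count_novel_starts <- function(variant_reads, pos = NULL) {
  variant_reads <- validate_reads(variant_reads)
  if (nrow(variant_reads) == 0L) return(0L)
  start5 <- ifelse(variant_reads$strand == "+", variant_reads$start,
                   variant_reads$start + variant_reads$align_len - 1L)
  length(unique(paste0(variant_reads$strand, ":", start5)))
}
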