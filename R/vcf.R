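# VCF 4.1 output. Post-processing flags live in FILTER (they gate call
# acceptance); NNS and MR are duplicated into INFO for machine reading.
# QUAL is always "." — the caller computes no p-value by design. Sample
# columns (NORMAL, TUMOR) carry the genotype, total depth and the stranded
# depth of the variant allele.

.vcf_filters <- c(
  COVN12 = "Less than 12 reads coverage in matched normal sample",
  COVN8  = "Less than 8 reads coverage in matched normal sample",
  SAN3   = "Less than 3 reads of same allele in normal",
  COVT8  = "Less than 8 reads coverage in tumor",
  SAT3   = "Less than 3 reads of same allele in tumor",
  GERM   = "Variant is a germline variant in another patient",
  MIN    = "Variant also found in pileup of normal sample",
  MIUN   = "Variant also found in pileup of unfiltered normal sample",
  NNS    = "Less than 4 novel starts not considering read pair",
  MR     = "Less than 5 variant reads",
  MER    = "Mutant allele same as reference",
  SBIAS  = "Strand bias (Illumina only)"
)

#' Write annotated calls to VCF
#'
#' @param calls Annotated calls ([annotate_calls()] or [call_somatic()]),
#'   sorted by chromosome and position.
#' @param path Output file path.
#' @param date Include a `##fileDate` header line; off by default so that
#'   identical inputs produce byte-identical files.
#' @return `calls`, invisibly.
#' @export
write_vcf <- function(calls, path, date = FALSE) {
  ord <- order(calls$chrom, calls$pos)
  if (!identical(ord, seq_len(nrow(calls)))) {
    abort("calls must be sorted by chromosome and position")
  }
  header <- c(
    "##fileformat=VCFv4.1",
    if (date) paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
    "##source=snvpure",
    sprintf('##FILTER=<ID=%s,Description="%s">',
            names(.vcf_filters), unname(.vcf_filters)),
    '##INFO=<ID=CLASS,Number=1,Type=String,Description="Joint classification: Somatic or Germline">',
    '##INFO=<ID=CONF,Number=1,Type=String,Description="Confidence tier: high, medium or low">',
    '##INFO=<ID=NNS,Number=1,Type=Integer,Description="Novel starts supporting the variant, not considering read pair">',
    '##INFO=<ID=MR,Number=1,Type=Integer,Description="Variant reads in tumor">',
    '##INFO=<ID=VA,Number=1,Type=String,Description="Variant allele the evidence checks examined">',
    '##INFO=<ID=MA,Number=1,Type=String,Description="Mutant allele (somatic calls)">',
    '##INFO=<ID=SMA,Number=1,Type=String,Description="Second novel tumor allele, when present">',
    '##INFO=<ID=NOTE,Number=1,Type=String,Description="Classification note (e.g. possible-LOH)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Filtered read depth">',
    '##FORMAT=<ID=ADF,Number=1,Type=Integer,Description="Variant-allele depth, forward strand">',
    '##FORMAT=<ID=ADR,Number=1,Type=Integer,Description="Variant-allele depth, reverse strand">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NORMAL", "TUMOR", sep = "\t")
  )
  rows <- map_chr(seq_len(nrow(calls)), function(i) .vcf_row(calls[i, ]))
  writeLines(c(header, rows), path)
  invisible(calls)
}

.vcf_alts <- function(call) {
  gts <- unique(c(strsplit(call$normal_gt, "/")[[1]],
                  strsplit(call$tumor_gt, "/")[[1]]))
  alts <- setdiff(gts, call$ref)
  extra <- setdiff(stats::na.omit(c(call$variant_allele,
                                    call$second_mutant_allele)), call$ref)
  first <- if (!is.na(call$variant_allele) && call$variant_allele != call$ref) {
    call$variant_allele
  } else character()
  unique(c(first, sort(union(alts, extra))))
}

.vcf_gt <- function(gt, ref, alts) {
  idx <- match(strsplit(gt, "/")[[1]], c(ref, alts)) - 1L
  paste(idx, collapse = "/")
}

.vcf_row <- function(call) {
  alts <- .vcf_alts(call)
  info <- c(
    paste0("CLASS=", call$classification),
    paste0("CONF=", call$confidence),
    paste0("NNS=", call$novel_starts),
    paste0("MR=", call$mutant_reads),
    if (!is.na(call$variant_allele)) paste0("VA=", call$variant_allele),
    if (!is.na(call$mutant_allele)) paste0("MA=", call$mutant_allele),
    if (!is.na(call$second_mutant_allele))
      paste0("SMA=", call$second_mutant_allele),
    if (!is.na(call$note)) paste0("NOTE=", call$note)
  )
  normal <- paste(.vcf_gt(call$normal_gt, call$ref, alts), call$normal_cov,
                  call$normal_variant_fwd, call$normal_variant_rev, sep = ":")
  tumor <- paste(.vcf_gt(call$tumor_gt, call$ref, alts), call$tumor_cov,
                 call$mutant_fwd, call$mutant_rev, sep = ":")
  paste(call$chrom, call$pos, ".", call$ref,
        if (length(alts)) paste(alts, collapse = ",") else ".",
        ".", call$filter, paste(info, collapse = ";"),
        "GT:DP:ADF:ADR", normal, tumor, sep = "\t")
}

#' Read a VCF written by [write_vcf()]
#'
#' Parses the package's own VCF output back into the annotated-call
#' layout, reconstructing genotypes from the GT indices.
#'
#' @param path VCF file path.
#' @return A tibble with the call columns that [write_vcf()] serializes.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) return(.empty_calls())
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    if (length(m) == 0L) NA_character_ else sub(paste0(".*", key, "="), "", m)
  }
  rows <- map(f, function(x) {
    ref <- x[4]
    alts <- if (x[5] == ".") character() else strsplit(x[5], ",")[[1]]
    alleles <- c(ref, alts)
    decode_gt <- function(s) {
      idx <- as.integer(strsplit(strsplit(s, ":")[[1]][1], "/")[[1]]) + 1L
      paste(alleles[idx], collapse = "/")
    }
    nrm <- strsplit(x[10], ":")[[1]]
    tum <- strsplit(x[11], ":")[[1]]
    info <- x[8]
    filter <- x[7]
    tibble(
      chrom = x[1], pos = as.integer(x[2]), ref = ref,
      normal_gt = decode_gt(x[10]), tumor_gt = decode_gt(x[11]),
      classification = info_get(info, "CLASS"),
      mutant_allele = info_get(info, "MA"),
      second_mutant_allele = info_get(info, "SMA"),
      note = info_get(info, "NOTE"),
      variant_allele = info_get(info, "VA"),
      mutant_reads = as.integer(info_get(info, "MR")),
      mutant_fwd = as.integer(tum[3]), mutant_rev = as.integer(tum[4]),
      novel_starts = as.integer(info_get(info, "NNS")),
      tumor_cov = as.integer(tum[2]), normal_cov = as.integer(nrm[2]),
      normal_variant_fwd = as.integer(nrm[3]),
      normal_variant_rev = as.integer(nrm[4]),
      normal_variant_reads = as.integer(nrm[3]) + as.integer(nrm[4]),
      filter = filter
    )
  })
  out <- list_rbind(rows)
  out$flags <- map(out$filter, function(fl) {
    if (fl == "PASS") character() else strsplit(fl, ";")[[1]]
  })
  out$confidence <- map_chr(seq_len(nrow(out)), function(i) {
    info_get(f[[i]][8], "CONF")
  })
  out
}
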