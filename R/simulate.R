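# Synthetic tumor/normal read generator.
#
# The generator emulates the structure of an exon-capture mixture series:
# a diploid, copy-number-neutral genome carrying heterozygous and
# homozygous germline variants in both samples and heterozygous somatic
# mutations in the tumor clone only, so a somatic variant's expected
# tumor allele fraction is purity/2. Reads are single-locus-informative
# fragments: each read reports one base at its focal position and carries
# an N placeholder footprint of `read_len` bases around it, so that read
# start coordinates (and hence novel-start counting) behave like real
# fragments while pileups stay cheap. Duplicate read pairs are cloned from
# a source read; most are duplicate-marked, but a configurable fraction
# are "disguised" — left unmarked with their mates scattered to random
# other chromosomes — the failure mode that novel-start counting exists to
# catch.

#' Simulation parameters
#'
#' Defaults describe the mixture-series study conditions: mean depth 65x,
#' 200 planted somatic mutations, and a diploid copy-neutral genome in
#' which a heterozygous somatic variant has expected tumor allele fraction
#' purity/2.
#'
#' @param purity Tumor DNA fraction in the tumor sample, in `[0, 1]`.
#' @param mean_depth Mean reads per position (Poisson).
#' @param n_somatic,n_germline_het,n_germline_hom Planted variant counts.
#' @param n_background Additional variant-free positions receiving reads.
#' @param seq_error_rate Per-base substitution error rate.
#' @param qual_mean,qual_sd Phred base-quality distribution (normal,
#'   rounded, clipped to `[2, 40]`).
#' @param dup_rate Fraction of reads cloned as PCR duplicates.
#' @param disguised_dup_rate Fraction of those duplicate clones that are
#'   left unmarked with mates reassigned to random chromosomes (escaping
#'   duplicate marking) instead of being duplicate-flagged.
#' @param read_len Fragment footprint in bp; focal-base offset is uniform
#'   over the footprint.
#' @param region_length Reference length; variant positions are sampled
#'   without replacement from it.
#' @param chrom Chromosome name.
#' @param seed RNG seed; the same seed reproduces the output exactly.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(purity = 1.0, mean_depth = 65, n_somatic = 200L,
                       n_germline_het = 100L, n_germline_hom = 50L,
                       n_background = 100L, seq_error_rate = 0.002,
                       qual_mean = 32, qual_sd = 4, dup_rate = 0.05,
                       disguised_dup_rate = 0.1, read_len = 35L,
                       region_length = 100000L, chrom = "chr1", seed = 1L) {
  p <- list(purity = purity, mean_depth = mean_depth,
            n_somatic = as.integer(n_somatic),
            n_germline_het = as.integer(n_germline_het),
            n_germline_hom = as.integer(n_germline_hom),
            n_background = as.integer(n_background),
            seq_error_rate = seq_error_rate, qual_mean = qual_mean,
            qual_sd = qual_sd, dup_rate = dup_rate,
            disguised_dup_rate = disguised_dup_rate,
            read_len = as.integer(read_len),
            region_length = as.integer(region_length),
            chrom = chrom, seed = as.integer(seed))
  stopifnot(p$purity >= 0, p$purity <= 1, p$mean_depth > 0,
            p$seq_error_rate >= 0, p$seq_error_rate <= 1,
            p$dup_rate >= 0, p$dup_rate <= 1,
            p$disguised_dup_rate >= 0, p$disguised_dup_rate <= 1,
            p$read_len >= 1L, p$region_length > 10L * p$read_len)
  structure(p, class = "sim_params")
}

# site layout: positions, reference, planted alleles; deterministic given
# the seed, independent of purity so one truth set can serve a whole
# mixture series
sim_layout <- function(params) {
  set.seed(params$seed)
  bases <- c("A", "C", "G", "T")
  refseq <- paste(sample(bases, params$region_length, replace = TRUE),
                  collapse = "")
  n_sites <- params$n_somatic + params$n_germline_het +
    params$n_germline_hom + params$n_background
  lo <- params$read_len + 1L
  hi <- params$region_length - params$read_len
  pos <- sort(sample(lo:hi, n_sites))
  kind <- sample(rep(c("somatic", "germline-het", "germline-hom",
                       "background"),
                     c(params$n_somatic, params$n_germline_het,
                       params$n_germline_hom, params$n_background)))
  ref <- vapply(pos, function(p) substr(refseq, p, p), "")
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  alt[kind == "background"] <- NA_character_
  list(
    reference = setNames(refseq, params$chrom),
    sites = tibble(chrom = params$chrom, pos = pos, ref = ref, alt = alt,
                   kind = kind)
  )
}

.sim_sample <- function(sites, params, alt_prob) {
  n_sites <- nrow(sites)
  depth <- rpois(n_sites, params$mean_depth)
  idx <- rep.int(seq_len(n_sites), depth)
  n <- length(idx)
  if (n == 0L) return(reads_tbl())
  bases4 <- c("A", "C", "G", "T")

  is_alt <- runif(n) < alt_prob[idx]
  obs <- ifelse(is_alt, sites$alt[idx], sites$ref[idx])
  err <- runif(n) < params$seq_error_rate
  if (any(err)) {
    shift <- sample.int(3L, sum(err), replace = TRUE)
    obs[err] <- bases4[(match(obs[err], bases4) - 1L + shift) %% 4L + 1L]
  }
  qual <- pmin(pmax(round(rnorm(n, params$qual_mean, params$qual_sd)), 2L), 40L)
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  off <- sample.int(params$read_len, n, replace = TRUE) - 1L
  start <- sites$pos[idx] - off

  L <- params$read_len
  bases_str <- paste0(strrep("N", off), obs, strrep("N", L - 1L - off))
  quals_str <- paste0(strrep("!", off), intToUtf8(qual + 33L, multiple = TRUE),
                      strrep("!", L - 1L - off))

  rd <- reads_tbl(
    chrom = sites$chrom[idx], start = start, strand = strand,
    bases = bases_str, quals = quals_str, mapq_single = 60L,
    align_len = L, mismatches = 0L, is_duplicate = FALSE,
    is_proper_pair = TRUE,
    is_second_in_pair = runif(n) < 0.5,
    mate_chrom = sites$chrom[idx],
    mate_start = start + ifelse(strand == "+", 150L, -150L)
  )

  # PCR duplicates: clone source reads; disguised clones stay unmarked but
  # their mates scatter to other chromosomes while the focal read keeps the
  # source's start and strand
  n_dup <- round(params$dup_rate * nrow(rd))
  if (n_dup > 0L) {
    src <- rd[sample.int(nrow(rd), n_dup, replace = TRUE), , drop = FALSE]
    disguised <- runif(n_dup) < params$disguised_dup_rate
    src$is_duplicate <- !disguised
    if (any(disguised)) {
      k <- sum(disguised)
      src$mate_chrom[disguised] <- paste0("chr_hom", sample.int(20L, k,
                                                                replace = TRUE))
      src$mate_start[disguised] <- sample.int(params$region_length, k,
                                              replace = TRUE)
    }
    rd <- bind_rows(rd, src)
  }
  arrange(rd, chrom, start)
}

#' Simulate a tumor/normal read pair with planted truth
#'
#' Draws Poisson-depth read sets for both samples over the planted site
#' layout. Germline variants appear in both samples (heterozygous at
#' allele fraction 1/2, homozygous at 1); somatic variants appear in the
#' tumor at expected allele fraction `purity / 2`. Sequencing errors
#' substitute bases uniformly; duplicates (marked and disguised) are
#' cloned from source reads.
#'
#' @param params A [sim_params()] object.
#' @param layout Optionally a precomputed `sim_layout()`; passing the same
#'   layout across calls (as [run_mixture_series()] does) keeps the truth
#'   set fixed while purity varies.
#' @return A list with `tumor` and `normal` reads tables, `truth` (planted
#'   variants with expected allele fractions), `reference` and `params`.
#' @examples
#' sim <- simulate_pair(sim_params(purity = 0.4, n_somatic = 10,
#'                                 n_germline_het = 5, n_germline_hom = 2,
#'                                 n_background = 5, seed = 42))
#' sim$truth
#' @export
simulate_pair <- function(params, layout = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(layout)) layout <- sim_layout(params)
  sites <- layout$sites
  set.seed(params$seed + 104729L)  # reads drawn independently of the layout

  normal_prob <- dplyr::case_when(
    sites$kind == "germline-het" ~ 0.5,
    sites$kind == "germline-hom" ~ 1.0,
    TRUE ~ 0.0
  )
  tumor_prob <- dplyr::case_when(
    sites$kind == "germline-het" ~ 0.5,
    sites$kind == "germline-hom" ~ 1.0,
    sites$kind == "somatic" ~ params$purity / 2,
    TRUE ~ 0.0
  )

  normal <- .sim_sample(sites, params, normal_prob)
  tumor <- .sim_sample(sites, params, tumor_prob)

  truth <- sites |>
    filter(kind != "background") |>
    mutate(vaf_normal = dplyr::case_when(kind == "germline-het" ~ 0.5,
                                         kind == "germline-hom" ~ 1.0,
                                         TRUE ~ 0.0),
           vaf_tumor = dplyr::case_when(kind == "somatic" ~ params$purity / 2,
                                        TRUE ~ vaf_normal))

  list(tumor = tumor, normal = normal, truth = truth,
       reference = layout$reference, params = params)
}
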