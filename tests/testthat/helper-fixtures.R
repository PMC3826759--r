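# Fixture builders shared across test files.

# random single-base reads scattered over a few positions
random_reads <- function(n, seed = 1, chroms = "chr1", span = 50L,
                         read_len = 8L) {
  set.seed(seed)
  start <- sample.int(span, n, replace = TRUE)
  reads_tbl(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    strand = sample(c("+", "-"), n, replace = TRUE),
    bases = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), read_len, replace = TRUE),
            collapse = "")
    }, ""),
    quals = strrep(intToUtf8(33L + sample(20:40, n, replace = TRUE),
                             multiple = TRUE), read_len),
    mapq_single = sample(0:60, n, replace = TRUE),
    mismatches = sample(0:5, n, replace = TRUE),
    is_duplicate = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.15, .85)),
    is_proper_pair = sample(c(TRUE, FALSE), n, replace = TRUE),
    is_second_in_pair = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}

# a one-row genotype tibble in the call_genotypes() layout
gt_row <- function(gt, ref = "A", chrom = "chr1", pos = 100L,
                   n1 = 20L, n2 = 10L) {
  alleles <- strsplit(gt, "/", fixed = TRUE)[[1]]
  het <- alleles[1] != alleles[2]
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref,
    allele1 = alleles[1],
    allele2 = if (het) alleles[2] else NA_character_,
    zygosity = if (het) "het" else "hom",
    gt = gt, n_reads1 = n1,
    n_reads2 = if (het) n2 else NA_integer_
  )
}

# Build one annotated somatic (or germline) call with full control over the
# quantities the post-processing checks read.
annotated_fixture <- function(mutant_reads = 6L, novel_starts = 4L,
                              normal_cov = 30L, tumor_cov = 30L,
                              normal_alt = 0L, unfiltered_normal_alt = NULL,
                              mutant_fwd = NULL, mutant_rev = NULL,
                              germline = FALSE, mutant = "G", ref = "A",
                              platform = "solid", db = NULL,
                              thresholds = annotation_thresholds()) {
  novel_starts <- min(novel_starts, mutant_reads)
  if (is.null(mutant_fwd)) {
    mutant_fwd <- ceiling(mutant_reads / 2)
    mutant_rev <- mutant_reads - mutant_fwd
  }
  if (is.null(mutant_rev)) mutant_rev <- mutant_reads - mutant_fwd
  if (is.null(unfiltered_normal_alt)) unfiltered_normal_alt <- normal_alt

  t_ref <- tumor_cov - mutant_reads
  tum <- pileup_column(
    ref = ref, allele = c(ref, mutant),
    n_fwd = c(ceiling(t_ref / 2), mutant_fwd),
    n_rev = c(floor(t_ref / 2), mutant_rev),
    novel_starts = c(t_ref, novel_starts)
  )
  nrm <- pileup_column(
    ref = ref, allele = c(ref, mutant),
    n_fwd = c(normal_cov - normal_alt, normal_alt), n_rev = 0L
  )
  nrm_unf <- pileup_column(
    ref = ref, allele = c(ref, mutant),
    n_fwd = c(normal_cov - unfiltered_normal_alt, unfiltered_normal_alt),
    n_rev = 0L
  )
  if (germline) {
    calls <- classify_somatic(gt_row(paste0(ref, "/", mutant), ref = ref),
                              gt_row(paste0(ref, "/", mutant), ref = ref))
  } else {
    calls <- classify_somatic(gt_row(paste0(ref, "/", ref), ref = ref),
                              gt_row(paste0(ref, "/", mutant), ref = ref))
  }
  annotate_calls(calls, tum, nrm, nrm_unf, germline_db = db,
                 platform = platform, thresholds = thresholds)
}

# random annotated calls for serialization round-trips
random_calls <- function(n, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pos <- sort(sample.int(10L * n, n))
  ref <- sample(bases, n, replace = TRUE)
  mutant <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  somatic <- runif(n) < 0.7
  flags_pool <- c("COVN12", "MIN", "MIUN", "NNS", "MR", "GERM")
  flags <- lapply(seq_len(n), function(i) {
    if (!somatic[i]) return(sample(c(list(character()), list("SAN3")), 1L)[[1]])
    k <- sample(0:2, 1L, prob = c(.5, .3, .2))
    sort(sample(flags_pool, k))
  })
  mr <- sample(1:40, n, replace = TRUE)
  tcov <- mr + sample(10:60, n, replace = TRUE)
  ncov <- sample(5:60, n, replace = TRUE)
  nvar <- ifelse(somatic, sample(0:2, n, replace = TRUE),
                 sample(5:20, n, replace = TRUE))
  mfwd <- vapply(mr, function(m) sample.int(m + 1L, 1L) - 1L, 1L)
  nfwd <- vapply(nvar, function(m) if (m == 0) 0L else sample.int(m + 1L, 1L) - 1L, 1L)
  tibble::tibble(
    chrom = "chr1", pos = as.integer(pos), ref = ref,
    normal_gt = ifelse(somatic, paste0(ref, "/", ref),
                       paste0(pmin(ref, mutant), "/", pmax(ref, mutant))),
    tumor_gt = paste0(pmin(ref, mutant), "/", pmax(ref, mutant)),
    classification = ifelse(somatic, "Somatic", "Germline"),
    mutant_allele = ifelse(somatic, mutant, NA_character_),
    second_mutant_allele = NA_character_,
    note = ifelse(runif(n) < 0.1, "possible-LOH", NA_character_),
    variant_allele = mutant,
    mutant_reads = mr,
    mutant_fwd = as.integer(mfwd), mutant_rev = as.integer(mr - mfwd),
    novel_starts = pmin(mr, sample(1:20, n, replace = TRUE)),
    tumor_cov = tcov, normal_cov = ncov,
    normal_variant_fwd = as.integer(nfwd),
    normal_variant_rev = as.integer(nvar - nfwd),
    normal_variant_reads = as.integer(nvar),
    flags = flags,
    filter = vapply(flags, function(f) {
      if (length(f) == 0L) "PASS" else paste(f, collapse = ";")
    }, ""),
    confidence = assign_confidence(flags, somatic = somatic)
  )
}
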