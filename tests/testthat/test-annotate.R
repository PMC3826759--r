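test_that("a clean somatic call with enough evidence is PASS / high", {
  out <- annotated_fixture(mutant_reads = 6L, novel_starts = 4L,
                           normal_cov = 30L)
  expect_equal(out$flags[[1]], character())
  expect_equal(out$filter, "PASS")
  expect_equal(out$confidence, "high")
  expect_equal(out$mutant_reads, 6L)
  expect_equal(out$novel_starts, 4L)
})

test_that("thin normal coverage alone gives COVN12 and the medium tier", {
  out <- annotated_fixture(normal_cov = 11L)
  expect_equal(out$flags[[1]], "COVN12")
  expect_equal(out$confidence, "medium")
  # the boundary: 12 reads in the normal is adequate
  expect_equal(annotated_fixture(normal_cov = 12L)$filter, "PASS")
})

test_that("low novel starts or low mutant reads demote to low confidence", {
  nns <- annotated_fixture(novel_starts = 3L)
  expect_equal(nns$flags[[1]], "NNS")
  expect_equal(nns$confidence, "low")
  expect_equal(annotated_fixture(novel_starts = 4L)$filter, "PASS")

  mr <- annotated_fixture(mutant_reads = 4L, novel_starts = 4L)
  expect_true("MR" %in% mr$flags[[1]])
  expect_equal(mr$confidence, "low")
  expect_equal(annotated_fixture(mutant_reads = 5L, novel_starts = 4L)$filter,
               "PASS")
})

test_that("variant evidence in the normal triggers MIN, and MIUN follows", {
  out <- annotated_fixture(normal_alt = 1L)
  expect_true(all(c("MIN", "MIUN") %in% out$flags[[1]]))
  expect_equal(out$confidence, "low")
  # evidence only in the unfiltered pileup triggers MIUN alone
  unf <- annotated_fixture(normal_alt = 0L, unfiltered_normal_alt = 2L)
  expect_equal(unf$flags[[1]], "MIUN")
})

test_that("a mutant allele equal to the reference is flagged MER", {
  calls <- classify_somatic(gt_row("G/G", ref = "A"), gt_row("A/A", ref = "A"))
  tum <- pileup_column(ref = "A", allele = "A", n_fwd = 15, n_rev = 15)
  nrm <- pileup_column(ref = "A", allele = "G", n_fwd = 15, n_rev = 15)
  out <- annotate_calls(calls, tum, nrm, nrm)
  expect_true("MER" %in% out$flags[[1]])
  expect_equal(out$confidence, "low")
})

test_that("a known germline variant in the database flags GERM", {
  db <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                       obs_count = 3L)
  out <- annotated_fixture(db = db)
  expect_equal(out$flags[[1]], "GERM")
  # a different alt allele at the same position does not match
  db2 <- dplyr::mutate(db, alt = "T")
  expect_equal(annotated_fixture(db = db2)$filter, "PASS")
})

test_that("strand bias is flagged on Illumina only, and only when informative", {
  biased <- annotated_fixture(mutant_reads = 6L, mutant_fwd = 6L,
                              mutant_rev = 0L, platform = "illumina")
  expect_true("SBIAS" %in% biased$flags[[1]])
  # same data on SOLiD: no flag (one-strand support is common there)
  solid <- annotated_fixture(mutant_reads = 6L, mutant_fwd = 6L,
                             mutant_rev = 0L, platform = "solid")
  expect_false("SBIAS" %in% solid$flags[[1]])
  # both-strand support on Illumina: no flag
  both <- annotated_fixture(mutant_reads = 6L, mutant_fwd = 3L,
                            mutant_rev = 3L, platform = "illumina")
  expect_false("SBIAS" %in% both$flags[[1]])
})

test_that("germline calls get the germline-only coverage and allele checks", {
  g <- annotated_fixture(germline = TRUE, normal_cov = 7L, tumor_cov = 30L,
                         normal_alt = 4L)
  expect_true("COVN8" %in% g$flags[[1]])
  g2 <- annotated_fixture(germline = TRUE, normal_cov = 30L, normal_alt = 2L)
  expect_true("SAN3" %in% g2$flags[[1]])
  g3 <- annotated_fixture(germline = TRUE, tumor_cov = 7L, mutant_reads = 2L,
                          normal_cov = 30L, normal_alt = 10L)
  expect_true(all(c("COVT8", "SAT3", "MR", "NNS") %in% g3$flags[[1]]))
  # somatic-only checks never fire on germline calls
  expect_false(any(c("COVN12", "MIN", "MIUN", "MER", "SBIAS") %in%
                     unlist(c(g$flags, g2$flags, g3$flags))))
  # clean germline call carries no flags
  clean <- annotated_fixture(germline = TRUE, mutant_reads = 10L,
                             novel_starts = 8L, normal_cov = 30L,
                             normal_alt = 12L)
  expect_equal(clean$filter, "PASS")
})

test_that("PASS never co-occurs with another flag across random fixtures", {
  set.seed(9)
  for (i in 1:40) {
    out <- annotated_fixture(
      mutant_reads = sample(1:12, 1), novel_starts = sample(1:6, 1),
      normal_cov = sample(5:40, 1), normal_alt = sample(0:2, 1),
      germline = sample(c(TRUE, FALSE), 1)
    )
    expect_false("PASS" %in% out$flags[[1]])
    if (out$filter == "PASS") {
      expect_equal(length(out$flags[[1]]), 0L)
      expect_gte(out$mutant_reads, 5L)
      expect_gte(out$novel_starts, 4L)
    }
  }
})

test_that("confidence tiers follow the flag sets", {
  expect_equal(assign_confidence(list(character(), "COVN12",
                                      c("MIN", "NNS"))),
               c("high", "medium", "low"))
  # COVN12 only mediates medium for somatic calls
  expect_equal(assign_confidence(list("COVN12"), somatic = FALSE), "low")
})

test_that("the germline database grows idempotently with clean calls only", {
  clean <- annotated_fixture(germline = TRUE, mutant_reads = 10L,
                             novel_starts = 8L, normal_cov = 30L,
                             normal_alt = 12L)
  calls <- dplyr::bind_rows(
    clean,
    dplyr::mutate(clean, pos = 200L),
    dplyr::mutate(clean, pos = 300L)
  )
  db <- update_germline_db(empty_germline_db(), calls)
  expect_equal(nrow(db), 3L)
  # appending the same calls again changes nothing
  expect_equal(update_germline_db(db, calls), db)
  # a flagged germline call is not "high quality" and is not exported
  flagged <- annotated_fixture(germline = TRUE, normal_cov = 30L,
                               normal_alt = 2L)  # SAN3
  expect_equal(nrow(update_germline_db(empty_germline_db(), flagged)), 0L)
  # somatic calls are never exported
  som <- annotated_fixture()
  expect_equal(nrow(update_germline_db(empty_germline_db(), som)), 0L)
})

test_that("germline database files round-trip", {
  db <- update_germline_db(
    empty_germline_db(),
    annotated_fixture(germline = TRUE, mutant_reads = 10L, novel_starts = 8L,
                      normal_cov = 30L, normal_alt = 12L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_germline_db(db, path)
  expect_equal(as.data.frame(read_germline_db(path)), as.data.frame(db))
})
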