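test_that("precision and sensitivity arithmetic from bare counts", {
  m <- score_calls(tp = 704, fp = 534, fn = 13)
  expect_equal(m$precision_pct, 57)
  expect_equal(m$sensitivity_pct, 98)
  expect_equal(m$precision, 704 / 1238)
  # empty denominators are defined 0 with a warning
  expect_warning(z <- score_calls(tp = 0, fp = 0, fn = 5), "precision")
  expect_equal(z$precision, 0)
  expect_warning(z2 <- score_calls(tp = 0, fp = 3, fn = 0), "sensitivity")
  expect_equal(z2$sensitivity, 0)
})

test_that("scoring against a truth set keys on position and allele", {
  calls <- dplyr::bind_rows(
    annotated_fixture(),                              # PASS somatic at 100
    dplyr::mutate(annotated_fixture(), pos = 200L),   # PASS somatic at 200
    dplyr::mutate(annotated_fixture(novel_starts = 3L), pos = 300L)  # NNS
  )
  truth <- tibble::tibble(chrom = "chr1", pos = c(100L, 300L, 400L),
                          alt = "G", kind = "somatic")
  m <- score_calls(calls, truth = truth)
  expect_equal(m$tp, 1L)   # only the PASS call at 100 matches
  expect_equal(m$fp, 1L)   # PASS call at 200 is absent from truth
  expect_equal(m$fn, 2L)   # 300 (non-PASS) and 400 are missed
  # wrong allele at a right position is not a TP
  m2 <- score_calls(calls, truth = dplyr::mutate(truth, alt = "T"))
  expect_equal(m2$tp, 0L)
})

test_that("amplicon verification applies the printed minima", {
  tum <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(180, 20))
  nrm <- pileup_column(ref = "A", allele = "A", n_fwd = 200)
  expect_equal(verify_amplicon(tum, nrm, "G"), "verified")
  # tumor depth 99 fails the 100x floor
  tum99 <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(89, 10))
  expect_equal(verify_amplicon(tum99, nrm, "G"), "not_verified")
  # a normal mutant fraction of exactly 0.5% fails the strict bound
  nrm05 <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(199, 1))
  expect_equal(verify_amplicon(tum, nrm05, "G"), "not_verified")
  # 10% tumor fraction is the boundary: 9.5% fails
  tum095 <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(181, 19))
  expect_equal(verify_amplicon(tum095, nrm, "G"), "not_verified")
})

test_that("cross-platform verification needs 20x, 5% and 3 reads jointly", {
  mk <- function(cov, alt) pileup_column(ref = "A", allele = c("A", "G"),
                                         n_fwd = c(cov - alt, alt))
  expect_equal(verify_cross_platform(mk(20, 3), "G"), "verified")
  expect_equal(verify_cross_platform(mk(20, 1), "G"), "not_verified")  # 5% but 1 read
  expect_equal(verify_cross_platform(mk(19, 3), "G"), "not_verified")
  expect_equal(verify_cross_platform(mk(100, 4), "G"), "not_verified") # 4% < 5%
})

test_that("overlap reports cover the full Venn partition", {
  ident <- overlap_report(list(a = letters[1:10], b = letters[1:10],
                               c = letters[1:10]))
  expect_equal(ident$count[ident$region == "a&b&c"], 10L)
  expect_equal(sum(ident$count), 10L)
  disj <- overlap_report(list(a = c("x", "y"), b = c("z")))
  expect_equal(disj$count[disj$region == "a"], 2L)
  expect_equal(disj$count[disj$region == "b"], 1L)
  expect_equal(disj$count[disj$region == "a&b"], 0L)
  # random sets against brute-force set algebra
  set.seed(31)
  A <- sample(letters, 12); B <- sample(letters, 15); C <- sample(letters, 8)
  rep3 <- overlap_report(list(A = A, B = B, C = C))
  expect_equal(rep3$count[rep3$region == "A&B&C"],
               length(intersect(intersect(A, B), C)))
  expect_equal(rep3$count[rep3$region == "A"],
               length(setdiff(setdiff(A, B), C)))
  expect_equal(rep3$count[rep3$region == "A&B"],
               length(setdiff(intersect(A, B), C)))
  expect_equal(sum(rep3$count), length(union(union(A, B), C)))
  # tibble inputs key on chrom:pos:alt
  t1 <- tibble::tibble(chrom = "chr1", pos = 1:3, alt = "G")
  t2 <- tibble::tibble(chrom = "chr1", pos = 2:4, mutant_allele = "G")
  rep2 <- overlap_report(list(x = t1, y = t2))
  expect_equal(rep2$count[rep2$region == "x&y"], 2L)
})

test_that("a zero-purity series yields no PASS somatic detections", {
  res <- run_mixture_series(
    c(0, 0),
    sim_params(n_somatic = 25L, n_germline_het = 10L, n_germline_hom = 5L,
               n_background = 10L, region_length = 20000L, seed = 21)
  )
  expect_true(all(res$sensitivity == 0))
})

test_that("sensitivity decays with purity and recovers with depth (small scale)", {
  base <- sim_params(n_somatic = 40L, n_germline_het = 15L,
                     n_germline_hom = 5L, n_background = 15L,
                     region_length = 30000L, seed = 31)
  res <- run_mixture_series(c(1, 0.4, 0.1), base, seeds = 31:33)
  means <- tidy(res) |>
    dplyr::group_by(purity) |>
    dplyr::summarise(s = mean(sensitivity)) |>
    dplyr::arrange(dplyr::desc(purity))
  expect_true(all(diff(means$s) <= 0.05))  # non-increasing within noise
  expect_gt(means$s[1], 0.85)
  expect_lt(means$s[3], 0.6)
  # doubling depth at 20% purity does not hurt sensitivity
  lo <- run_mixture_series(c(0.2, 0.2), base, seeds = 41:43)
  deep <- base; deep$mean_depth <- 130
  hi <- run_mixture_series(c(0.2, 0.2), deep, seeds = 41:43)
  expect_gte(mean(hi$sensitivity), mean(lo$sensitivity) - 0.05)
})

test_that("mixture-series results expose tidy, glance and autoplot", {
  res <- run_mixture_series(
    c(1, 0.2),
    sim_params(n_somatic = 20L, n_germline_het = 5L, n_germline_hom = 2L,
               n_background = 5L, region_length = 20000L, seed = 51)
  )
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("seed", "purity", "n_true", "tp_pass", "fp",
                     "sensitivity"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$sens_high_purity >= gl$sens_low_purity)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
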