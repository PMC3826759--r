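# quality sums chosen so the quality fraction is innocuous (all reads
# qual 30) unless a test manipulates it explicitly

test_that("the 3-read minimum triggers at low coverage", {
  col <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(12, 3))
  expect_true(evidence_check(col, "G")$pass)
  # an absent allele fails
  expect_false(evidence_check(col, "T")$pass)
  # 2 reads are not enough
  col2 <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(13, 2))
  res <- evidence_check(col2, "G")
  expect_false(res$pass)
  expect_match(res$reason, "fewer than 3")
})

test_that("coverage over 20x requires 4 mutant reads", {
  col <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(27, 3))
  res <- evidence_check(col, "G")
  expect_false(res$pass)
  expect_match(res$reason, "fewer than 4")
  col4 <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(26, 4))
  expect_true(evidence_check(col4, "G")$pass)
})

test_that("above 50x the fraction rules govern, with the 3-read floor", {
  # 4 reads on one strand at 100x = 4% < 5%: fail
  col4 <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(96, 4))
  expect_false(evidence_check(col4, "G")$pass)
  # 5 reads = 5%: pass (quality fraction 5% >= 10%? qual fraction here is
  # 5/100 = 5% of summed quality, single strand -> needs 10%: adjust quals)
  col5 <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(95, 5),
                        qual_sum = c(95 * 30, 5 * 30 * 3))
  expect_true(evidence_check(col5, "G")$pass)
  # 3 reads split across strands at 100x = 3% >= 2.5%, and the relaxed 5%
  # quality floor applies on both strands above 50x
  col3 <- pileup_column(ref = "A", allele = c("A", "G"),
                        n_fwd = c(49, 2), n_rev = c(48, 1),
                        qual_sum = c(97 * 30, 3 * 60))
  ev3 <- evidence_check(col3, "G")
  expect_true(ev3$pass)
  expect_equal(ev3$band, "high")
  # but 2 reads stay below the global 3-read trigger even at 2.5%
  col2 <- pileup_column(ref = "A", allele = c("A", "G"),
                        n_fwd = c(50, 1), n_rev = c(49, 1))
  expect_false(evidence_check(col2, "G")$pass)
})

test_that("the quality-fraction requirement can fail a well-counted allele", {
  # 5 of 40 reads but carrying only ~4% of summed base quality
  col <- pileup_column(ref = "A", allele = c("A", "G"),
                       n_fwd = c(35, 5), qual_sum = c(35 * 38, 5 * 11))
  res <- evidence_check(col, "G")
  expect_false(res$pass)
  expect_match(res$reason, "quality fraction")
})

test_that("band edges are strict: 20 and 50 belong to the lower bands", {
  # alt base qualities boosted so the quality-fraction rule is passing and
  # only the count rules are under test
  mk <- function(cov, alt) {
    pileup_column(ref = "A", allele = c("A", "G"),
                  n_fwd = c(cov - alt, alt),
                  qual_sum = c((cov - alt) * 10L, alt * 60L))
  }
  expect_true(evidence_check(mk(20, 3), "G")$pass)    # 3-read rule at 20x
  expect_false(evidence_check(mk(21, 3), "G")$pass)   # 4-read rule at 21x
  expect_true(evidence_check(mk(21, 4), "G")$pass)
  expect_false(evidence_check(mk(50, 3), "G")$pass)   # 4-read rule at 50x
  expect_true(evidence_check(mk(50, 4), "G")$pass)
  # at 51x the fraction rules take over: 3 reads are 5.9% >= 5%
  expect_true(evidence_check(mk(51, 3), "G")$pass)
  expect_false(evidence_check(mk(51, 2), "G")$pass)   # global 3-read floor
})

test_that("evidence is monotone in the allele read count", {
  for (cov in c(15, 30, 80)) {
    passed_before <- FALSE
    for (k in 1:12) {
      col <- pileup_column(ref = "A", allele = c("A", "G"),
                           n_fwd = c(cov - k, k))
      p <- evidence_check(col, "G")$pass
      expect_false(passed_before && !p)
      passed_before <- p
    }
  }
})

test_that("two passing alleles make a het, one a hom", {
  het <- call_genotypes(pileup_column(ref = "A", allele = c("A", "G"),
                                      n_fwd = c(15, 15)))
  expect_equal(het$zygosity, "het")
  expect_equal(het$gt, "A/G")
  hom <- call_genotypes(pileup_column(ref = "A", allele = "G", n_fwd = 30))
  expect_equal(hom$gt, "G/G")
  # minor allele failing the >20x count rule leaves a hom call
  weak <- call_genotypes(pileup_column(ref = "A", allele = c("A", "G"),
                                       n_fwd = c(28, 2)))
  expect_equal(weak$gt, "A/A")
})

test_that("no passing allele falls back to hom-reference when ref is seen", {
  col <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(2, 1))
  gt <- call_genotypes(col)
  expect_equal(gt$gt, "A/A")
  # reference unseen: no-call, dropped by default but kept on request
  col2 <- pileup_column(ref = "T", allele = c("A", "G"), n_fwd = c(2, 1))
  expect_equal(nrow(call_genotypes(col2)), 0L)
  kept <- call_genotypes(col2, drop_nocall = FALSE)
  expect_true(is.na(kept$zygosity))
})

test_that("genotype calls match the brute-force oracle on enumerated columns", {
  # all allele-count partitions at small coverage, three strand layouts
  cases <- 0L
  for (cov in c(1, 3, 6, 9)) {
    parts <- expand.grid(A = 0:cov, C = 0:cov, G = 0:cov)
    parts$T <- cov - parts$A - parts$C - parts$G
    parts <- parts[parts$T >= 0, ]
    for (i in seq_len(nrow(parts))) {
      cnt <- unlist(parts[i, ])
      keep <- cnt > 0
      if (!any(keep)) next
      for (layout in c("fwd", "split")) {
        fwd <- if (layout == "fwd") cnt[keep] else ceiling(cnt[keep] / 2)
        col <- pileup_column(ref = "A", allele = names(cnt)[keep],
                             n_fwd = fwd, n_rev = cnt[keep] - fwd)
        got <- call_genotypes(col, drop_nocall = FALSE)
        want <- oracle_genotype(col)
        expect_identical(got$zygosity, want$zygosity)
        expect_identical(got$gt, want$gt)
        cases <- cases + 1L
      }
    }
  }
  expect_gt(cases, 500L)
})
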