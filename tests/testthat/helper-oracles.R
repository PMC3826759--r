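# Independent scalar transliterations of the printed evidence rules, used
# as oracles against the vectorized implementation.

oracle_evidence <- function(n, fwd, rev, qsum, cov, qtot) {
  both <- fwd > 0 && rev > 0
  # read-count requirement by coverage band
  count_ok <- if (cov <= 20) {
    n >= 3
  } else if (cov <= 50) {
    n >= 4
  } else {
    frac <- n / cov
    (if (both) frac >= 0.025 else frac >= 0.05) && n >= 3
  }
  # base-quality-fraction requirement
  qfrac <- if (qtot > 0) qsum / qtot else 0
  qual_ok <- if (both && cov > 50) qfrac >= 0.05 else qfrac >= 0.10
  count_ok && qual_ok
}

# brute-force genotype call for a single pileup column
oracle_genotype <- function(col) {
  col <- col[order(-col$n_reads, -col$qual_sum, col$allele), ]
  cov <- col$coverage[1]
  qtot <- col$qual_total[1]
  passing <- vapply(seq_len(nrow(col)), function(i) {
    oracle_evidence(col$n_reads[i], col$n_fwd[i], col$n_rev[i],
                    col$qual_sum[i], cov, qtot)
  }, logical(1))
  top <- head(seq_len(nrow(col)), 2L)
  top_pass <- top[passing[top]]
  ref <- col$ref[1]
  if (length(top_pass) == 2L) {
    a <- sort(col$allele[top_pass])
    list(zygosity = "het", gt = paste0(a[1], "/", a[2]))
  } else if (length(top_pass) == 1L) {
    a <- col$allele[top_pass]
    list(zygosity = "hom", gt = paste0(a, "/", a))
  } else if (any(col$allele == ref & col$n_reads > 0)) {
    list(zygosity = "hom", gt = paste0(ref, "/", ref))
  } else {
    list(zygosity = NA_character_, gt = NA_character_)
  }
}

# independent per-row transliteration of the germline/somatic rule table
oracle_classify <- function(ref, n_alleles, t_alleles) {
  n_set <- unique(n_alleles)
  t_set <- unique(t_alleles)
  novel <- setdiff(t_set, n_set)
  n_zyg <- if (length(n_set) == 1L) "hom" else "het"
  t_zyg <- if (length(t_set) == 1L) "hom" else "het"
  if (n_zyg == "hom" && t_zyg == "het") {
    if (length(novel) == 1L && novel == ref) return("Germline")
    return(if (length(novel)) "Somatic" else "Germline")
  }
  if (length(novel) == 0L) return("Germline")
  "Somatic"
}
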