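# Purity-mixture benchmark: run the full caller over simulated tumor/normal
# pairs at a ladder of purities against one shared truth set and track how
# sensitivity of PASS somatic detection decays as the mutant allele
# fraction (purity/2 for a heterozygous copy-neutral somatic variant)
# approaches the evidence floor.

#' Run a purity-mixture series
#'
#' For each purity (and each seed), simulates a tumor/normal pair sharing
#' one planted truth set, runs [call_somatic()], and scores PASS somatic
#' calls against the truth.
#'
#' @param purities Numeric vector of tumor purities (at least 2).
#' @param params Base [sim_params()]; its `purity` is overridden per
#'   mixture.
#' @param seeds Integer vector of seeds; each seed gets its own layout and
#'   read draws. Defaults to the seed in `params`.
#' @param platform Platform preset used for filtering and strand checks.
#' @return A tibble of class `mixture_series`: one row per (seed, purity)
#'   with `n_true` (planted somatic variants), `tp_pass` (PASS somatic
#'   calls matching truth), `fp` (PASS somatic calls absent from truth),
#'   and `sensitivity`.
#' @examples
#' \donttest{
#' res <- run_mixture_series(c(1, 0.4), sim_params(n_somatic = 30,
#'   n_germline_het = 10, n_germline_hom = 5, n_background = 10, seed = 3))
#' tidy(res)
#' }
#' @export
run_mixture_series <- function(purities, params = sim_params(),
                               seeds = params$seed,
                               platform = c("solid", "illumina")) {
  if (length(purities) < 2L) abort("need at least 2 purity levels")
  platform <- match.arg(platform)
  rows <- list()
  for (s in seeds) {
    p_seed <- params
    p_seed$seed <- as.integer(s)
    layout <- sim_layout(p_seed)
    truth_somatic <- layout$sites[layout$sites$kind == "somatic", ]
    for (pu in purities) {
      p <- p_seed
      p$purity <- pu
      sim <- simulate_pair(p, layout = layout)
      calls <- call_somatic(sim$tumor, sim$normal, sim$reference,
                            platform = platform)
      sc <- suppressWarnings(score_calls(calls, truth = sim$truth))
      rows[[length(rows) + 1L]] <- tibble(
        seed = as.integer(s), purity = pu,
        n_true = nrow(truth_somatic),
        tp_pass = sc$tp, fp = sc$fp,
        sensitivity = sc$sensitivity
      )
    }
  }
  out <- list_rbind(rows)
  class(out) <- c("mixture_series", class(out))
  out
}

#' Score calls against a truth set (or from bare counts)
#'
#' Precision is `TP / (TP + FP)` and sensitivity `TP / (TP + FN)`. Called
#' either with annotated calls plus a truth table — a true positive is a
#' PASS somatic call matching a planted somatic variant on (chrom, pos,
#' alt) — or directly with `tp`/`fp`/`fn` counts (e.g. printed
#' verification tallies).
#'
#' @param calls Annotated calls; ignored when counts are given.
#' @param truth Truth tibble with `chrom`, `pos`, `alt` and `kind`
#'   columns (rows with `kind == "somatic"` are the positives) or just
#'   `chrom`, `pos`, `alt`.
#' @param tp,fp,fn Direct counts.
#' @param pass_only Score only PASS somatic calls (default) or all somatic
#'   calls.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `sensitivity`
#'   (proportions), and `precision_pct`, `sensitivity_pct` (rounded whole
#'   percentages). Empty denominators give 0 with a warning.
#' @examples
#' score_calls(tp = 704, fp = 534, fn = 13)
#' @export
score_calls <- function(calls = NULL, truth = NULL, tp = NULL, fp = NULL,
                        fn = NULL, pass_only = TRUE) {
  if (is.null(tp)) {
    stopifnot(!is.null(calls), !is.null(truth))
    if ("kind" %in% names(truth)) {
      truth <- truth[truth$kind == "somatic", , drop = FALSE]
    }
    som <- calls[calls$classification == "Somatic", , drop = FALSE]
    if (pass_only) som <- som[som$filter == "PASS", , drop = FALSE]
    call_key <- paste(som$chrom, som$pos, som$mutant_allele)
    truth_key <- paste(truth$chrom, truth$pos, truth$alt)
    tp <- sum(call_key %in% truth_key)
    fp <- sum(!call_key %in% truth_key)
    fn <- sum(!truth_key %in% call_key)
  }
  precision <- if (tp + fp == 0) {
    warn("no positive calls; precision set to 0")
    0
  } else tp / (tp + fp)
  sensitivity <- if (tp + fn == 0) {
    warn("empty truth set; sensitivity set to 0")
    0
  } else tp / (tp + fn)
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, sensitivity = sensitivity,
         precision_pct = round(100 * precision),
         sensitivity_pct = round(100 * sensitivity))
}

#' Amplicon verification rule
#'
#' A putative somatic mutation re-sequenced with deep targeted amplicons
#' is verified when both samples reach at least 100x coverage, the tumor
#' mutant allele frequency is at least 10%, and the normal mutant allele
#' frequency is strictly below 0.5%.
#'
#' @param tumor_col,normal_col One-position pileup tibbles at the mutant
#'   position.
#' @param alt The mutant allele.
#' @param min_depth,min_tumor_vaf,max_normal_vaf The rule's thresholds.
#' @return `"verified"` or `"not_verified"`.
#' @examples
#' tum <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(180, 20))
#' nrm <- pileup_column(ref = "A", allele = "A", n_fwd = 200)
#' verify_amplicon(tum, nrm, "G")
#' @export
verify_amplicon <- function(tumor_col, normal_col, alt, min_depth = 100L,
                            min_tumor_vaf = 0.10, max_normal_vaf = 0.005) {
  stats <- function(col) {
    cov <- if (nrow(col)) col$coverage[1] else 0L
    n_alt <- sum(col$n_reads[col$allele == alt])
    c(cov = cov, vaf = if (cov > 0) n_alt / cov else 0)
  }
  t <- stats(tumor_col); n <- stats(normal_col)
  ok <- t[["cov"]] >= min_depth && n[["cov"]] >= min_depth &&
    t[["vaf"]] >= min_tumor_vaf && n[["vaf"]] < max_normal_vaf
  if (ok) "verified" else "not_verified"
}

#' Cross-platform verification rule
#'
#' A call made on one sequencing platform is verified on an alternate
#' platform when the alternate pileup shows depth of at least 20x, mutant
#' allele frequency of at least 5%, and at least 3 variant reads.
#'
#' @param alt_col One-position pileup tibble from the alternate platform.
#' @param alt The mutant allele.
#' @param min_depth,min_vaf,min_reads The rule's thresholds.
#' @return `"verified"` or `"not_verified"`.
#' @examples
#' col <- pileup_column(ref = "A", allele = c("A", "G"), n_fwd = c(17, 3))
#' verify_cross_platform(col, "G")
#' @export
verify_cross_platform <- function(alt_col, alt, min_depth = 20L,
                                  min_vaf = 0.05, min_reads = 3L) {
  cov <- if (nrow(alt_col)) alt_col$coverage[1] else 0L
  n_alt <- sum(alt_col$n_reads[alt_col$allele == alt])
  vaf <- if (cov > 0) n_alt / cov else 0
  if (cov >= min_depth && vaf >= min_vaf && n_alt >= min_reads) "verified"
  else "not_verified"
}

#' Venn-partition counts across call sets
#'
#' Counts, for every region of the Venn partition of two or more named
#' call sets, how many calls fall exclusively in that region.
#'
#' @param call_sets A named list; each element is a character vector of
#'   call keys, or a tibble with `chrom`, `pos` and an allele column
#'   (`alt` or `mutant_allele`), keyed as `chrom:pos:alt`.
#' @return A tibble with one row per non-empty membership pattern:
#'   `region` (set names joined by `&`), `n_sets`, and `count`, plus a
#'   zero-count row for every empty pattern so all `2^k - 1` regions are
#'   reported.
#' @examples
#' overlap_report(list(a = c("x", "y"), b = c("y", "z")))
#' @export
overlap_report <- function(call_sets) {
  if (length(call_sets) < 2L || is.null(names(call_sets))) {
    abort("call_sets must be a named list of at least 2 sets")
  }
  keys <- map(call_sets, function(s) {
    if (is.data.frame(s)) {
      allele_col <- intersect(c("alt", "mutant_allele"), names(s))[1]
      unique(paste(s$chrom, s$pos, s[[allele_col]], sep = ":"))
    } else unique(as.character(s))
  })
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  set_names <- names(call_sets)
  k <- length(set_names)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- set_names
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == p)))
  })
  tibble(
    region = apply(patterns, 1L, function(p) {
      paste(set_names[as.logical(p)], collapse = "&")
    }),
    n_sets = rowSums(patterns),
    count = as.integer(counts)
  ) |> arrange(desc(n_sets), region)
}

# ---- broom / ggplot2 methods for the mixture series ------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture-series result
#'
#' @param x A `mixture_series` from [run_mixture_series()].
#' @param ... Unused.
#' @return One row per (seed, purity) with counts and sensitivity.
#' @export
tidy.mixture_series <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row summary of a mixture-series result
#'
#' @param x A `mixture_series`.
#' @param ... Unused.
#' @return A one-row tibble: number of mixtures and seeds, mean
#'   sensitivity at the highest and lowest purity, total false positives,
#'   and whether mean sensitivity is non-increasing as purity decreases.
#' @export
glance.mixture_series <- function(x, ...) {
  means <- x |>
    group_by(purity) |>
    summarise(sensitivity = mean(sensitivity), .groups = "drop") |>
    arrange(desc(purity))
  tibble(
    n_mixtures = dplyr::n_distinct(x$purity),
    n_seeds = dplyr::n_distinct(x$seed),
    sens_high_purity = means$sensitivity[1],
    sens_low_purity = means$sensitivity[nrow(means)],
    total_fp = sum(x$fp),
    monotone_decay = !is.unsorted(rev(means$sensitivity))
  )
}

#' Plot sensitivity decay across a purity-mixture series
#'
#' Per-seed trajectories in light lines with the cross-seed mean overlaid.
#'
#' @param object A `mixture_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_series <- function(object, ...) {
  df <- as_tibble(unclass(object))
  means <- df |>
    group_by(purity) |>
    summarise(sensitivity = mean(sensitivity), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = purity, y = sensitivity)) +
    ggplot2::geom_line(ggplot2::aes(group = seed), alpha = 0.3) +
    ggplot2::geom_line(data = means, linewidth = 1.2, colour = "#b2182b") +
    ggplot2::geom_point(data = means, colour = "#b2182b") +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Tumor purity", y = "Sensitivity (PASS somatic)",
                  title = "Sensitivity decay with tumor purity")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.mixture_series <- function(x, ...) print(autoplot(x, ...))
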