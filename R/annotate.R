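# Post-processing checks. Each call collects every applicable flag; a call
# with no flags is PASS. Somatic-only checks: COVN12, GERM, MIN, MIUN,
# MER, SBIAS. Germline-only: COVN8, SAN3, COVT8, SAT3. Applied to both:
# NNS (< 4 novel starts) and MR (< 5 variant reads). Confidence tiers:
# high = PASS; medium = somatic with COVN12 as the only flag (normal
# coverage too thin to exclude a germline variant); low = anything else.

#' Annotation thresholds
#'
#' @param min_normal_cov_somatic Somatic calls need at least this much
#'   matched-normal coverage to escape COVN12.
#' @param min_normal_cov_germline,min_tumor_cov_germline Germline coverage
#'   floors (COVN8 / COVT8).
#' @param min_allele_reads_germline Germline same-allele read floor in each
#'   sample (SAN3 / SAT3).
#' @param min_mutant_reads Variant reads needed to escape MR.
#' @param min_novel_starts Novel starts (pair-blind) needed to escape NNS.
#' @param sbias_min_variant,sbias_min_opposite SBIAS triggers (Illumina
#'   only) when at least `sbias_min_variant` variant reads all sit on one
#'   strand while the opposite strand still holds at least
#'   `sbias_min_opposite` reads of any allele, so the one-sidedness is
#'   informative rather than a coverage artifact.
#' @return A list of class `annotation_thresholds`.
#' @export
annotation_thresholds <- function(min_normal_cov_somatic = 12L,
                                  min_normal_cov_germline = 8L,
                                  min_tumor_cov_germline = 8L,
                                  min_allele_reads_germline = 3L,
                                  min_mutant_reads = 5L,
                                  min_novel_starts = 4L,
                                  sbias_min_variant = 5L,
                                  sbias_min_opposite = 5L) {
  structure(list(
    min_normal_cov_somatic = as.integer(min_normal_cov_somatic),
    min_normal_cov_germline = as.integer(min_normal_cov_germline),
    min_tumor_cov_germline = as.integer(min_tumor_cov_germline),
    min_allele_reads_germline = as.integer(min_allele_reads_germline),
    min_mutant_reads = as.integer(min_mutant_reads),
    min_novel_starts = as.integer(min_novel_starts),
    sbias_min_variant = as.integer(sbias_min_variant),
    sbias_min_opposite = as.integer(sbias_min_opposite)
  ), class = "annotation_thresholds")
}

.allele_stats <- function(pileup, prefix) {
  if (is.null(pileup) || nrow(pileup) == 0L) {
    out <- tibble(chrom = character(), pos = integer(),
                  variant_allele = character(), n = integer(),
                  fwd = integer(), rev = integer(), nns = integer())
  } else {
    out <- pileup |>
      select(chrom, pos, variant_allele = allele, n = n_reads,
             fwd = n_fwd, rev = n_rev, nns = novel_starts)
  }
  names(out)[-(1:3)] <- paste0(prefix, c("_n", "_fwd", "_rev", "_nns"))
  out
}

.pos_stats <- function(pileup, prefix) {
  if (is.null(pileup) || nrow(pileup) == 0L) {
    out <- tibble(chrom = character(), pos = integer(), cov = integer(),
                  fwd_cov = integer(), rev_cov = integer())
  } else {
    out <- pileup |>
      group_by(chrom, pos) |>
      summarise(cov = coverage[1], fwd_cov = sum(n_fwd),
                rev_cov = sum(n_rev), .groups = "drop")
  }
  names(out)[-(1:2)] <- paste0(prefix, c("_cov", "_fwd_cov", "_rev_cov"))
  out
}

#' Annotate joint calls with post-processing flags
#'
#' Evaluates every applicable post-processing check on each classified
#' call, records all triggered flags, and assigns the confidence tier.
#'
#' @param calls A joint-call tibble from [classify_somatic()].
#' @param tumor_pileup,normal_pileup Filtered pileups for the two samples.
#' @param normal_unfiltered_pileup The unfiltered non-duplicate pileup of
#'   the normal sample (build with `filter = NULL`); `NULL` skips the MIUN
#'   check.
#' @param germline_db A germline-variant database tibble
#'   ([empty_germline_db()]); `NULL` or empty skips the GERM check.
#' @param platform `"solid"` or `"illumina"`; the strand-bias check only
#'   applies to Illumina data.
#' @param thresholds An [annotation_thresholds()] object.
#' @return `calls` with added columns `variant_allele`, `mutant_reads`,
#'   `novel_starts`, `tumor_cov`, `normal_cov`, `flags` (list of character
#'   vectors, empty for passing calls), `filter` (`"PASS"` or
#'   semicolon-joined flags) and `confidence` (`"high"`/`"medium"`/
#'   `"low"`).
#' @export
annotate_calls <- function(calls, tumor_pileup, normal_pileup,
                           normal_unfiltered_pileup = NULL,
                           germline_db = NULL,
                           platform = c("solid", "illumina"),
                           thresholds = annotation_thresholds()) {
  platform <- match.arg(platform)
  th <- thresholds
  if (nrow(calls) == 0L) {
    return(mutate(calls, variant_allele = character(),
                  mutant_reads = integer(), mutant_fwd = integer(),
                  mutant_rev = integer(), novel_starts = integer(),
                  tumor_cov = integer(), normal_cov = integer(),
                  normal_variant_fwd = integer(),
                  normal_variant_rev = integer(),
                  normal_variant_reads = integer(),
                  flags = list(), filter = character(),
                  confidence = character()))
  }
  missing_pos <- anti_join(calls, tumor_pileup, by = c("chrom", "pos"))
  if (nrow(missing_pos) > 0L) {
    abort("tumor pileup lacks the position of one or more calls")
  }

  # the allele whose evidence the variant-level checks examine: the mutant
  # allele for somatic calls, the (first) non-reference genotype allele for
  # germline calls
  t_alleles <- strsplit(calls$tumor_gt, "/", fixed = TRUE)
  n_alleles <- strsplit(calls$normal_gt, "/", fixed = TRUE)
  calls$variant_allele <- ifelse(
    calls$classification == "Somatic",
    calls$mutant_allele,
    map_chr(seq_len(nrow(calls)), function(i) {
      cand <- setdiff(unique(c(t_alleles[[i]], n_alleles[[i]])), calls$ref[i])
      if (length(cand)) cand[1] else NA_character_
    })
  )

  ann <- calls |>
    left_join(.allele_stats(tumor_pileup, "t"), by = c("chrom", "pos", "variant_allele")) |>
    left_join(.allele_stats(normal_pileup, "n"), by = c("chrom", "pos", "variant_allele")) |>
    left_join(.allele_stats(normal_unfiltered_pileup, "u"), by = c("chrom", "pos", "variant_allele")) |>
    left_join(.pos_stats(tumor_pileup, "t"), by = c("chrom", "pos")) |>
    left_join(.pos_stats(normal_pileup, "n"), by = c("chrom", "pos"))
  for (col in c("t_n", "t_fwd", "t_rev", "t_nns", "n_n", "n_fwd", "n_rev",
                "u_n", "t_cov", "n_cov", "t_fwd_cov", "t_rev_cov")) {
    ann[[col]] <- dplyr::coalesce(ann[[col]], 0L)
  }

  in_db <- if (is.null(germline_db) || nrow(germline_db) == 0L) {
    rep(FALSE, nrow(ann))
  } else {
    paste(ann$chrom, ann$pos, ann$variant_allele) %in%
      paste(germline_db$chrom, germline_db$pos, germline_db$alt)
  }

  som <- ann$classification == "Somatic"
  ger <- !som
  has_miun <- !is.null(normal_unfiltered_pileup)

  flag_tbl <- tibble(
    COVN12 = som & ann$n_cov < th$min_normal_cov_somatic,
    COVN8  = ger & ann$n_cov < th$min_normal_cov_germline,
    SAN3   = ger & !is.na(ann$variant_allele) &
             ann$n_n < th$min_allele_reads_germline,
    COVT8  = ger & ann$t_cov < th$min_tumor_cov_germline,
    SAT3   = ger & !is.na(ann$variant_allele) &
             ann$t_n < th$min_allele_reads_germline,
    GERM   = som & in_db,
    MIN    = som & ann$n_n >= 1L,
    MIUN   = som & has_miun & ann$u_n >= 1L,
    NNS    = ann$t_nns < th$min_novel_starts,
    MR     = ann$t_n < th$min_mutant_reads,
    MER    = som & !is.na(ann$mutant_allele) & ann$mutant_allele == ann$ref,
    SBIAS  = som & platform == "illumina" &
             ann$t_n >= th$sbias_min_variant &
             (ann$t_fwd == 0L | ann$t_rev == 0L) &
             ifelse(ann$t_fwd == 0L, ann$t_fwd_cov, ann$t_rev_cov) >=
               th$sbias_min_opposite
  )
  flag_names <- names(flag_tbl)
  fm <- as.matrix(flag_tbl)
  flags <- apply(fm, 1L, function(r) flag_names[which(r)], simplify = FALSE)

  out <- calls
  out$variant_allele <- ann$variant_allele
  out$mutant_reads <- ann$t_n
  out$mutant_fwd <- ann$t_fwd
  out$mutant_rev <- ann$t_rev
  out$novel_starts <- ann$t_nns
  out$tumor_cov <- ann$t_cov
  out$normal_cov <- ann$n_cov
  out$normal_variant_fwd <- dplyr::coalesce(ann$n_fwd, 0L)
  out$normal_variant_rev <- dplyr::coalesce(ann$n_rev, 0L)
  out$normal_variant_reads <- ann$n_n
  out$flags <- flags
  out$filter <- map_chr(flags, function(f) {
    if (length(f) == 0L) "PASS" else paste(f, collapse = ";")
  })
  out$confidence <- assign_confidence(flags,
                                      somatic = out$classification == "Somatic")
  out
}

#' Assign confidence tiers from flags
#'
#' `high` for calls that pass every check (no flags), `medium` for somatic
#' calls whose only problem is thin normal coverage (COVN12 alone), `low`
#' otherwise.
#'
#' @param flags A list of character vectors (one per call), or a single
#'   character vector of flags for one call.
#' @param somatic Logical, whether each call is somatic (COVN12 mediates
#'   the medium tier for somatic calls only).
#' @return Character vector of `"high"`, `"medium"`, `"low"`.
#' @examples
#' assign_confidence(list(character(), "COVN12", c("MIN", "NNS")))
#' @export
assign_confidence <- function(flags, somatic = TRUE) {
  if (is.character(flags)) flags <- list(flags)
  somatic <- rep_len(somatic, length(flags))
  map_chr(seq_along(flags), function(i) {
    f <- setdiff(flags[[i]], "PASS")
    if (length(f) == 0L) "high"
    else if (somatic[i] && identical(f, "COVN12")) "medium"
    else "low"
  })
}

# ---- germline variant database ---------------------------------------------

#' Germline-variant database
#'
#' A shared database of high-quality germline variants seen in other
#' patients; somatic calls matching an entry are flagged GERM, since a
#' known germline variant surfacing as somatic usually means the matched
#' normal was under-sampled. Stored as a tab-delimited file with columns
#' `chrom`, `pos`, `ref`, `alt`, `obs_count`.
#'
#' @param path File path.
#' @param db A database tibble.
#' @return A database tibble.
#' @export
empty_germline_db <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), obs_count = integer())
}

#' @rdname empty_germline_db
#' @export
read_germline_db <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", obs_count = "i"
  ), progress = FALSE)
}

#' @rdname empty_germline_db
#' @export
write_germline_db <- function(db, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(db, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(db)
}

#' Add high-quality germline calls to the database
#'
#' Appends germline-classified calls that carry no flags (the germline
#' analogue of PASS) and a non-reference allele. Re-adding an existing
#' (chrom, pos, alt) record is a no-op, so repeated runs over the same
#' sample leave the database unchanged.
#'
#' @param db A germline database tibble.
#' @param calls Annotated calls ([annotate_calls()]).
#' @return The updated database tibble.
#' @export
update_germline_db <- function(db, calls) {
  keep <- calls$classification == "Germline" &
    lengths(calls$flags) == 0L & !is.na(calls$variant_allele)
  add <- calls[keep, c("chrom", "pos", "ref", "variant_allele")]
  names(add)[4] <- "alt"
  add$obs_count <- 1L
  new <- anti_join(distinct(add, chrom, pos, alt, .keep_all = TRUE),
                   db, by = c("chrom", "pos", "alt"))
  bind_rows(db, new) |> arrange(chrom, pos, alt)
}
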