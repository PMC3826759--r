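# Aligned reads live in a plain tibble, one row per read. `bases` and
# `quals` are strings spanning the aligned footprint [start, start +
# align_len - 1]; quals is Phred+33 encoded as in FASTQ. Mate coordinates
# are carried so the simulator can plant duplicate pairs whose mates
# scatter across chromosomes, but the caller itself never consults them.

.read_cols <- c(
  "chrom", "start", "strand", "bases", "quals", "mapq_single", "align_len",
  "mismatches", "is_duplicate", "is_proper_pair", "is_second_in_pair",
  "mate_chrom", "mate_start"
)

#' Construct a reads table
#'
#' Builds the tibble of aligned reads that every pileup and calling function
#' consumes. Coordinates are 1-based and fully closed; a read covers
#' `start .. start + align_len - 1` with `align_len` taken from
#' `nchar(bases)` unless given. Base qualities are Phred+33 characters, one
#' per base.
#'
#' @param chrom,start,strand,bases,quals Per-read vectors; `strand` is
#'   `"+"` or `"-"`.
#' @param mapq_single Single-read mapping quality (pair-blind).
#' @param align_len Aligned length in bp; defaults to `nchar(bases)`.
#' @param mismatches Mismatch count to the reference.
#' @param is_duplicate,is_proper_pair,is_second_in_pair Alignment flags.
#' @param mate_chrom,mate_start Mate coordinates (informational).
#' @return A tibble with one row per read.
#' @examples
#' reads_tbl(chrom = "chr1", start = c(10, 12), strand = c("+", "-"),
#'           bases = c("ACGT", "ACGT"), quals = c("IIII", "IIII"))
#' @export
reads_tbl <- function(chrom = character(), start = integer(),
                      strand = character(), bases = character(),
                      quals = character(), mapq_single = 60L,
                      align_len = NULL, mismatches = 0L,
                      is_duplicate = FALSE, is_proper_pair = TRUE,
                      is_second_in_pair = FALSE,
                      mate_chrom = NA_character_, mate_start = NA_integer_) {
  n <- max(length(chrom), length(start), length(strand), length(bases))
  if (n > 0L) {
    n <- max(n, length(quals), length(mapq_single), length(align_len %||% 0L),
             length(mismatches), length(is_duplicate),
             length(is_proper_pair), length(is_second_in_pair),
             length(mate_chrom), length(mate_start))
  }
  if (n == 0L) {
    return(tibble(
      chrom = character(), start = integer(), strand = character(),
      bases = character(), quals = character(), mapq_single = integer(),
      align_len = integer(), mismatches = integer(), is_duplicate = logical(),
      is_proper_pair = logical(), is_second_in_pair = logical(),
      mate_chrom = character(), mate_start = integer()
    ))
  }
  out <- tibble(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    strand = rep_len(as.character(strand), n),
    bases = rep_len(toupper(as.character(bases)), n),
    quals = rep_len(as.character(quals), n),
    mapq_single = rep_len(as.integer(mapq_single), n),
    align_len = if (is.null(align_len)) nchar(rep_len(as.character(bases), n))
                else rep_len(as.integer(align_len), n),
    mismatches = rep_len(as.integer(mismatches), n),
    is_duplicate = rep_len(as.logical(is_duplicate), n),
    is_proper_pair = rep_len(as.logical(is_proper_pair), n),
    is_second_in_pair = rep_len(as.logical(is_second_in_pair), n),
    mate_chrom = rep_len(as.character(mate_chrom), n),
    mate_start = rep_len(as.integer(mate_start), n)
  )
  validate_reads(out)
}

#' Validate a reads table
#'
#' Checks the column set and the basic invariants (positive starts,
#' strand in +/-, quality string length matching `align_len`).
#'
#' @param reads A data frame of reads.
#' @return The validated tibble (invisibly coerced).
#' @export
validate_reads <- function(reads) {
  if (!is.data.frame(reads)) abort("reads must be a data frame")
  missing <- setdiff(.read_cols, names(reads))
  if (length(missing)) {
    abort(paste0("reads table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  reads <- as_tibble(reads)
  if (nrow(reads) == 0L) return(reads)
  if (any(reads$start < 1L)) abort("read start positions must be >= 1")
  if (!all(reads$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(reads$align_len < 1L)) abort("align_len must be >= 1")
  if (any(reads$mismatches < 0L)) abort("mismatches must be >= 0")
  if (any(nchar(reads$bases) != reads$align_len) ||
      any(nchar(reads$quals) != reads$align_len)) {
    abort("bases and quals must each have align_len characters")
  }
  reads
}

#' Read or write the plain-text reads fixture format
#'
#' One read per line, tab-delimited, with the same columns as
#' [reads_tbl()]. Used for small test fixtures and by the `simulate` CLI.
#'
#' @param path File path.
#' @param reads A reads table.
#' @return `read_reads_tsv()` returns a reads tibble; `write_reads_tsv()`
#'   returns `reads` invisibly.
#' @export
read_reads_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", strand = "c", bases = "c", quals = "c",
    mapq_single = "i", align_len = "i", mismatches = "i",
    is_duplicate = "l", is_proper_pair = "l", is_second_in_pair = "l",
    mate_chrom = "c", mate_start = "i"
  ), progress = FALSE)
  validate_reads(out)
}

#' @rdname read_reads_tsv
#' @export
write_reads_tsv <- function(reads, path) {
  readr::write_tsv(validate_reads(reads), path, progress = FALSE)
  invisible(reads)
}

#' Import aligned reads from a BAM/SAM file
#'
#' Converts coordinate-sorted, duplicate-marked alignments into the
#' package's reads table. Clipped bases are dropped so that `bases` covers
#' exactly the aligned reference footprint; reads with insertions or
#' deletions in their CIGAR are skipped with a message (the caller is
#' SNV-only and pileups require a colinear footprint). Mapping quality is
#' taken from the `SM` tag when present, else the MAPQ column; mismatches
#' from the `NM` tag.
#'
#' @param path BAM (or SAM, converted via [Rsamtools::asBam()]) file path.
#' @param region Optional `c(chrom, start, end)` restriction.
#' @return A reads tibble.
#' @export
read_alignments <- function(path, region = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("read_alignments() requires the Rsamtools package")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = TRUE)
  }
  param_args <- list(
    what = c("rname", "pos", "strand", "seq", "qual", "mapq", "cigar",
             "flag", "mrnm", "mpos"),
    tag = c("SM", "NM")
  )
  if (!is.null(region)) {
    param_args$which <- GenomicRanges::GRanges(
      region[[1]], IRanges::IRanges(as.integer(region[[2]]),
                                    as.integer(region[[3]]))
    )
  }
  param <- do.call(Rsamtools::ScanBamParam, param_args)
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(res$pos)
  if (n == 0L) return(reads_tbl())

  flag <- res$flag
  keep <- grepl("^(\\d+[MS=X])+$", res$cigar) & !is.na(res$pos)
  if (any(!keep)) {
    message(sum(!keep), " read(s) with indel/skip CIGARs or no position skipped")
  }
  seqs <- as.character(res$seq)[keep]
  quals <- as.character(res$qual)[keep]
  cig <- res$cigar[keep]
  # trim soft clips off both ends
  lead <- rep(0L, length(cig))
  has_lead <- grepl("^\\d+S", cig)
  lead[has_lead] <- as.integer(sub("^(\\d+)S.*$", "\\1", cig[has_lead]))
  trail <- rep(0L, length(cig))
  has_trail <- grepl("\\d+S$", cig)
  trail[has_trail] <- as.integer(sub("^.*?(\\d+)S$", "\\1", cig[has_trail]))
  alen <- nchar(seqs) - lead - trail
  bases <- substr(seqs, lead + 1L, lead + alen)
  qualstr <- substr(quals, lead + 1L, lead + alen)

  sm <- res$tag$SM
  nm <- res$tag$NM
  mapq <- as.integer(res$mapq)[keep]
  if (!is.null(sm)) {
    smk <- as.integer(sm)[keep]
    mapq <- ifelse(is.na(smk), mapq, smk)
  }
  mm <- if (is.null(nm)) rep(0L, sum(keep)) else {
    v <- as.integer(nm)[keep]
    ifelse(is.na(v), 0L, v)
  }
  fl <- flag[keep]
  reads_tbl(
    chrom = as.character(res$rname)[keep],
    start = as.integer(res$pos)[keep],
    strand = ifelse(as.character(res$strand)[keep] == "-", "-", "+"),
    bases = bases, quals = qualstr,
    mapq_single = ifelse(is.na(mapq), 0L, mapq),
    align_len = alen, mismatches = mm,
    is_duplicate = bitwAnd(fl, 1024L) > 0L,
    is_proper_pair = bitwAnd(fl, 2L) > 0L,
    is_second_in_pair = bitwAnd(fl, 128L) > 0L,
    mate_chrom = as.character(res$mrnm)[keep],
    mate_start = as.integer(res$mpos)[keep]
  )
}

# ---- reference sequences ----------------------------------------------------

#' Load or build a reference
#'
#' The reference is a named character vector of uppercase sequences, one per
#' chromosome. `read_reference()` loads a FASTA file (via Biostrings when
#' available, else a minimal plain-text FASTA reader).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_reference <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    out <- toupper(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  lines <- readLines(path)
  idx <- grepl("^>", lines)
  nm <- sub("^>(\\S+).*$", "\\1", lines[idx])
  grp <- cumsum(idx)
  seqs <- vapply(split(lines[!idx], grp[!idx]), paste0, "", collapse = "")
  setNames(toupper(unname(seqs)), nm)
}

#' Look up reference bases
#'
#' @param reference Named character vector of chromosome sequences.
#' @param chrom,pos Parallel vectors of coordinates (1-based).
#' @return Character vector of bases.
#' @export
ref_base_at <- function(reference, chrom, pos) {
  if (!is.character(reference) || is.null(names(reference))) {
    abort("reference must be a named character vector of sequences")
  }
  bad <- !(chrom %in% names(reference))
  if (any(bad)) {
    abort(sprintf("chromosome '%s' not in reference", chrom[bad][1]))
  }
  out <- substr(reference[chrom], pos, pos)
  if (any(!nzchar(out))) {
    abort("position outside reference bounds")
  }
  unname(out)
}
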