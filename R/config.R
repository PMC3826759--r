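# Run configuration: a single INI-style plain-text file drives a calling
# run. Example:
#
#   [inputs]
#   tumor = tumor_reads.tsv
#   normal = normal_reads.tsv
#   reference = ref.fa
#   germline_db = germline.tsv
#
#   [general]
#   platform = illumina
#   seed = 7
#   output_vcf = calls.vcf
#   output_dcc = calls.dcc.tsv
#
#   [filter]
#   expression = mapq_single > 10 and mismatches <= 3 and not duplicate
#
#   [thresholds]
#   min_reads_low = 3
#   min_mutant_reads = 5

#' Load a run configuration
#'
#' Parses the INI-style configuration file. The `[filter]` section's
#' `expression` is compiled with [parse_filter_spec()]; keys in
#' `[thresholds]` override the matching argument of [evidence_rules()] or
#' [annotation_thresholds()] and are type-checked.
#'
#' @param path Configuration file path.
#' @param require_inputs Require `tumor`, `normal` and `reference` keys
#'   (as the `call` command does).
#' @return A list of class `run_config` with elements `inputs` (paths),
#'   `platform`, `seed`, `outputs`, `filter` (a `filter_spec` or `NULL`,
#'   meaning the platform preset), `rules` and `thresholds`.
#' @export
load_config <- function(path, require_inputs = TRUE) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  section <- ""
  kv <- list()
  for (i in seq_along(lines)) {
    line <- sub("[;#].*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- tolower(sub("^\\[(.*)\\]$", "\\1", line))
      next
    }
    if (!grepl("=", line, fixed = TRUE)) {
      abort(sprintf("config line %d is neither a [section] nor key = value: '%s'",
                    i, lines[i]))
    }
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    kv[[paste0(section, ".", key)]] <- val
  }
  get <- function(name, default = NULL) kv[[name]] %||% default

  inputs <- list(
    tumor = get("inputs.tumor"),
    normal = get("inputs.normal"),
    reference = get("inputs.reference"),
    germline_db = get("inputs.germline_db")
  )
  if (require_inputs) {
    for (need in c("tumor", "normal", "reference")) {
      if (is.null(inputs[[need]])) {
        abort(sprintf("config is missing required key '%s' in [inputs]", need))
      }
    }
  }
  platform <- tolower(get("general.platform", "illumina"))
  if (!platform %in% c("solid", "illumina")) {
    abort(sprintf("platform must be 'solid' or 'illumina', got '%s'", platform))
  }
  seed <- get("general.seed")
  if (!is.null(seed)) {
    seed <- suppressWarnings(as.integer(seed))
    if (is.na(seed)) abort("seed must be an integer")
  }

  filt <- get("filter.expression")
  filter <- if (is.null(filt)) NULL else parse_filter_spec(filt)

  rule_args <- names(formals(evidence_rules))
  ann_args <- names(formals(annotation_thresholds))
  rules_over <- list(); ann_over <- list()
  for (nm in names(kv)) {
    if (!startsWith(nm, "thresholds.")) next
    key <- sub("^thresholds\\.", "", nm)
    val <- suppressWarnings(as.numeric(kv[[nm]]))
    if (is.na(val)) {
      abort(sprintf("threshold '%s' must be numeric, got '%s'", key, kv[[nm]]))
    }
    if (key %in% rule_args) rules_over[[key]] <- val
    else if (key %in% ann_args) ann_over[[key]] <- val
    else abort(sprintf("unknown threshold '%s'", key))
  }

  structure(list(
    inputs = inputs,
    platform = platform,
    seed = seed,
    outputs = list(vcf = get("general.output_vcf"),
                   dcc = get("general.output_dcc")),
    filter = filter,
    rules = do.call(evidence_rules, rules_over),
    thresholds = do.call(annotation_thresholds, ann_over)
  ), class = "run_config")
}
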