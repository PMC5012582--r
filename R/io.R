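## Readers and writers for the tabular dialects the pipeline consumes:
## tab-separated GWAS summary statistics, comma-separated study tables
## (summary and categorical dialects), and TSV/JSON results.

SUMMARY_STAT_COLS <- c("snp", "effect_allele", "other_allele", "eaf",
                       "beta", "se", "pval", "info")
SUMMARY_STAT_REQUIRED <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")

#' Read a GWAS summary-statistics table
#'
#' Tab-delimited UTF-8 with a header row naming (at least)
#' `snp effect_allele other_allele beta se pval`; `eaf` and `info` are
#' optional. Allele fields are upper-cased; rows with unparseable numeric
#' fields are rejected with their row numbers.
#'
#' @param path file path
#' @return data frame, one row per SNP
#' @export
read_summary_stats <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(SUMMARY_STAT_REQUIRED, names(tab))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  num_cols <- intersect(c("eaf", "beta", "se", "pval", "info"), names(tab))
  for (cc in num_cols) {
    raw <- tab[[cc]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad)) {
      stop(sprintf("unparseable numeric value(s) in column '%s' at row(s) %s",
                   cc, paste(bad, collapse = ", ")))
    }
    tab[[cc]] <- val
  }
  tab$effect_allele <- toupper(tab$effect_allele)
  tab$other_allele <- toupper(tab$other_allele)
  if (anyDuplicated(tab$snp)) stop("duplicate snp identifiers in summary-statistics table")
  if (any(tab$se <= 0, na.rm = TRUE)) stop("non-positive standard error in summary-statistics table")
  tab
}

#' Write a GWAS summary-statistics table
#'
#' @param records data frame of SNP records
#' @param path destination path (tab-separated)
#' @return `path`, invisibly
#' @export
write_summary_stats <- function(records, path) {
  cols <- intersect(SUMMARY_STAT_COLS, names(records))
  write.table(format(records[, cols], digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

STRATA_COLS <- c("sex", "cancer_site", "colon_vs_rectum", "smoking_adjusted",
                 "height_measured", "ancestry")

#' Read a study-level table
#'
#' Comma-delimited with a header. The `summary` dialect carries one row per
#' study (`study_id, rr, ci_low, ci_high, unit_cm` plus optional stratum
#' columns); RRs are converted to log scale with
#' `se = (log(ci_high) - log(ci_low)) / 3.92`. The `categorical` dialect adds
#' per-level columns (`level_index, lower_cm, upper_cm, score_cm, n_cases,
#' n_total, person_time, is_reference, design`) and returns one
#' [categorical_study()] per `study_id`.
#'
#' @param path file path
#' @param dialect `"summary"` or `"categorical"`
#' @return for `"summary"`, a data frame of study estimates with columns
#'   `study_id, beta, se, unit_cm` plus strata; for `"categorical"`, a named
#'   list of `categorical_study` objects
#' @export
read_study_table <- function(path, dialect = c("summary", "categorical")) {
  dialect <- match.arg(dialect)
  tab <- read.csv(path, header = TRUE, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (dialect == "summary") {
    for (cc in c("study_id", "rr", "ci_low", "ci_high")) {
      if (!cc %in% names(tab)) stop("missing required column: ", cc)
    }
    if (any(tab$rr <= 0)) stop("rr must be > 0")
    if (any(!(tab$ci_low < tab$rr & tab$rr < tab$ci_high))) {
      stop("each row must satisfy ci_low < rr < ci_high")
    }
    if (is.null(tab$unit_cm)) tab$unit_cm <- 10
    if (any(tab$unit_cm <= 0)) stop("unit_cm must be > 0")
    out <- data.frame(study_id = tab$study_id,
                      beta = log(tab$rr),
                      se = se_from_ci(tab$rr, tab$ci_low, tab$ci_high),
                      unit_cm = tab$unit_cm,
                      stringsAsFactors = FALSE)
    for (sc in intersect(STRATA_COLS, names(tab))) out[[sc]] <- tab[[sc]]
    out
  } else {
    for (cc in c("study_id", "level_index", "rr", "is_reference")) {
      if (!cc %in% names(tab)) stop("missing required column: ", cc)
    }
    if (is.null(tab$design)) tab$design <- "cumulative_incidence"
    studies <- split(tab, tab$study_id)
    out <- lapply(studies, function(d) {
      d <- d[order(d$level_index), , drop = FALSE]
      lv_cols <- intersect(c("lower_cm", "upper_cm", "score_cm", "n_cases",
                             "n_total", "person_time", "rr", "ci_low",
                             "ci_high", "is_reference"), names(d))
      strata <- lapply(intersect(STRATA_COLS, names(d)), function(sc) d[[sc]][1])
      names(strata) <- intersect(STRATA_COLS, names(d))
      categorical_study(study_id = d$study_id[1], design = d$design[1],
                        levels = d[, lv_cols, drop = FALSE],
                        strata = strata)
    })
    out
  }
}

#' Write a study-level table
#'
#' Inverse of [read_study_table()]. Summary estimates are written as RR/CI
#' rows; categorical studies as one row per level.
#'
#' @param x data frame of study estimates (with `beta`, `se`) or a list of
#'   `categorical_study` objects
#' @param path destination (comma-separated)
#' @return `path`, invisibly
#' @export
write_study_table <- function(x, path) {
  if (is.data.frame(x)) {
    out <- data.frame(study_id = x$study_id,
                      rr = exp(x$beta),
                      ci_low = exp(x$beta - 1.96 * x$se),
                      ci_high = exp(x$beta + 1.96 * x$se),
                      unit_cm = if (is.null(x$unit_cm)) 10 else x$unit_cm,
                      stringsAsFactors = FALSE)
    for (sc in intersect(STRATA_COLS, names(x))) out[[sc]] <- x[[sc]]
  } else {
    out <- do.call(rbind, lapply(x, function(st) {
      lv <- st$levels
      lv$study_id <- st$study_id
      lv$design <- st$design
      lv$level_index <- seq_len(nrow(lv))
      lv
    }))
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write analysis results to TSV or JSON
#'
#' Data frames are written as tab-separated text with a deterministic column
#' order and full-precision floats. Everything else is serialized as JSON
#' with run metadata (`seed`, package version, and an optional config hash)
#' under `$meta`.
#'
#' @param results a data frame or any result object/list
#' @param path destination path
#' @param format `"tsv"` (data frames only) or `"json"`
#' @param seed optional seed recorded in the JSON metadata
#' @return `path`, invisibly
#' @export
write_results <- function(results, path, format = c("tsv", "json"), seed = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(results)) stop("TSV output requires a data frame")
    num <- vapply(results, is.numeric, logical(1))
    results[num] <- lapply(results[num], function(v) formatC(v, digits = 17, format = "g"))
    write.table(results[, sort(names(results)), drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    payload <- list(
      meta = list(
        package = "trendmr",
        version = as.character(packageVersion("trendmr")),
        seed = seed,
        config_hash = attr(results, "config_hash")
      ),
      results = unclass(results)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path file path
#' @param format `"tsv"` or `"json"`
#' @return data frame (tsv) or list (json, the `results` element)
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               fileEncoding = "UTF-8")
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)$results
  }
}
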