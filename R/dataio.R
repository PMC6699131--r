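#' Read a genotype call table
#'
#' Reads a delimited genotype table into a [geno_matrix()]. Two dialects are
#' supported: `wide` (one row per sample, first column `sample_id`, one
#' column per marker — the canonical on-disk form, matching DArTSeq-style
#' exports) and `long` (columns `sample`, `marker`, `call`). Calls must be
#' coded `0` (homozygous reference), `1` (heterozygous), `2` (homozygous
#' alternate) or a missing token. Any other token is an error naming the
#' offending cell — it is never silently treated as missing.
#'
#' @param path path to a delimited text file.
#' @param dialect `"wide"` (default) or `"long"`.
#' @param missing_tokens character vector of tokens read as missing;
#'   default `c("NA", "-")`.
#' @param sep field separator, default `","`.
#' @return A [geno_matrix()].
#' @export
read_genotype_table <- function(path, dialect = c("wide", "long"),
                                missing_tokens = c("NA", "-"), sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(sprintf("Genotype file not found: '%s'.", path))
  }
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    rlang::abort(sprintf(
      "Ragged genotype table: row %d has %d fields, expected %d.",
      bad, nf[bad], nf[1]))
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (ncol(df) < 2) rlang::abort("Wide genotype table needs a sample_id column plus markers.")
    sample_ids <- df[[1]]
    marker_ids <- colnames(df)[-1]
    calls <- as.matrix(df[, -1, drop = FALSE])
    dimnames(calls) <- list(sample_ids, marker_ids)
    .parse_calls(calls, missing_tokens)
  } else {
    need <- c("sample", "marker", "call")
    if (!all(need %in% names(df))) {
      rlang::abort("Long genotype table must have columns sample, marker, call.")
    }
    key <- paste(df$sample, df$marker)
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE]
      rlang::abort(sprintf("Duplicate (sample, marker) entry: ('%s', '%s').",
                           d$sample[1], d$marker[1]))
    }
    sample_ids <- unique(df$sample)
    marker_ids <- unique(df$marker)
    calls <- matrix(NA_character_, length(sample_ids), length(marker_ids),
                    dimnames = list(sample_ids, marker_ids))
    calls[cbind(match(df$sample, sample_ids), match(df$marker, marker_ids))] <- df$call
    calls[is.na(calls)] <- missing_tokens[1]
    .parse_calls(calls, missing_tokens)
  }
}

.parse_calls <- function(chr, missing_tokens) {
  out <- matrix(NA_integer_, nrow(chr), ncol(chr), dimnames = dimnames(chr))
  chr_t <- trimws(chr)
  is_missing <- chr_t %in% missing_tokens
  ok <- chr_t %in% c("0", "1", "2")
  bad <- !ok & !is_missing
  if (any(bad)) {
    idx <- which(bad)[1]
    rlang::abort(sprintf(
      "Invalid genotype token '%s' at sample '%s', marker '%s'; expected 0/1/2 or one of: %s.",
      chr[idx],
      rownames(chr)[(idx - 1) %% nrow(chr) + 1],
      colnames(chr)[(idx - 1) %/% nrow(chr) + 1],
      paste(missing_tokens, collapse = ", ")))
  }
  out[ok] <- as.integer(chr_t[ok])
  geno_matrix(out)
}

#' Write a genotype call table
#'
#' Inverse of [read_genotype_table()]; `read(write(x))` is the identity for
#' both dialects.
#'
#' @param g a [geno_matrix()].
#' @param path output path.
#' @param dialect `"wide"` (default) or `"long"`.
#' @param missing_token token written for missing calls; default `"NA"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path, dialect = c("wide", "long"),
                                 missing_token = "NA") {
  dialect <- match.arg(dialect)
  chr <- matrix(as.character(g), nrow(g), ncol(g), dimnames = dimnames(g))
  chr[is.na(chr)] <- missing_token
  if (dialect == "wide") {
    df <- data.frame(sample_id = rownames(g), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(
      sample = rep(rownames(g), times = ncol(g)),
      marker = rep(colnames(g), each = nrow(g)),
      call = as.vector(chr),
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Fixed-column CSV: `sample_id, role, reported_name, province, district,
#' village, pedigree, release_year, germplasm_group, replicate_group`.
#' Absent optional columns are filled with `NA`; the table is validated
#' with [validate_sample_records()].
#'
#' @param path path to the metadata CSV.
#' @return A validated tibble of sample records.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Metadata file not found: '%s'.", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_records(df)
}

#' Write an analysis report to disk
#'
#' Tabular results (tibbles/data frames, e.g. assignment tables, QC stage
#' tables, diversity reports) are written as CSV; list-like results
#' (identity thresholds, agreement reports, library audits) as JSON.
#' An empty table writes a header-only CSV. Round-trips are lossless for
#' all report types via [read_report()].
#'
#' @param result the report object.
#' @param path output path.
#' @param format `"csv"` or `"json"`; defaults by result type.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = NULL) {
  if (is.null(format)) {
    format <- if (is.data.frame(result)) "csv" else "json"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    if (!is.data.frame(result)) {
      rlang::abort("CSV reports require a data frame; use format = 'json'.")
    }
    readr::write_csv(tibble::as_tibble(result), path, progress = FALSE)
  } else {
    x <- if (is.data.frame(result)) as.list(result) else unclass(result)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path path to a `.csv` or `.json` report.
#' @param format `"csv"` or `"json"`; inferred from the extension if `NULL`.
#' @return A tibble (CSV) or a named list (JSON).
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
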