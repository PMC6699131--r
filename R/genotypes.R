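#' Genotype call matrix
#'
#' The internal substrate of all computation: a samples x markers matrix of
#' biallelic genotype calls coded as reference-allele dosage complements,
#' i.e. `0` = homozygous reference, `1` = heterozygous, `2` = homozygous
#' alternate, `NA` = missing. Row names are sample ids, column names marker
#' ids; both must be unique.
#'
#' @param calls integer matrix with values in `{0, 1, 2, NA}`; row names are
#'   sample ids, column names are marker ids.
#' @param marker_info optional tibble of per-marker annotation with a
#'   `marker_id` column (e.g. chromosome, position). Not used by any
#'   analysis in the package, carried through for bookkeeping.
#' @return An object of class `geno_matrix`.
#' @examples
#' m <- matrix(c(0L, 2L, 1L, NA, 0L, 2L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2", "m3")))
#' g <- geno_matrix(m)
#' dim(g)
#' @export
geno_matrix <- function(calls, marker_info = NULL) {
  if (!is.matrix(calls)) {
    rlang::abort("`calls` must be a matrix.")
  }
  storage.mode(calls) <- "integer"
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) {
    idx <- which(bad)[1]
    rlang::abort(sprintf(
      "Invalid genotype code %s at (sample %s, marker %s); allowed codes are 0, 1, 2, NA.",
      calls[idx],
      rownames(calls)[(idx - 1) %% nrow(calls) + 1],
      colnames(calls)[(idx - 1) %/% nrow(calls) + 1]
    ))
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    rlang::abort("`calls` must carry sample ids as row names and marker ids as column names.")
  }
  if (anyDuplicated(rownames(calls))) {
    rlang::abort(sprintf("Duplicate sample id: '%s'.",
                         rownames(calls)[duplicated(rownames(calls))][1]))
  }
  if (anyDuplicated(colnames(calls))) {
    rlang::abort(sprintf("Duplicate marker id: '%s'.",
                         colnames(calls)[duplicated(colnames(calls))][1]))
  }
  structure(calls, marker_info = marker_info,
            class = c("geno_matrix", class(matrix())))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d markers; %.1f%% missing, %.1f%% heterozygous\n",
              nrow(x), ncol(x),
              100 * mean(is.na(x)),
              100 * mean(x == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "marker_info") <- attr(x, "marker_info")
    class(out) <- c("geno_matrix", class(matrix()))
  }
  out
}

#' Convert a genotype matrix to a long tibble
#'
#' @param x a [geno_matrix()].
#' @param ... unused.
#' @return A tibble with columns `sample_id`, `marker_id`, `call`
#'   (integer dosage, `NA` = missing).
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    marker_id = rep(colnames(x), each = nrow(x)),
    call = as.integer(x)
  )
}

#' @export
glance.geno_matrix <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_markers = ncol(x),
    missing_rate = mean(is.na(x)),
    het_rate = mean(x == 1L, na.rm = TRUE)
  )
}

# shared validation of role / group vocabularies
.roles <- c("field", "reference", "replicate")
.germplasm_groups <- c("afghan_collection", "landrace", "released", "other_elite")

#' Validate a sample metadata table
#'
#' Checks the fixed-column metadata contract used throughout the package:
#' one row per sample, roles in `field`/`reference`/`replicate`, and every
#' replicate carrying a `replicate_group` shared by at least one other
#' replicate.
#'
#' @param records data frame with at least `sample_id` and `role`; optional
#'   columns `reported_name`, `province`, `district`, `village`, `pedigree`,
#'   `release_year`, `germplasm_group`, `replicate_group`.
#' @return The records as a tibble with all optional columns present
#'   (filled with `NA` where absent).
#' @export
validate_sample_records <- function(records) {
  records <- tibble::as_tibble(records)
  req <- c("sample_id", "role")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    rlang::abort(paste0("Metadata is missing required column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(records$sample_id)) {
    rlang::abort(sprintf("Duplicate sample_id in metadata: '%s'.",
                         records$sample_id[duplicated(records$sample_id)][1]))
  }
  bad_role <- setdiff(unique(records$role), .roles)
  if (length(bad_role)) {
    rlang::abort(sprintf("Unknown role '%s'; roles must be one of %s.",
                         bad_role[1], paste(.roles, collapse = ", ")))
  }
  opt <- c("reported_name", "province", "district", "village", "pedigree",
           "germplasm_group", "replicate_group")
  for (col in opt) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  if (!"release_year" %in% names(records)) records[[
    "release_year"]] <- NA_integer_
  records$release_year <- as.integer(records$release_year)
  reps <- dplyr::filter(records, .data$role == "replicate")
  if (nrow(reps)) {
    if (anyNA(reps$replicate_group)) {
      rlang::abort("Every replicate sample must carry a replicate_group.")
    }
    sizes <- table(reps$replicate_group)
    if (any(sizes < 2)) {
      rlang::abort(sprintf(
        "Replicate group '%s' has fewer than 2 members.",
        names(sizes)[sizes < 2][1]))
    }
  }
  grp <- records$germplasm_group
  bad_grp <- setdiff(unique(grp[!is.na(grp)]), .germplasm_groups)
  if (length(bad_grp)) {
    rlang::abort(sprintf("Unknown germplasm_group '%s'; must be one of %s.",
                         bad_grp[1], paste(.germplasm_groups, collapse = ", ")))
  }
  records
}
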