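#' QC filter parameters
#'
#' Thresholds for the standard genotyping-by-sequencing cleaning steps:
#' markers and samples with >= 20% missing calls are excluded (inclusive
#' cut), markers with minor allele frequency below 0.01 are excluded
#' (strict cut), and heterozygous calls are recoded to missing beforehand
#' (low-depth platforms call heterozygotes unreliably in inbred material;
#' no imputation is performed at any point).
#'
#' @param max_missing_marker markers with missing fraction `>=` this are
#'   dropped; default 0.20.
#' @param max_missing_sample samples with missing fraction `>=` this are
#'   dropped (computed on surviving markers); default 0.20.
#' @param min_maf markers with minor allele frequency `<` this are dropped
#'   (frequency over non-missing calls on surviving samples); default 0.01.
#' @param recode_het recode heterozygous calls to missing first; default
#'   `TRUE`.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(max_missing_marker = 0.20, max_missing_sample = 0.20,
                      min_maf = 0.01, recode_het = TRUE) {
  for (v in c(max_missing_marker, max_missing_sample, min_maf)) {
    if (!is.numeric(v) || v < 0 || v > 1) {
      rlang::abort("QC thresholds must lie in [0, 1].")
    }
  }
  structure(list(max_missing_marker = max_missing_marker,
                 max_missing_sample = max_missing_sample,
                 min_maf = min_maf, recode_het = isTRUE(recode_het)),
            class = "qc_params")
}

#' Recode heterozygous calls to missing
#'
#' @param g a [geno_matrix()].
#' @return A list with `genotypes` (the recoded matrix) and `count` (number
#'   of cells recoded).
#' @export
recode_heterozygotes <- function(g) {
  het <- which(g == 1L)
  g[het] <- NA_integer_
  list(genotypes = g, count = length(het))
}

#' Apply the QC filter cascade
#'
#' Stages run in a fixed, logged order: (1) recode heterozygotes to
#' missing; (2) drop markers with missing fraction `>= max_missing_marker`;
#' (3) drop samples with missing fraction `>= max_missing_sample`, computed
#' on the surviving markers; (4) drop markers with MAF `< min_maf`,
#' computed over non-missing calls of the surviving samples. Markers left
#' with no non-missing calls at stage 4 are dropped there. The order
#' matters (a marker can survive only because a high-missing sample was
#' removed first) and is therefore part of the contract.
#'
#' @param g a [geno_matrix()].
#' @param params a [qc_params()].
#' @return A list of class `qc_result`: `genotypes` (filtered matrix) and
#'   `report` (class `qc_report`): per-stage before/after counts, removed
#'   ids, and the heterozygote recode count.
#' @export
apply_qc <- function(g, params = qc_params()) {
  stopifnot(inherits(g, "geno_matrix"))
  if (nrow(g) == 0 || ncol(g) == 0) rlang::abort("Genotype matrix is empty.")
  stages <- list()
  log_stage <- function(stage, axis, before, after, removed) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = stage, axis = axis,
      n_before = before, n_after = after,
      removed = list(removed))
  }
  het_count <- 0L
  if (params$recode_het) {
    rc <- recode_heterozygotes(g)
    g <- rc$genotypes
    het_count <- rc$count
  }
  # stage 2: marker missingness
  miss_m <- colMeans(is.na(g))
  drop_m <- colnames(g)[miss_m >= params$max_missing_marker]
  log_stage("marker_missingness", "markers", ncol(g), ncol(g) - length(drop_m), drop_m)
  if (length(drop_m) == ncol(g)) {
    rlang::abort("All markers removed at the marker-missingness stage.")
  }
  g <- g[, setdiff(colnames(g), drop_m), drop = FALSE]
  # stage 3: sample missingness on surviving markers
  miss_s <- rowMeans(is.na(g))
  drop_s <- rownames(g)[miss_s >= params$max_missing_sample]
  log_stage("sample_missingness", "samples", nrow(g), nrow(g) - length(drop_s), drop_s)
  if (length(drop_s) == nrow(g)) {
    rlang::abort("All samples removed at the sample-missingness stage.")
  }
  g <- g[setdiff(rownames(g), drop_s), , drop = FALSE]
  # stage 4: MAF over non-missing calls of surviving samples
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_f <- colnames(g)[is.nan(maf) | maf < params$min_maf]
  log_stage("maf", "markers", ncol(g), ncol(g) - length(drop_f), drop_f)
  if (length(drop_f) == ncol(g)) {
    rlang::abort("All markers removed at the MAF stage.")
  }
  g <- g[, setdiff(colnames(g), drop_f), drop = FALSE]
  report <- structure(list(
    stages = dplyr::bind_rows(stages),
    het_recoded = het_count,
    params = params,
    n_markers_final = ncol(g),
    n_samples_final = nrow(g)
  ), class = "qc_report")
  structure(list(genotypes = g, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d heterozygous calls recoded to missing\n", x$het_recoded))
  st <- x$stages
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-20s %s: %d -> %d (removed %d)\n", st$stage[i], st$axis[i],
                st$n_before[i], st$n_after[i],
                st$n_before[i] - st$n_after[i]))
  }
  cat(sprintf("  final: %d samples x %d markers\n",
              x$n_samples_final, x$n_markers_final))
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::mutate(x$stages,
                n_removed = .data$n_before - .data$n_after,
                removed = purrr::map_chr(.data$removed, paste, collapse = ";"))
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    het_recoded = x$het_recoded,
    n_samples_final = x$n_samples_final,
    n_markers_final = x$n_markers_final
  )
}
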