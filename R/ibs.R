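#' Pairwise identity-by-state between two genotype vectors
#'
#' IBS between two individuals is the mean, over loci non-missing in both,
#' of the fraction of alleles shared at the locus: identical homozygotes
#' share 2/2 alleles (score 1), opposite homozygotes 0/2 (score 0), a
#' heterozygote against a homozygote 1/2 (score 0.5), and two
#' heterozygotes 2/2 (score 1). With dosage coding this is
#' `1 - |d_i - d_j| / 2` per locus.
#'
#' @param a,b integer dosage vectors of equal length (`NA` = missing).
#' @return A list with `ibs` (mean per-locus score; `NA` if no locus is
#'   jointly non-missing) and `n_shared` (number of loci compared).
#' @examples
#' pairwise_ibs(c(0, 2, 2, 0), c(0, 2, 0, NA))
#' @export
pairwise_ibs <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("Genotype vectors must have equal length.")
  }
  keep <- !is.na(a) & !is.na(b)
  n_shared <- sum(keep)
  if (n_shared == 0) {
    return(list(ibs = NA_real_, n_shared = 0L))
  }
  list(ibs = mean(1 - abs(a[keep] - b[keep]) / 2), n_shared = n_shared)
}

#' Pairwise IBS matrix over all samples
#'
#' Computes the full symmetric identity matrix by pairwise comparison of
#' genotypes across all SNP sites, using pairwise-complete loci (the
#' per-pair denominator is the count of loci non-missing in both samples,
#' recorded in `n_shared`). Implemented with indicator cross-products, so
#' it scales to thousands of samples and markers.
#'
#' @param g a [geno_matrix()] with at least 2 samples.
#' @return An object of class `ibs_matrix`: list with `ibs` (symmetric
#'   numeric matrix, `NA` where a pair shares no loci), `n_shared`
#'   (symmetric integer matrix) and `sample_ids`.
#' @export
compute_ibs_matrix <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (nrow(g) < 2) rlang::abort("Need at least 2 samples.")
  X <- unclass(g)
  M <- !is.na(X)
  A0 <- (X == 0L & M) + 0
  A1 <- (X == 1L & M) + 0
  A2 <- (X == 2L & M) + 0
  S <- tcrossprod(M + 0)                       # shared loci
  D1 <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
        tcrossprod(A1, A2) + tcrossprod(A2, A1) # |d_i - d_j| = 1
  D2 <- tcrossprod(A0, A2) + tcrossprod(A2, A0) # |d_i - d_j| = 2
  ibs <- 1 - (D1 + 2 * D2) / (2 * S)
  ibs[S == 0] <- NA_real_
  dimnames(ibs) <- list(rownames(X), rownames(X))
  storage.mode(S) <- "integer"
  dimnames(S) <- dimnames(ibs)
  structure(list(ibs = ibs, n_shared = S, sample_ids = rownames(X)),
            class = "ibs_matrix")
}

#' @export
print.ibs_matrix <- function(x, ...) {
  v <- x$ibs[upper.tri(x$ibs)]
  cat(sprintf("<ibs_matrix> %d samples; off-diagonal IBS range [%.4f, %.4f]%s\n",
              length(x$sample_ids),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              if (anyNA(v)) sprintf(" (%d undefined pairs)", sum(is.na(v))) else ""))
  invisible(x)
}

#' @export
tidy.ibs_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$ibs), arr.ind = TRUE)
  tibble::tibble(
    sample_a = x$sample_ids[ut[, 1]],
    sample_b = x$sample_ids[ut[, 2]],
    ibs = x$ibs[ut],
    n_shared = x$n_shared[ut]
  )
}

# IBS submatrix lookup helper
.ibs_lookup <- function(ibs, rows, cols) {
  ibs$ibs[rows, cols, drop = FALSE]
}

#' Calibrate identity thresholds from technical replicates
#'
#' Genotyping error makes even re-runs of the same DNA fall short of
#' IBS = 1; the distribution of within-group replicate IBS therefore
#' defines what "identical" means for the platform. The initial threshold
#' is the arithmetic mean over all within-group replicate pairs (pooled,
#' unweighted) and the minimum threshold is the smallest such pair value.
#'
#' @param ibs an `ibs_matrix` covering the replicate samples.
#' @param records sample metadata; rows with `role == "replicate"` and
#'   their `replicate_group` define the pairs.
#' @return An object of class `identity_thresholds`: `initial`, `minimum`,
#'   `n_pairs`, and the per-pair tibble `pairs`.
#' @export
calibrate_thresholds <- function(ibs, records) {
  records <- validate_sample_records(records)
  reps <- dplyr::filter(records, .data$role == "replicate",
                        .data$sample_id %in% ibs$sample_ids)
  if (nrow(reps) == 0 || !any(table(reps$replicate_group) >= 2)) {
    rlang::abort(paste(
      "No technical replicate groups of size >= 2 found;",
      "supply identity thresholds manually via identity_thresholds()."))
  }
  pairs <- reps |>
    dplyr::group_by(.data$replicate_group) |>
    dplyr::reframe({
      ids <- .data$sample_id
      cmb <- utils::combn(ids, 2)
      tibble::tibble(sample_a = cmb[1, ], sample_b = cmb[2, ])
    }) |>
    dplyr::mutate(ibs = ibs$ibs[cbind(.data$sample_a, .data$sample_b)])
  if (anyNA(pairs$ibs)) {
    rlang::abort("Undefined IBS (no shared loci) within a replicate pair.")
  }
  identity_thresholds(initial = mean(pairs$ibs), minimum = min(pairs$ibs),
                      n_pairs = nrow(pairs), pairs = pairs)
}

#' Identity thresholds
#'
#' Constructor for manually supplied or replicate-calibrated identity
#' cutoffs.
#'
#' @param initial identity threshold applied first (mean replicate IBS).
#' @param minimum relaxed threshold (minimum replicate IBS).
#' @param n_pairs number of replicate pairs used (0 if manual).
#' @param pairs optional per-pair tibble.
#' @return An object of class `identity_thresholds`.
#' @export
identity_thresholds <- function(initial, minimum, n_pairs = 0L, pairs = NULL) {
  if (!(minimum <= initial && initial <= 1)) {
    rlang::abort("Thresholds must satisfy minimum <= initial <= 1.")
  }
  structure(list(initial = initial, minimum = minimum,
                 n_pairs = as.integer(n_pairs), pairs = pairs),
            class = "identity_thresholds")
}

#' @export
print.identity_thresholds <- function(x, ...) {
  cat(sprintf("<identity_thresholds> initial %.4f, minimum %.4f (from %d replicate pairs)\n",
              x$initial, x$minimum, x$n_pairs))
  invisible(x)
}

#' @export
glance.identity_thresholds <- function(x, ...) {
  tibble::tibble(initial = x$initial, minimum = x$minimum, n_pairs = x$n_pairs)
}

#' @export
tidy.identity_thresholds <- function(x, ...) {
  if (is.null(x$pairs)) return(tibble::tibble())
  x$pairs
}
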