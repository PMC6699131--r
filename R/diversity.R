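#' Modified Rogers' distance matrix
#'
#' MRD between two individuals is
#' `sqrt( (1 / (2 m)) * sum_loci sum_alleles (p_ia - p_ja)^2 )` with
#' within-individual allele fractions `p` in `{0, 0.5, 1}` and `m` the
#' number of pairwise-complete loci. It is a Euclidean distance, which is
#' what licenses metric multidimensional scaling on it. On
#' heterozygote-free, missing-free data `MRD^2 = 1 - IBS`.
#'
#' @param g a [geno_matrix()] with at least 2 samples.
#' @return A list of class `mrd_matrix`: `mrd` (symmetric, zero diagonal,
#'   `NA` where a pair shares no loci) and `n_shared`.
#' @export
mrd_matrix <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (nrow(g) < 2) rlang::abort("Need at least 2 samples.")
  X <- unclass(g)
  M <- !is.na(X)
  A0 <- (X == 0L & M) + 0
  A1 <- (X == 1L & M) + 0
  A2 <- (X == 2L & M) + 0
  S <- tcrossprod(M + 0)
  # sum of squared dosage differences: |d|=1 pairs weigh 1, |d|=2 pairs weigh 4
  SS <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
        tcrossprod(A1, A2) + tcrossprod(A2, A1) +
        4 * (tcrossprod(A0, A2) + tcrossprod(A2, A0))
  d2 <- SS / (4 * S)
  d2[S == 0] <- NA_real_
  diag(d2) <- 0
  mrd <- sqrt(pmax(d2, 0))
  dimnames(mrd) <- list(rownames(X), rownames(X))
  storage.mode(S) <- "integer"
  dimnames(S) <- dimnames(mrd)
  structure(list(mrd = mrd, n_shared = S), class = "mrd_matrix")
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and
#' returns coordinates scaled by the square roots of the leading
#' eigenvalues. Negative eigenvalues (non-Euclidean input) are truncated
#' with a warning.
#'
#' @param distances symmetric numeric matrix with zero diagonal (e.g.
#'   `mrd_matrix(g)$mrd`), or an `mrd_matrix`.
#' @param n_dims number of dimensions to return (default 2).
#' @return An object of class `mds_result`: `points` tibble (`sample_id`,
#'   `dim1`, ...), `eigenvalues`.
#' @export
classical_mds <- function(distances, n_dims = 2) {
  if (inherits(distances, "mrd_matrix")) distances <- distances$mrd
  if (!isSymmetric(unname(distances), tol = 1e-8)) {
    rlang::abort("`distances` must be a symmetric matrix.")
  }
  if (any(abs(diag(distances)) > 1e-12)) {
    rlang::abort("`distances` must have a zero diagonal.")
  }
  n <- nrow(distances)
  n_dims <- min(n_dims, n - 1)
  fit <- stats::cmdscale(stats::as.dist(distances), k = n_dims, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig)))) {
    rlang::warn("Distance matrix is not exactly Euclidean; negative eigenvalues truncated.")
  }
  pts <- fit$points
  if (ncol(pts) < n_dims) {
    pts <- cbind(pts, matrix(0, n, n_dims - ncol(pts)))
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  ids <- rownames(distances)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                              tibble::as_tibble(pts)),
    eigenvalues = fit$eig
  ), class = "mds_result")
}

#' @export
tidy.mds_result <- function(x, ...) x$points

#' Per-group genetic diversity indices
#'
#' For each germplasm group: expected heterozygosity (mean over loci of
#' `2 p (1 - p)` with `p` the group alternate-allele frequency over
#' non-missing calls), the Shannon diversity index (mean over loci of
#' `-(p ln p + q ln q)`, natural log, `0 ln 0 = 0`), and the mean
#' within-group Modified Rogers' distance. Groups of size 1 report `NA`
#' MRD; empty groups are skipped with a warning.
#'
#' @param g a [geno_matrix()].
#' @param records metadata with `germplasm_group` populated for the
#'   samples of `g`.
#' @return A tibble of class `diversity_report`: `germplasm_group`,
#'   `n_entries`, `expected_heterozygosity`, `shannon_index`, `mean_mrd`.
#' @export
group_diversity <- function(g, records) {
  records <- validate_sample_records(records)
  recs <- dplyr::filter(records, .data$sample_id %in% rownames(g),
                        !is.na(.data$germplasm_group))
  if (nrow(recs) == 0) rlang::abort("No samples with assigned germplasm groups.")
  skipped <- setdiff(unique(records$germplasm_group), unique(recs$germplasm_group))
  skipped <- skipped[!is.na(skipped)]
  if (length(skipped)) {
    rlang::warn(sprintf("Empty germplasm group(s) skipped: %s.",
                        paste(skipped, collapse = ", ")))
  }
  out <- recs |>
    dplyr::group_by(.data$germplasm_group) |>
    dplyr::group_modify(function(d, key) {
      sub <- g[d$sample_id, , drop = FALSE]
      p <- colMeans(sub, na.rm = TRUE) / 2
      p <- p[!is.nan(p)]
      q <- 1 - p
      he <- mean(2 * p * q)
      term <- function(z) ifelse(z > 0, -z * log(z), 0)
      shannon <- mean(term(p) + term(q))
      mmrd <- if (nrow(sub) >= 2) {
        mm <- mrd_matrix(sub)$mrd
        mean(mm[upper.tri(mm)], na.rm = TRUE)
      } else NA_real_
      tibble::tibble(n_entries = nrow(sub),
                     expected_heterozygosity = he,
                     shannon_index = shannon,
                     mean_mrd = mmrd)
    }) |>
    dplyr::ungroup()
  class(out) <- c("diversity_report", class(out))
  out
}
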