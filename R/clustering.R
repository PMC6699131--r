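#' Ward hierarchical clustering on IBS-derived distance
#'
#' Agglomerates samples by Ward's minimum-variance criterion on the
#' distance `1 - IBS` (similarity-to-distance transform), and cuts the
#' tree at a requested number of flat clusters.
#'
#' @param ibs an `ibs_matrix` with no undefined entries.
#' @param n_clusters number of flat clusters to cut (optional; `NULL`
#'   returns the tree only).
#' @return A list of class `dendrogram_result`: `hclust` (the merge tree),
#'   `labels` (named integer vector of flat cluster labels, or `NULL`).
#' @export
ward_cluster <- function(ibs, n_clusters = NULL) {
  stopifnot(inherits(ibs, "ibs_matrix"))
  if (anyNA(ibs$ibs)) {
    bad <- which(is.na(ibs$ibs) & upper.tri(ibs$ibs), arr.ind = TRUE)
    pairs <- apply(bad, 1, function(r)
      paste(ibs$sample_ids[r[1]], ibs$sample_ids[r[2]], sep = "~"))
    rlang::abort(paste0("Undefined IBS for pair(s): ",
                        paste(utils::head(pairs, 5), collapse = ", "),
                        if (length(pairs) > 5) ", ..." else ""))
  }
  d <- stats::as.dist(1 - ibs$ibs)
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- if (!is.null(n_clusters)) stats::cutree(hc, k = n_clusters) else NULL
  structure(list(hclust = hc, labels = labels), class = "dendrogram_result")
}

#' Export a sample dendrogram as Newick
#'
#' @param dend a `dendrogram_result` from [ward_cluster()].
#' @param path optional output path; if `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly if written to `path`).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

# project each row of X onto the probability simplex (Euclidean projection)
.project_simplex_rows <- function(X) {
  K <- ncol(X)
  if (K == 1) return(matrix(1, nrow(X), 1, dimnames = dimnames(X)))
  U <- -t(apply(-X, 1, sort))          # rows sorted decreasing
  css <- t(apply(U, 1, cumsum))
  j <- matrix(rep(seq_len(K), each = nrow(X)), nrow(X), K)
  ok <- U + (1 - css) / j > 0
  rho <- K + 1 - max.col(ok[, K:1, drop = FALSE], ties.method = "first")
  theta <- (css[cbind(seq_len(nrow(X)), rho)] - 1) / rho
  out <- pmax(X - theta, 0)
  dimnames(out) <- dimnames(X)
  out
}

.masked_loss <- function(W, Y, Q, G) sum((W * (Y - Q %*% G))^2)

#' Fit a simplex-constrained NMF ancestry model
#'
#' Models observed alternate-allele dosage fractions (0, 0.5, 1; missing
#' entries excluded via a mask) as `Q %*% G`, where each row of the
#' samples-by-K matrix `Q` is a vector of ancestry coefficients on the
#' probability simplex and the K-by-markers matrix `G` holds ancestral
#' allele frequencies in `[0, 1]`. Fitting alternates projected-gradient
#' steps on `Q` (row-wise simplex projection) and `G` (clipping), with
#' backtracking so the masked squared-error loss never increases. The best
#' of `reps` random restarts by final training loss is returned. A sample
#' is assigned to its majority group when its largest coefficient exceeds
#' 0.5, otherwise it is called admixed.
#'
#' @param g a [geno_matrix()].
#' @param K number of ancestral groups (1 to `nrow(g)`).
#' @param seed integer seed for the restarts.
#' @param reps number of random restarts (default 5).
#' @param max_iter,tol convergence controls: stop when the relative loss
#'   change falls below `tol` (default `1e-6`) or after `max_iter`
#'   (default 200) iterations.
#' @return An object of class `ancestry_fit`: `Q`, `G`, `K`, `loss`
#'   (final), `loss_trace`, `converged`, and `group_call` (per sample,
#'   `"1"..K` or `"admixed"`).
#' @export
fit_ancestry <- function(g, K, seed = 1L, reps = 5, max_iter = 200, tol = 1e-6) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- nrow(g); m <- ncol(g)
  if (K < 1) rlang::abort("`K` must be >= 1.")
  if (K > n) rlang::abort("`K` exceeds the number of samples.")
  Y <- unclass(g) / 2
  W <- !is.na(Y) + 0
  Y[is.na(Y)] <- 0
  if (K == 1) {
    G <- matrix(colSums(W * Y) / pmax(colSums(W), 1), 1, m,
                dimnames = list(NULL, colnames(g)))
    Q <- matrix(1, n, 1, dimnames = list(rownames(g), NULL))
    loss <- .masked_loss(W, Y, Q, G)
    return(structure(list(Q = Q, G = G, K = 1L, loss = loss,
                          loss_trace = loss, converged = TRUE,
                          group_call = stats::setNames(rep("1", n), rownames(g))),
                     class = "ancestry_fit"))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(reps)) {
    Q <- .project_simplex_rows(matrix(stats::runif(n * K), n, K))
    G <- matrix(stats::runif(K * m), K, m)
    loss <- .masked_loss(W, Y, Q, G)
    trace <- loss
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # Q step (backtracking projected gradient)
      R <- W * (Q %*% G - Y)
      gradQ <- 2 * R %*% t(G)
      LQ <- 2 * norm(tcrossprod(G), "2") + 1e-12
      step <- 1 / LQ
      repeat {
        Qn <- .project_simplex_rows(Q - step * gradQ)
        if (.masked_loss(W, Y, Qn, G) <= loss + 1e-12 || step < 1e-12) break
        step <- step / 2
      }
      Q <- Qn
      # G step
      R <- W * (Q %*% G - Y)
      gradG <- 2 * t(Q) %*% R
      LG <- 2 * norm(crossprod(Q), "2") + 1e-12
      step <- 1 / LG
      loss_q <- .masked_loss(W, Y, Q, G)
      repeat {
        Gn <- pmin(pmax(G - step * gradG, 0), 1)
        if (.masked_loss(W, Y, Q, Gn) <= loss_q + 1e-12 || step < 1e-12) break
        step <- step / 2
      }
      G <- Gn
      new_loss <- .masked_loss(W, Y, Q, G)
      trace <- c(trace, new_loss)
      if (loss - new_loss < tol * max(loss, 1e-12)) {
        loss <- new_loss
        converged <- TRUE
        break
      }
      loss <- new_loss
    }
    if (is.null(best) || loss < best$loss) {
      best <- list(Q = Q, G = G, loss = loss, trace = trace,
                   converged = converged)
    }
  }
  Q <- best$Q
  rownames(Q) <- rownames(g)
  top <- max.col(Q, ties.method = "first")
  call <- ifelse(Q[cbind(seq_len(n), top)] > 0.5, as.character(top), "admixed")
  structure(list(Q = Q, G = best$G, K = as.integer(K), loss = best$loss,
                 loss_trace = best$trace, converged = best$converged,
                 group_call = stats::setNames(call, rownames(g))),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("<ancestry_fit> K = %d over %d samples; loss %.4f%s; %d admixed\n",
              x$K, nrow(x$Q), x$loss,
              if (x$converged) "" else " (not converged)",
              sum(x$group_call == "admixed")))
  invisible(x)
}

#' @export
tidy.ancestry_fit <- function(x, ...) {
  tibble::as_tibble(x$Q, .name_repair = ~ paste0("Q", seq_len(x$K))) |>
    dplyr::mutate(sample_id = rownames(x$Q),
                  group_call = unname(x$group_call), .before = 1) |>
    tidyr::pivot_longer(dplyr::starts_with("Q"), names_to = "group",
                        names_prefix = "Q", values_to = "coefficient")
}

#' @export
glance.ancestry_fit <- function(x, ...) {
  tibble::tibble(K = x$K, loss = x$loss, converged = x$converged,
                 n_iter = length(x$loss_trace) - 1L,
                 n_admixed = sum(x$group_call == "admixed"))
}

#' Choose the number of ancestral groups by masked cross-entropy
#'
#' For each candidate K, a fixed fraction of the non-missing genotype
#' entries is held out, the ancestry model is fitted on the rest, and the
#' binomial cross-entropy
#' `-mean(y * log(p) + (1 - y) * log(1 - p))` is evaluated on the held-out
#' dosage fractions with `p = (Q G)` clipped to `[1e-6, 1 - 1e-6]`. The
#' chosen K is the smallest one whose relative improvement over K - 1
#' falls below `plateau_tol` (the plateau of the cross-entropy curve); if
#' the curve keeps improving, the largest K wins.
#'
#' @param g a [geno_matrix()].
#' @param K_range candidate K values (default `1:15`).
#' @param mask_fraction fraction of non-missing entries held out, in
#'   `(0, 0.5]` (default 0.1).
#' @param seed integer seed (mask and restarts).
#' @param reps restarts per K (default 2).
#' @param plateau_tol relative-improvement tolerance declaring the plateau
#'   (default 0.01).
#' @param ... passed to [fit_ancestry()].
#' @return An object of class `kselect_result`: tibble
#'   `cross_entropy_by_K` and `chosen_K`.
#' @export
select_k <- function(g, K_range = 1:15, mask_fraction = 0.1, seed = 1L,
                     reps = 2, plateau_tol = 0.01, ...) {
  stopifnot(inherits(g, "geno_matrix"))
  if (mask_fraction <= 0 || mask_fraction > 0.5) {
    rlang::abort("`mask_fraction` must lie in (0, 0.5].")
  }
  K_range <- sort(unique(as.integer(K_range)))
  set.seed(seed)
  obs <- which(!is.na(unclass(g)))
  held <- sample(obs, max(1, round(mask_fraction * length(obs))))
  g_train <- g
  g_train[held] <- NA_integer_
  y <- unclass(g)[held] / 2
  ce <- purrr::map_dbl(K_range, function(K) {
    fit <- fit_ancestry(g_train, K, seed = seed + K, reps = reps, ...)
    P <- fit$Q %*% fit$G
    p <- pmin(pmax(P[held], 1e-6), 1 - 1e-6)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  })
  chosen <- K_range[length(K_range)]
  if (length(K_range) > 1) {
    for (i in 2:length(K_range)) {
      impr <- (ce[i - 1] - ce[i]) / abs(ce[i - 1])
      if (impr < plateau_tol) {
        chosen <- K_range[i - 1]
        break
      }
    }
  }
  structure(list(
    cross_entropy_by_K = tibble::tibble(K = K_range, cross_entropy = ce),
    chosen_K = chosen,
    mask_fraction = mask_fraction
  ), class = "kselect_result")
}

#' @export
print.kselect_result <- function(x, ...) {
  cat(sprintf("<kselect_result> chosen K = %d (cross-entropy plateau over K = %s)\n",
              x$chosen_K, paste(range(x$cross_entropy_by_K$K), collapse = "-")))
  invisible(x)
}

#' @export
tidy.kselect_result <- function(x, ...) x$cross_entropy_by_K

#' Adjusted Rand index between two partitions
#'
#' @param labels_a,labels_b two label vectors of equal length.
#' @return The adjusted Rand index in `[-1, 1]` (1 for identical
#'   partitions up to label permutation).
#' @export
compare_partitions <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    rlang::abort("Partitions must have equal length.")
  }
  mclust::adjustedRandIndex(labels_a, labels_b)
}
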