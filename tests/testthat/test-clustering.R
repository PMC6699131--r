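test_that("Ward on 1-IBS separates constructed blocks and merges clones at 0", {
  block1 <- rep(0L, 60); block2 <- c(rep(0L, 30), rep(2L, 30))
  calls <- rbind(a1 = block1, a2 = block1, a3 = block1,
                 b1 = block2, b2 = block2, b3 = block2)
  g <- gm(calls, samples = rownames(calls))
  ibs <- compute_ibs_matrix(g)
  wc <- ward_cluster(ibs, n_clusters = 2)
  expect_equal(length(unique(wc$labels[1:3])), 1L)
  expect_equal(length(unique(wc$labels[4:6])), 1L)
  expect_false(wc$labels[1] == wc$labels[4])
  # identical samples merge at height 0, and heights never decrease
  expect_equal(wc$hclust$height[1], 0)
  expect_true(all(diff(wc$hclust$height) >= -1e-12))
})

test_that("Ward agrees with an independent Lance-Williams agglomeration", {
  set.seed(41)
  for (rep in 1:3) {
    calls <- matrix(sample(c(0L, 2L), 15 * 60, TRUE), 15, 60)
    g <- gm(calls)
    ibs <- compute_ibs_matrix(g)
    D <- 1 - ibs$ibs
    for (k in c(2, 4)) {
      ours <- ward_cluster(ibs, n_clusters = k)$labels
      oracle <- ward_oracle_labels(D, k)
      expect_equal(compare_partitions(ours, oracle), 1)
    }
  }
})

test_that("undefined IBS entries are rejected with the offending pairs", {
  calls <- rbind(c(0L, NA), c(NA, 2L), c(0L, 2L))
  g <- gm(calls)
  expect_error(ward_cluster(compute_ibs_matrix(g)), "S01~S02")
})

test_that("K = 1 ancestry is the forced solution", {
  set.seed(42)
  g <- gm(matrix(sample(c(0L, 2L, NA), 80, TRUE), 8, 10))
  fit <- fit_ancestry(g, 1)
  expect_true(all(fit$Q == 1))
  Y <- unclass(g) / 2
  expect_equal(as.numeric(fit$G), unname(colMeans(Y, na.rm = TRUE)))
  expect_true(all(fit$group_call == "1"))
})

test_that("two founder blocks resolve to near-pure ancestries; mosaics sit near 50/50", {
  set.seed(43)
  m <- 2000
  fA <- 2L * rbinom(m, 1, 0.5); fB <- 2L * rbinom(m, 1, 0.5)
  noisy <- function(f) { i <- sample.int(m, 10); f[i] <- 2L - f[i]; f }
  mosaic <- function() ifelse(rbinom(m, 1, 0.5) == 1, fA, fB)
  calls <- rbind(a1 = fA, a2 = noisy(fA), a3 = noisy(fA),
                 b1 = fB, b2 = noisy(fB), b3 = noisy(fB),
                 m1 = mosaic(), m2 = mosaic())
  g <- gm(calls, samples = rownames(calls))
  fit <- fit_ancestry(g, 2, seed = 5, reps = 3)
  top <- apply(fit$Q, 1, max)
  expect_true(all(top[1:6] > 0.99))
  expect_true(all(top[7:8] < 0.6))
  # the admixed label is exactly the >0.5 cut on the top coefficient
  expect_equal(unname(fit$group_call == "admixed"), unname(top <= 0.5))
  expect_true(all(fit$group_call[1:3] != "admixed"))
  expect_equal(length(unique(fit$group_call[1:3])), 1L)
})

test_that("ancestry loss is monotone non-increasing and Q stays on the simplex", {
  set.seed(44)
  g <- gm(matrix(sample(c(0L, 1L, 2L, NA), 30 * 40, TRUE), 30, 40))
  fit <- fit_ancestry(g, 3, seed = 1, reps = 1, max_iter = 50)
  expect_true(all(diff(fit$loss_trace) <= 1e-9))
  expect_equal(unname(rowSums(fit$Q)), rep(1, 30), tolerance = 1e-6)
  expect_true(all(fit$Q >= -1e-12))
  expect_true(all(fit$G >= 0 & fit$G <= 1))
  # reproducibility under a fixed seed
  fit2 <- fit_ancestry(g, 3, seed = 1, reps = 1, max_iter = 50)
  expect_identical(fit$Q, fit2$Q)
})

test_that("simplex projection returns the closest simplex point", {
  X <- rbind(c(0.5, 0.5, 0.5), c(-1, 2, 0.2), c(1, 0, 0), c(10, 1, 1))
  P <- varident:::.project_simplex_rows(X)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_equal(P[3, ], c(1, 0, 0))
  expect_equal(P[1, ], rep(1 / 3, 3))
})

test_that("cross-entropy selects the true number of groups", {
  cfg <- sim_config(n_markers = 300, n_varieties = 3, n_field_samples = 45,
                    misnaming_rate = 0, error_rate = 0.002, missing_rate = 0.02,
                    het_rate = 0, admixed_fraction = 0, seed = 11)
  lib <- generate_reference_library(cfg)
  fld <- generate_field_samples(lib, cfg)
  ks <- select_k(fld$genotypes, K_range = 1:5, mask_fraction = 0.1, seed = 2)
  expect_equal(ks$chosen_K, 3L)
  expect_true(all(is.finite(ks$cross_entropy_by_K$cross_entropy)))
  expect_true(all(ks$cross_entropy_by_K$cross_entropy > 0))

  # single homogeneous population: no K > 1 helps
  cfg1 <- sim_config(n_markers = 200, n_varieties = 1, n_field_samples = 30,
                     misnaming_rate = 0, error_rate = 0.01, missing_rate = 0,
                     het_rate = 0, admixed_fraction = 0, seed = 12)
  lib1 <- generate_reference_library(cfg1)
  fld1 <- generate_field_samples(lib1, cfg1)
  ks1 <- select_k(fld1$genotypes, K_range = 1:3, mask_fraction = 0.1, seed = 3)
  expect_equal(ks1$chosen_K, 1L)
})

test_that("adjusted Rand index matches the contingency-table formula", {
  expect_equal(compare_partitions(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  a <- c(1, 1, 1, 1); b <- 1:4
  expect_equal(compare_partitions(a, b), ari_oracle(a, b))
  set.seed(9)
  x <- sample(1:3, 30, TRUE); y <- sample(1:3, 30, TRUE)
  expect_equal(compare_partitions(x, y), ari_oracle(x, y))
  # permutation invariance of labels
  expect_equal(compare_partitions(x, c(3, 1, 2)[y]), compare_partitions(x, y))
  expect_error(compare_partitions(1:3, 1:4), "equal length")
})
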