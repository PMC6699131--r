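test_that("duplicate-profile sets are connected components, with chain flagging", {
  base <- rep(0L, 1000)
  mk <- function(loci) { v <- base; v[loci] <- 2L; v }
  calls <- rbind(A = base, B = mk(1), C = mk(1:2),  # A~B .999, B~C .999, A~C .998
                 D = mk(300:500))                   # far from everything
  g <- gm(calls, samples = rownames(calls))
  recs <- tibble::tibble(sample_id = rownames(calls), role = "reference",
                         reported_name = rownames(calls))
  ibs <- compute_ibs_matrix(g)
  sets <- detect_duplicate_profiles(ibs, recs, threshold = 0.9985)
  expect_equal(nrow(sets), 1L)
  expect_equal(sets$entries[[1]], c("A", "B", "C"))
  expect_false(sets$is_clique[1])        # A~C sits below the threshold

  # identical triple forms one clique; all-distinct library forms none
  calls2 <- rbind(X1 = base, X2 = base, X3 = base)
  recs2 <- tibble::tibble(sample_id = rownames(calls2), role = "reference",
                          reported_name = "X")
  sets2 <- detect_duplicate_profiles(
    compute_ibs_matrix(gm(calls2, samples = rownames(calls2))), recs2, 0.998)
  expect_equal(sets2$size, 3L)
  expect_true(sets2$is_clique)
  sets3 <- detect_duplicate_profiles(ibs, recs, threshold = 1.1 - 0.1)  # 1.0
  expect_equal(nrow(sets3), 0L)
})

test_that("audit classifies name/profile inconsistencies by hand construction", {
  set.seed(55)
  m <- 400
  r <- function() 2L * rbinom(m, 1, 0.5)
  pA <- r(); pB <- r(); pC <- r(); pD <- r()
  calls <- rbind(
    X1 = pA, X2 = pB,          # class A: same name+pedigree, distinct profiles
    Y = pC, Z = pC,            # class B: same profile, different names
    W = pD                     # consistent singleton
  )
  colnames(calls) <- sprintf("M%03d", seq_len(m))
  recs <- tibble::tibble(
    sample_id = rownames(calls), role = "reference",
    reported_name = c("X", "X", "Y", "Z", "W"),
    pedigree = c("p1", "p1", "p2", "p3", "p4"))
  ibs <- compute_ibs_matrix(geno_matrix(calls))
  aud <- audit_library(ibs, recs, threshold = 0.998)
  expect_equal(aud$classA, c("X1", "X2"))
  expect_equal(aud$classB, c("Y", "Z"))
  expect_equal(aud$fraction_classA, 2 / 5)
  expect_equal(aud$fraction_classB, 2 / 5)
  expect_equal(aud$fraction_inconsistent, 4 / 5)
  expect_equal(aud$n_before, 5L)
  expect_equal(aud$n_after, 5L)
})

test_that("exact duplicates are collapsed and incomplete entries excluded", {
  base <- rep(0L, 300); alt <- rep(2L, 300)
  calls <- rbind(K1 = base, K2 = base, L = alt, M = c(base[1:150], alt[1:150]))
  recs <- tibble::tibble(
    sample_id = rownames(calls), role = "reference",
    reported_name = c("K", "K", "L", NA),
    pedigree = c("pk", "pk", "pl", "pm"))
  ibs <- compute_ibs_matrix(gm(calls, samples = rownames(calls)))
  aud <- audit_library(ibs, recs, 0.998)
  expect_equal(aud$removed_duplicates, "K2")      # same name+pedigree+profile
  expect_equal(aud$excluded_incomplete, "M")      # missing name
  expect_equal(aud$n_after, 2L)
  expect_equal(length(aud$classA) + length(aud$classB), 0L)
})

test_that("landrace entries are exempt from class A counting", {
  set.seed(56)
  m <- 300
  r <- function() 2L * rbinom(m, 1, 0.5)
  calls <- rbind(L1 = r(), L2 = r())
  recs <- tibble::tibble(
    sample_id = c("L1", "L2"), role = "reference",
    reported_name = "WATANI", pedigree = "unknown ped",
    germplasm_group = "landrace")
  ibs <- compute_ibs_matrix(gm(calls, samples = rownames(calls)))
  aud <- audit_library(ibs, recs, 0.998)
  expect_equal(length(aud$classA), 0L)
})

test_that("audit recovers injected inconsistencies and ignores entry order", {
  cfg <- sim_config(n_markers = 400, n_varieties = 10, seed = 19,
                    n_discordant_dup = 2, n_aliases = 2, n_landraces = 1)
  lib <- generate_reference_library(cfg)
  ibs <- compute_ibs_matrix(lib$genotypes)
  aud <- audit_library(ibs, lib$records, 0.998)
  expect_setequal(aud$classA, lib$truth$classA_entries)
  expect_setequal(aud$classB, lib$truth$classB_entries)

  set.seed(3)
  shuf <- lib$records[sample(nrow(lib$records)), ]
  aud2 <- audit_library(ibs, shuf, 0.998)
  expect_setequal(aud2$classA, aud$classA)
  expect_setequal(aud2$classB, aud$classB)
  expect_equal(glance(aud2)$fraction_inconsistent,
               glance(aud)$fraction_inconsistent)
})

test_that("germplasm group assignment maps, defaults and rejects", {
  recs <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         role = "reference", reported_name = letters[1:4])
  tbl <- tibble::tibble(sample_id = c("a", "b", "c"),
                        germplasm_group = c("afghan_collection", "landrace",
                                            "released"))
  expect_warning(out <- assign_germplasm_groups(recs, tbl), "other_elite")
  expect_equal(out$germplasm_group, c("afghan_collection", "landrace",
                                      "released", "other_elite"))
  bad <- tibble::tibble(sample_id = "a", germplasm_group = "banana")
  expect_error(assign_germplasm_groups(recs, bad), "banana")
})
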