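test_that("config validation rejects bad rates and over-allocation", {
  expect_error(sim_config(misnaming_rate = 1.2), "must be in")
  expect_error(sim_config(n_varieties = 0), ">= 1")
  expect_error(sim_config(n_varieties = 3, n_landraces = 2, n_concordant_dup = 2),
               "exceed")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_markers = 120, n_varieties = 6, n_field_samples = 30,
                    n_landraces = 1, n_concordant_dup = 1, seed = 9)
  a <- generate_reference_library(cfg)
  b <- generate_reference_library(cfg)
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  fa <- generate_field_samples(a, cfg)
  fb <- generate_field_samples(b, cfg)
  expect_identical(unclass(fa$genotypes), unclass(fb$genotypes))
  expect_identical(fa$truth, fb$truth)
  ra <- generate_technical_replicates(a, 4, 3, 0.001, seed = 2)
  rb <- generate_technical_replicates(b, 4, 3, 0.001, seed = 2)
  expect_identical(unclass(ra$genotypes), unclass(rb$genotypes))
})

test_that("founders are homozygous and distinct; concordant sources identical", {
  cfg <- sim_config(n_markers = 100, n_varieties = 5, n_concordant_dup = 1,
                    concordant_copies = 3, seed = 5)
  lib <- generate_reference_library(cfg)
  expect_true(all(lib$founders %in% c(0L, 2L)))
  ibs <- compute_ibs_matrix(gm(lib$founders))
  off <- ibs$ibs[upper.tri(ibs$ibs)]
  expect_true(all(off < 1))
  dup_ids <- grep("VAR-01_s", rownames(lib$genotypes), value = TRUE)
  expect_length(dup_ids, 3)
  sub <- unclass(lib$genotypes)[dup_ids, ]
  expect_true(all(sub[1, ] == sub[2, ]) && all(sub[2, ] == sub[3, ]))
})

test_that("noise-free field samples copy their founder and name exactly", {
  cfg <- sim_config(n_markers = 80, n_varieties = 4, n_field_samples = 25,
                    misnaming_rate = 0, error_rate = 0, missing_rate = 0,
                    het_rate = 0, admixed_fraction = 0, seed = 3)
  lib <- generate_reference_library(cfg)
  fld <- generate_field_samples(lib, cfg)
  expect_false(any(fld$truth$is_misnamed))
  for (i in seq_len(nrow(fld$truth))) {
    expect_equal(unname(unclass(fld$genotypes)[i, ]),
                 unname(lib$founders[fld$truth$true_variety[i], ]))
  }
})

test_that("misnaming rate is realized within binomial tolerance", {
  cfg <- sim_config(n_markers = 10, n_varieties = 6, n_field_samples = 1000,
                    misnaming_rate = 0.4, error_rate = 0, missing_rate = 0,
                    het_rate = 0, admixed_fraction = 0, seed = 21)
  lib <- generate_reference_library(cfg)
  fld <- generate_field_samples(lib, cfg)
  # binomial: sd = sqrt(0.4 * 0.6 / 1000) ~ 0.0155; +-0.04 is ~2.6 sd
  expect_lt(abs(mean(fld$truth$is_misnamed) - 0.4), 0.04)
  expect_equal(fld$truth$is_misnamed,
               fld$truth$reported_name != fld$truth$true_variety)
})

test_that("full admixture yields ~50% locus sharing with each parent", {
  cfg <- sim_config(n_markers = 2000, n_varieties = 2, n_field_samples = 20,
                    misnaming_rate = 0, error_rate = 0, missing_rate = 0,
                    het_rate = 0, admixed_fraction = 1, seed = 8)
  lib <- generate_reference_library(cfg)
  fld <- generate_field_samples(lib, cfg)
  X <- unclass(fld$genotypes)
  # only count loci where the parents differ: there the mosaic picks one of
  # the two with probability 1/2
  diff_loci <- lib$founders[1, ] != lib$founders[2, ]
  for (i in 1:nrow(X)) {
    frac_a <- mean(X[i, diff_loci] == lib$founders[1, diff_loci])
    expect_lt(abs(frac_a - 0.5), 0.06)
  }
})

test_that("per-allele error produces the closed-form discordance 2e(1-e)", {
  set.seed(13)
  e <- 0.02
  founder <- 2L * rbinom(20000, 1, 0.5)
  noisy <- varident:::.flip_alleles(founder, e)
  disc <- mean(noisy != founder)
  expected <- 2 * e * (1 - e) + e^2  # het miscall + double flip
  expect_lt(abs(disc - expected), 0.004)
})

test_that("replicate generation enforces its preconditions", {
  cfg <- sim_config(n_markers = 50, n_varieties = 3, seed = 1)
  lib <- generate_reference_library(cfg)
  expect_error(generate_technical_replicates(lib, 3, copies_per_group = 1),
               ">= 2")
  expect_error(generate_technical_replicates(lib, 10, 3), "exceeds")
  reps <- generate_technical_replicates(lib, 3, 3, error_rate = 0, seed = 1)
  ibs <- compute_ibs_matrix(reps$genotypes)
  thr <- calibrate_thresholds(ibs, reps$records)
  expect_equal(thr$initial, 1)
  expect_equal(thr$minimum, 1)
})
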