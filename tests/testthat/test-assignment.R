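test_that("candidate search sorts by IBS then id and respects the threshold", {
  fx <- make_rule_fixture()
  ibs <- compute_ibs_matrix(fx$genotypes)
  # f_r2 copies founder B: all three concordant B sources and the alias G
  # match at IBS 1, ordered by id among ties
  cands <- find_candidates("f_r2", ibs, fx$records, 0.998)
  expect_equal(cands$reference_id, c("B_s1", "B_s2", "B_s3", "G"))
  expect_true(all(diff(cands$ibs) <= 0))
  # nothing matches a far-away sample
  expect_equal(nrow(find_candidates("f_r5a", ibs, fx$records, 0.998)), 0L)
})

test_that("cohesion requires every within-set pair to reach the threshold", {
  fx <- make_rule_fixture()
  ibs <- compute_ibs_matrix(fx$genotypes)
  expect_true(cohesion(c("f_r5a", "f_r5b"), ibs, 0.991))
  expect_false(cohesion(c("f_r6a", "f_r6b"), ibs, 0.991))
  expect_true(cohesion("f_r6a", ibs, 0.991))  # singleton convention
})

test_that("each decision rule fires on its intended configuration", {
  fx <- make_rule_fixture()
  ibs <- compute_ibs_matrix(fx$genotypes)
  asg <- apply_decision_rules(ibs, fx$records, fx$thresholds)
  expect_setequal(asg$sample_id, fx$records$sample_id[fx$records$role == "field"])
  got <- function(id) asg[asg$sample_id == id, ]

  r1 <- got("f_r1")
  expect_equal(r1$status, "identified")
  expect_equal(r1$rule, 1L)
  expect_equal(r1$assigned_name, "A")
  expect_equal(r1$threshold_used, "initial")

  r2 <- got("f_r2")
  expect_equal(r2$status, "identified")
  expect_equal(r2$rule, 2L)
  expect_equal(r2$assigned_name, "B")

  r3 <- got("f_r3")
  expect_equal(r3$status, "identified")
  expect_equal(r3$rule, 3L)
  expect_equal(r3$assigned_name, "C")

  r4 <- got("f_r4a")
  expect_equal(r4$status, "kept_reported")
  expect_equal(r4$rule, 4L)
  expect_equal(r4$assigned_name, "D")

  r5 <- got("f_r5a")
  expect_equal(r5$status, "kept_reported")
  expect_equal(r5$rule, 5L)
  expect_equal(r5$assigned_name, "E")

  r6 <- got("f_r6a")
  expect_equal(r6$status, "unknown")
  expect_equal(r6$rule, 6L)
  expect_true(is.na(r6$assigned_name))
})

test_that("a tie between equally supported names is flagged ambiguous, not rule 6", {
  set.seed(77)
  m <- 100
  h <- 2L * rbinom(m, 1, 0.5)
  calls <- rbind(H = h, I = h, fx = h)  # two single-source names, same profile
  colnames(calls) <- sprintf("M%03d", seq_len(m))
  g <- geno_matrix(calls)
  recs <- tibble::tibble(sample_id = c("H", "I", "fx"),
                         role = c("reference", "reference", "field"),
                         reported_name = c("H", "I", "H"))
  asg <- apply_decision_rules(compute_ibs_matrix(g), recs,
                              identity_thresholds(0.998, 0.991))
  expect_equal(asg$status, "ambiguous")
  expect_true(is.na(asg$rule))
  expect_true(is.na(asg$assigned_name))
})

test_that("assignments are invariant to sample order and statuses reconcile", {
  fx <- make_rule_fixture()
  ibs <- compute_ibs_matrix(fx$genotypes)
  asg <- apply_decision_rules(ibs, fx$records, fx$thresholds)
  set.seed(1)
  shuf <- fx$records[sample(nrow(fx$records)), ]
  asg2 <- apply_decision_rules(ibs, shuf, fx$thresholds)
  expect_equal(dplyr::arrange(asg, sample_id), dplyr::arrange(asg2, sample_id),
               ignore_attr = TRUE)
  counts <- table(asg$status)
  expect_equal(sum(counts), sum(fx$records$role == "field"))
})

test_that("name normalization trims, folds case and applies synonyms", {
  syn <- tibble::tibble(raw = c("GUL96", "CHONT#1", "CHONTE#1#1"),
                        canonical = c("GUL-96", "CHONTE#1", "CHONTE#1"))
  expect_equal(normalize_name("GUL96", syn), "GUL-96")
  expect_equal(normalize_name("  roshan-96 "), "ROSHAN-96")
  expect_equal(normalize_name("XYZ", syn), "XYZ")
  expect_equal(normalize_name(c("chont#1", NA), syn), c("CHONTE#1", NA))
})

test_that("agreement with reported names counts correct, incorrect and unknown", {
  fx <- make_rule_fixture()
  ibs <- compute_ibs_matrix(fx$genotypes)
  asg <- apply_decision_rules(ibs, fx$records, fx$thresholds)
  ag <- compare_with_reported(asg, fx$records)
  # f_r1..f_r5b carry their true names (7 correct); f_r6a/b undetermined
  expect_equal(ag$n_correct, 7L)
  expect_equal(ag$n_incorrect, 0L)
  expect_equal(ag$n_unknown, 2L)
  expect_equal(ag$n_total, 9L)
  expect_true(all(c("reported", "determined", "n") %in% names(ag$flow)))

  # synonym-mediated match counts as correct
  recs2 <- fx$records
  recs2$reported_name[recs2$sample_id == "f_r1"] <- "A-SYN"
  syn <- tibble::tibble(raw = "A-SYN", canonical = "A")
  ag2 <- compare_with_reported(asg, recs2, synonyms = syn)
  expect_equal(ag2$n_correct, 7L)
  ag3 <- compare_with_reported(asg, recs2)
  expect_equal(ag3$n_correct, 6L)
  expect_equal(ag3$n_incorrect, 1L)
})

test_that("trait-marker summaries report the majority allele and discordance", {
  asg <- tibble::tibble(
    sample_id = c("f1", "f2", "f3", "f4", "f5"),
    status = c(rep("identified", 4), "unknown"),
    assigned_name = c("V1", "V1", "V1", "V1", NA))
  calls <- tibble::tibble(
    sample_id = c("f1", "f2", "f3", "f4"),
    marker = "Rht-B1",
    allele = c("Rht-B1b", "Rht-B1b", "Rht-B1b", "Rht-B1a"))
  out <- annotate_trait_markers(asg, calls)
  expect_equal(out$allele, "Rht-B1b")
  expect_equal(out$n_samples, 4L)
  expect_equal(out$discordance, 1L)

  # unanimous allele, zero discordance
  out2 <- annotate_trait_markers(asg, dplyr::mutate(calls, allele = "Rht-B1b"))
  expect_equal(out2$discordance, 0L)

  # stray sample warns and is excluded; unknown samples contribute nothing
  calls3 <- dplyr::add_row(calls, sample_id = "ghost", marker = "Rht-B1",
                           allele = "Rht-B1a")
  expect_warning(out3 <- annotate_trait_markers(asg, calls3), "excluded")
  expect_equal(out3$n_samples, 4L)
  calls4 <- tibble::tibble(sample_id = "f5", marker = "Rht-B1", allele = "x")
  expect_equal(nrow(annotate_trait_markers(asg, calls4)), 0L)
})

test_that("noise-free synthetic samples are all identified by rule 1", {
  cfg <- sim_config(n_markers = 300, n_varieties = 6, n_field_samples = 40,
                    misnaming_rate = 0.3, error_rate = 0, missing_rate = 0,
                    het_rate = 0, admixed_fraction = 0, seed = 17)
  lib <- generate_reference_library(cfg)
  fld <- generate_field_samples(lib, cfg)
  g <- geno_matrix(rbind(unclass(lib$genotypes), unclass(fld$genotypes)))
  recs <- dplyr::bind_rows(lib$records, fld$records)
  ibs <- compute_ibs_matrix(g)
  asg <- apply_decision_rules(ibs, recs, identity_thresholds(0.998, 0.991))
  expect_true(all(asg$status == "identified"))
  expect_true(all(asg$rule == 1L))
  expect_equal(asg$assigned_name[match(fld$truth$sample_id, asg$sample_id)],
               fld$truth$true_variety)
})
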