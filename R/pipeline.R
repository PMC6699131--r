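#' Configure an end-to-end pipeline run
#'
#' Either synthetic (a [sim_config()] drives the generators) or file-based
#' (paths to genotype and metadata tables). Referenced input paths must
#' exist at validation time.
#'
#' @param out_dir directory for stage artifacts (created if needed).
#' @param sim a [sim_config()] for a synthetic run, or `NULL`.
#' @param genotype_path,metadata_path input tables for a file-based run
#'   (ignored when `sim` is given).
#' @param qc a [qc_params()].
#' @param thresholds optional [identity_thresholds()] override; when
#'   `NULL` they are calibrated from the replicate samples.
#' @param synonym_path optional synonym CSV (`raw`, `canonical`).
#' @param k_range candidate K values for ancestry model selection.
#' @param n_clusters flat cluster count for the Ward cut; defaults to the
#'   chosen K.
#' @param seed integer seed for all stochastic stages.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, genotype_path = NULL,
                            metadata_path = NULL, qc = qc_params(),
                            thresholds = NULL, synonym_path = NULL,
                            k_range = 1:10, n_clusters = NULL, seed = 1L) {
  if (is.null(sim)) {
    for (p in c(genotype_path, metadata_path)) {
      if (is.null(p) || !file.exists(p)) {
        rlang::abort(sprintf("Input file not found: '%s'.",
                             if (is.null(p)) "<missing path>" else p))
      }
    }
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  if (!is.null(synonym_path) && !file.exists(synonym_path)) {
    rlang::abort(sprintf("Synonym table not found: '%s'.", synonym_path))
  }
  structure(list(out_dir = out_dir, sim = sim,
                 genotype_path = genotype_path, metadata_path = metadata_path,
                 qc = qc, thresholds = thresholds, synonym_path = synonym_path,
                 k_range = k_range, n_clusters = n_clusters,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full identification pipeline
#'
#' Chains the stages simulate (or load) -> QC -> IBS -> threshold
#' calibration -> assignment -> library audit -> clustering/ancestry ->
#' diversity, writing each stage's artifact under `out_dir` and returning
#' a manifest. Reruns with the same config and seed produce byte-identical
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return A tibble manifest (`stage`, `artifact`, `path`), invisibly
#'   carrying the stage results in attribute `"results"`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list()
  results <- list()
  art <- function(stage, artifact, path) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, artifact = artifact, path = path)
  }
  pth <- function(...) file.path(config$out_dir, ...)
  synonyms <- if (!is.null(config$synonym_path)) {
    readr::read_csv(config$synonym_path, show_col_types = FALSE)
  } else NULL

  # stage 1: inputs
  if (!is.null(config$sim)) {
    say("simulate: generating synthetic library, field samples and replicates (seed %d)",
        config$sim$seed)
    lib <- generate_reference_library(config$sim)
    fld <- generate_field_samples(lib, config$sim)
    rep <- generate_technical_replicates(
      lib, config$sim$n_replicate_groups,
      config$sim$replicates_per_group, config$sim$error_rate,
      seed = config$sim$seed + 7L)
    calls <- rbind(unclass(lib$genotypes), unclass(fld$genotypes),
                   unclass(rep$genotypes))
    g <- geno_matrix(calls)
    records <- dplyr::bind_rows(lib$records, fld$records, rep$records)
    write_genotype_table(g, pth("genotypes.csv"))
    readr::write_csv(records, pth("metadata.csv"), progress = FALSE)
    readr::write_csv(fld$truth, pth("truth.csv"), progress = FALSE)
    art("simulate", "genotypes", pth("genotypes.csv"))
    art("simulate", "metadata", pth("metadata.csv"))
    art("simulate", "truth", pth("truth.csv"))
    results$sim <- list(library = lib, field = fld, replicates = rep)
  } else {
    say("load: reading %s", config$genotype_path)
    g <- read_genotype_table(config$genotype_path)
    records <- read_sample_metadata(config$metadata_path)
  }

  # stage 2: QC
  qc <- apply_qc(g, config$qc)
  say("qc: %d samples x %d markers survive", nrow(qc$genotypes), ncol(qc$genotypes))
  write_report(tidy(qc$report), pth("qc_report.csv"))
  art("qc", "qc_report", pth("qc_report.csv"))
  g <- qc$genotypes
  records <- dplyr::filter(records, .data$sample_id %in% rownames(g))
  results$qc <- qc

  # stage 3: IBS
  ibs <- compute_ibs_matrix(g)
  utils::write.csv(ibs$ibs, pth("ibs_matrix.csv"))
  art("ibs", "ibs_matrix", pth("ibs_matrix.csv"))
  results$ibs <- ibs

  # stage 4: thresholds
  thr <- config$thresholds
  if (is.null(thr)) {
    thr <- calibrate_thresholds(ibs, records)
    say("thresholds: initial %.4f, minimum %.4f (%d replicate pairs)",
        thr$initial, thr$minimum, thr$n_pairs)
  }
  write_report(glance(thr), pth("thresholds.json"), format = "json")
  art("thresholds", "thresholds", pth("thresholds.json"))
  results$thresholds <- thr

  # stage 5: assignment
  asg <- apply_decision_rules(ibs, records, thr, synonyms)
  agree <- compare_with_reported(asg, records, synonyms)
  say("assign: %d identified, %d kept reported, %d unknown, %d ambiguous",
      sum(asg$status == "identified"), sum(asg$status == "kept_reported"),
      sum(asg$status == "unknown"), sum(asg$status == "ambiguous"))
  write_report(asg, pth("assignments.csv"))
  write_report(glance(agree), pth("agreement.json"), format = "json")
  write_report(agree$flow, pth("agreement_flow.csv"))
  art("assign", "assignments", pth("assignments.csv"))
  art("assign", "agreement", pth("agreement.json"))
  art("assign", "agreement_flow", pth("agreement_flow.csv"))
  results$assignments <- asg
  results$agreement <- agree

  # stage 6: library audit
  audit <- audit_library(ibs, records, thr$initial, synonyms)
  write_report(glance(audit), pth("library_audit.json"), format = "json")
  art("audit", "library_audit", pth("library_audit.json"))
  results$audit <- audit

  # stage 7: clustering + ancestry on the field samples
  fld_ids <- records$sample_id[records$role == "field"]
  g_fld <- g[fld_ids, , drop = FALSE]
  ibs_fld <- compute_ibs_matrix(g_fld)
  ks <- select_k(g_fld, K_range = config$k_range, seed = config$seed)
  say("cluster: cross-entropy plateau at K = %d", ks$chosen_K)
  fit <- fit_ancestry(g_fld, ks$chosen_K, seed = config$seed)
  nk <- if (is.null(config$n_clusters)) ks$chosen_K else config$n_clusters
  dend <- ward_cluster(ibs_fld, n_clusters = nk)
  write_report(tidy(ks), pth("cross_entropy.csv"))
  write_report(tidy(fit), pth("ancestry_q.csv"))
  dendrogram_newick(dend, pth("dendrogram.nwk"))
  art("cluster", "cross_entropy", pth("cross_entropy.csv"))
  art("cluster", "ancestry_q", pth("ancestry_q.csv"))
  art("cluster", "dendrogram", pth("dendrogram.nwk"))
  results$kselect <- ks
  results$ancestry <- fit
  results$dendrogram <- dend

  # stage 8: diversity over reference entries with germplasm groups
  ref_records <- dplyr::filter(records, .data$role == "reference",
                               !is.na(.data$germplasm_group))
  if (nrow(ref_records) >= 2) {
    g_ref <- g[ref_records$sample_id, , drop = FALSE]
    div <- group_diversity(g_ref, ref_records)
    mds <- classical_mds(mrd_matrix(g_ref), n_dims = 2)
    write_report(div, pth("diversity.csv"))
    write_report(mds$points, pth("mds_coordinates.csv"))
    art("diversity", "diversity", pth("diversity.csv"))
    art("diversity", "mds_coordinates", pth("mds_coordinates.csv"))
    results$diversity <- div
    results$mds <- mds
  }

  out <- dplyr::bind_rows(manifest)
  attr(out, "results") <- results
  invisible(out)
}

#' Reproduce the deposited-study headline numbers
#'
#' Runs the identification pipeline on the deposited genotype and metadata
#' tables of the original survey (download the accession and export it to
#' the canonical wide-CSV/metadata-CSV layout first) and returns the
#' headline counts: samples matched at the initial threshold, UNKNOWN
#' samples, correctly reported names, and distinct determined varieties.
#'
#' @param accession_dir directory containing `genotypes.csv` and
#'   `metadata.csv` in the package's canonical dialects (and optionally
#'   `synonyms.csv`).
#' @return A tibble with `n_at_initial`, `n_unknown`, `n_correct`,
#'   `n_varieties_determined`.
#' @export
reproduce_study <- function(accession_dir) {
  gp <- file.path(accession_dir, "genotypes.csv")
  mp <- file.path(accession_dir, "metadata.csv")
  if (!file.exists(gp) || !file.exists(mp)) {
    rlang::abort(sprintf(
      "Deposited study data not found under '%s' (need genotypes.csv and metadata.csv).",
      accession_dir))
  }
  sp <- file.path(accession_dir, "synonyms.csv")
  cfg <- pipeline_config(out_dir = tempfile("reproduction"),
                         genotype_path = gp, metadata_path = mp,
                         synonym_path = if (file.exists(sp)) sp else NULL)
  man <- run_pipeline(cfg, quiet = TRUE)
  res <- attr(man, "results")
  asg <- res$assignments
  agree <- res$agreement
  tibble::tibble(
    n_at_initial = sum(asg$threshold_used == "initial" &
                         asg$status == "identified"),
    n_unknown = sum(asg$status %in% c("unknown", "ambiguous")),
    n_correct = agree$n_correct,
    n_varieties_determined = dplyr::n_distinct(asg$assigned_name[
      asg$status %in% c("identified", "kept_reported")])
  )
}
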