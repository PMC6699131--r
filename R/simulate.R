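#' Simulation settings for synthetic genotype data
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce
#' the structure of a DArTSeq varietal-identification study: 5203
#' biallelic markers, fully homozygous variety founders with population
#' alternate-allele frequencies drawn from Uniform(0.05, 0.95), a field
#' collection of 560 samples with per-allele genotyping error 0.001, 5%
#' missing calls, ~1% heterozygote miscalls, 8% admixed samples, a 41.5%
#' misreporting rate for farmer-declared names, and 29 technical-replicate
#' triplicate groups.
#'
#' @param n_markers number of biallelic SNP markers.
#' @param n_varieties number of distinct variety founders in the library
#'   (including `n_landraces` heterogeneous landraces).
#' @param freq_range range of the per-marker population alternate-allele
#'   frequency (drawn uniformly).
#' @param n_field_samples number of field samples to draw.
#' @param composition optional named numeric vector of sampling weights per
#'   variety name; default uniform over founders.
#' @param misnaming_rate probability a field sample's reported name differs
#'   from its true variety.
#' @param error_rate per-allele genotyping error (each of the two allele
#'   calls flips independently with this probability).
#' @param missing_rate per-call missingness probability.
#' @param het_rate probability a call is miscalled heterozygous.
#' @param admixed_fraction fraction of field samples that are 50/50
#'   locus-wise mosaics of two founders.
#' @param n_replicate_groups,replicates_per_group technical replicate design.
#' @param n_concordant_dup number of varieties entered in the library with
#'   `concordant_copies` identical seed sources.
#' @param concordant_copies copies per concordant-duplicate variety.
#' @param n_discordant_dup number of varieties with `discordant_copies`
#'   sources whose profiles disagree (perturbed at `discordant_perturb`
#'   of loci) — same name and pedigree, distinct profiles.
#' @param discordant_copies,discordant_perturb see above.
#' @param n_many_dup number of varieties duplicated `many_copies` (>= 4)
#'   times with mutually discordant profiles.
#' @param many_copies copies per many-duplicate variety.
#' @param n_aliases number of extra entries that copy an existing founder
#'   profile under a new name and pedigree (same profile, different
#'   identity).
#' @param n_landraces number of founders treated as heterogeneous
#'   landraces, each entered with `landrace_sources` sources perturbed at
#'   `landrace_heterogeneity` of loci.
#' @param landrace_sources,landrace_heterogeneity see above.
#' @param seed integer seed; all randomness in the generators flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 5203, n_varieties = 20,
                       freq_range = c(0.05, 0.95),
                       n_field_samples = 560, composition = NULL,
                       misnaming_rate = 0.415, error_rate = 0.001,
                       missing_rate = 0.05, het_rate = 0.01,
                       admixed_fraction = 0.08,
                       n_replicate_groups = 29, replicates_per_group = 3,
                       n_concordant_dup = 0, concordant_copies = 3,
                       n_discordant_dup = 0, discordant_copies = 2,
                       discordant_perturb = 0.05,
                       n_many_dup = 0, many_copies = 4,
                       n_aliases = 0,
                       n_landraces = 0, landrace_sources = 2,
                       landrace_heterogeneity = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c("misnaming_rate", "error_rate", "missing_rate", "het_rate",
             "admixed_fraction", "discordant_perturb", "landrace_heterogeneity")
  for (r in rates) {
    v <- cfg[[r]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      rlang::abort(sprintf("`%s` must be in [0, 1].", r))
    }
  }
  if (n_varieties < 1) rlang::abort("`n_varieties` must be >= 1.")
  if (n_markers < 1) rlang::abort("`n_markers` must be >= 1.")
  n_special <- n_concordant_dup + n_discordant_dup + n_many_dup + n_landraces
  if (n_special > n_varieties) {
    rlang::abort("Duplicated/landrace variety counts exceed `n_varieties`.")
  }
  if (!is.null(composition)) {
    if (any(composition < 0) || sum(composition) <= 0) {
      rlang::abort("`composition` weights must be >= 0 and sum > 0.")
    }
  }
  structure(cfg, class = "sim_config")
}

# flip each of the 2 allele calls of dosage vector d independently w.p. e
.flip_alleles <- function(d, e) {
  a1 <- as.integer(d >= 1L)
  a2 <- as.integer(d == 2L)
  r1 <- stats::rbinom(length(d), 1L, e)
  r2 <- stats::rbinom(length(d), 1L, e)
  abs(a1 - r1) + abs(a2 - r2)
}

# perturb `frac` of loci of a homozygous dosage vector (flip 0 <-> 2)
.perturb_loci <- function(d, frac) {
  n <- length(d)
  k <- round(frac * n)
  if (k == 0) return(d)
  idx <- sample.int(n, k)
  d[idx] <- 2L - d[idx]
  d
}

#' Generate a synthetic reference library
#'
#' Each variety receives a distinct fully homozygous founder genotype drawn
#' from per-marker population allele frequencies. Optionally, varieties are
#' entered with multiple seed sources — identical (concordant), perturbed
#' (discordant: same name/pedigree, distinct profile), or many-fold
#' discordant — plus alias entries (same profile, different name/pedigree)
#' and heterogeneous landraces. The injected inconsistencies are returned
#' as ground truth for audit-recovery checks.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_library` with elements `genotypes`
#'   ([geno_matrix()]), `records` (metadata tibble), `founders` (variety x
#'   marker dosage matrix), `freqs` (population alternate-allele
#'   frequencies) and `truth` (list with `classA_entries`,
#'   `classB_entries`).
#' @export
generate_reference_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_markers
  nv <- config$n_varieties
  p <- stats::runif(m, config$freq_range[1], config$freq_range[2])
  founders <- matrix(2L * stats::rbinom(nv * m, 1L, rep(p, each = nv)),
                     nrow = nv, ncol = m)
  n_plain_needed <- nv - config$n_landraces
  v_names <- c(sprintf("VAR-%02d", seq_len(n_plain_needed)),
               if (config$n_landraces > 0)
                 sprintf("WATANI-%02d", seq_len(config$n_landraces)))
  rownames(founders) <- v_names
  marker_ids <- sprintf("SNP%05d", seq_len(m))
  colnames(founders) <- marker_ids

  # roles of non-landrace varieties, in order
  kind <- rep("plain", nv)
  if (config$n_landraces > 0) {
    kind[(nv - config$n_landraces + 1):nv] <- "landrace"
  }
  assign_kind <- function(kind, what, count) {
    free <- which(kind == "plain")
    if (count > 0) kind[free[seq_len(count)]] <- what
    kind
  }
  kind <- assign_kind(kind, "concordant", config$n_concordant_dup)
  kind <- assign_kind(kind, "discordant", config$n_discordant_dup)
  kind <- assign_kind(kind, "many", config$n_many_dup)

  rows <- list(); ids <- character(); recs <- list()
  classA <- character(); classB <- character()
  pedigree_of <- stats::setNames(sprintf("P%02dA/P%02dB", seq_len(nv), seq_len(nv)),
                                 v_names)
  add_entry <- function(id, geno, name, pedigree, group, year) {
    rows[[length(rows) + 1]] <<- geno
    ids[length(ids) + 1] <<- id
    recs[[length(recs) + 1]] <<- tibble::tibble(
      sample_id = id, role = "reference", reported_name = name,
      pedigree = pedigree, germplasm_group = group,
      release_year = year)
  }
  years <- sample(1993:2013, nv, replace = TRUE)
  for (v in seq_len(nv)) {
    nm <- v_names[v]; fd <- founders[v, ]; ped <- pedigree_of[nm]
    grp <- if (kind[v] == "landrace") "landrace" else "released"
    yr <- if (grp == "released") years[v] else NA_integer_
    n_src <- switch(kind[v],
                    plain = 1L,
                    concordant = config$concordant_copies,
                    discordant = config$discordant_copies,
                    many = config$many_copies,
                    landrace = config$landrace_sources)
    for (s in seq_len(n_src)) {
      geno <- fd
      if (kind[v] == "discordant" && s > 1) {
        geno <- .perturb_loci(fd, config$discordant_perturb)
      } else if (kind[v] == "many" && s > 1) {
        geno <- .perturb_loci(fd, config$discordant_perturb)
      } else if (kind[v] == "landrace") {
        geno <- .perturb_loci(fd, config$landrace_heterogeneity)
      }
      id <- if (n_src == 1) nm else sprintf("%s_s%d", nm, s)
      add_entry(id, geno, nm, ped, grp, yr)
      if (kind[v] %in% c("discordant", "many")) classA <- c(classA, id)
    }
  }
  if (config$n_aliases > 0) {
    plain <- which(kind == "plain")
    if (!length(plain)) rlang::abort("Aliases require at least one plain variety.")
    src <- rep_len(plain, config$n_aliases)
    for (a in seq_len(config$n_aliases)) {
      v <- src[a]
      id <- sprintf("ALIAS-%02d", a)
      add_entry(id, founders[v, ], sprintf("ALIAS-%02d", a),
                sprintf("PX%02dA/PX%02dB", a, a), "other_elite", NA_integer_)
      # plain varieties are entered once under their own name as the id
      classB <- c(classB, id, v_names[v])
    }
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- ids
  colnames(calls) <- marker_ids
  records <- validate_sample_records(dplyr::bind_rows(recs))
  structure(list(
    genotypes = geno_matrix(calls),
    records = records,
    founders = founders,
    freqs = p,
    truth = list(classA_entries = unique(classA),
                 classB_entries = unique(classB))
  ), class = "sim_library")
}

#' Generate synthetic field samples with ground truth
#'
#' Each field sample copies its true variety's founder genotype, then
#' accumulates per-allele genotyping error, heterozygote miscalls and
#' missing calls. A configurable fraction of samples are 50/50 locus-wise
#' mosaics of two founders (admixed). The farmer-reported name equals the
#' true name with probability `1 - misnaming_rate`, otherwise a different
#' name drawn uniformly from the other variety names plus a vague
#' `"LOCAL"` label.
#'
#' @param library a `sim_library` from [generate_reference_library()].
#' @param config the same [sim_config()].
#' @return A list of class `sim_field` with `genotypes`, `records` and
#'   `truth` (tibble: `sample_id`, `true_variety`, `second_parent`,
#'   `is_admixed`, `reported_name`, `is_misnamed`).
#' @export
generate_field_samples <- function(library, config) {
  stopifnot(inherits(library, "sim_library"), inherits(config, "sim_config"))
  founders <- library$founders
  if (nrow(founders) == 0) rlang::abort("Reference library is empty.")
  set.seed(config$seed + 1000003L)
  nm <- rownames(founders)
  w <- config$composition
  if (is.null(w)) {
    w <- stats::setNames(rep(1, length(nm)), nm)
  } else {
    unknown <- setdiff(names(w), nm)
    if (length(unknown)) {
      rlang::abort(sprintf("`composition` references unknown variety '%s'.",
                           unknown[1]))
    }
    w <- w[w > 0]
  }
  n <- config$n_field_samples
  m <- ncol(founders)
  true_v <- sample(names(w), n, replace = TRUE, prob = w)
  n_adm <- floor(config$admixed_fraction * n)
  is_adm <- c(rep(TRUE, n_adm), rep(FALSE, n - n_adm))
  second <- rep(NA_character_, n)
  calls <- founders[true_v, , drop = FALSE]
  if (n_adm > 0 && length(nm) > 1) {
    for (i in seq_len(n_adm)) {
      second[i] <- sample(setdiff(nm, true_v[i]), 1)
      mask <- stats::rbinom(m, 1L, 0.5) == 1L
      calls[i, mask] <- founders[second[i], mask]
    }
  }
  if (config$error_rate > 0) {
    calls[] <- .flip_alleles(as.integer(calls), config$error_rate)
  }
  if (config$het_rate > 0) {
    hit <- matrix(stats::rbinom(n * m, 1L, config$het_rate) == 1L, n, m)
    calls[hit] <- 1L
  }
  if (config$missing_rate > 0) {
    gone <- matrix(stats::rbinom(n * m, 1L, config$missing_rate) == 1L, n, m)
    calls[gone] <- NA_integer_
  }
  reported <- true_v
  mis <- stats::runif(n) < config$misnaming_rate
  pool <- c(nm, "LOCAL")
  for (i in which(mis)) {
    reported[i] <- sample(setdiff(pool, true_v[i]), 1)
  }
  ids <- sprintf("FLD%04d", seq_len(n))
  rownames(calls) <- ids
  provinces <- sample(c("Herat", "Nangarhar", "Kabul", "Balkh"), n, replace = TRUE)
  records <- validate_sample_records(tibble::tibble(
    sample_id = ids, role = "field", reported_name = reported,
    province = provinces))
  truth <- tibble::tibble(
    sample_id = ids, true_variety = true_v, second_parent = second,
    is_admixed = is_adm, reported_name = reported,
    is_misnamed = reported != true_v)
  structure(list(genotypes = geno_matrix(calls), records = records,
                 truth = truth), class = "sim_field")
}

#' Generate technical replicate sets
#'
#' Re-genotypes randomly chosen library entries `copies_per_group` times,
#' each copy with independent per-allele error, mimicking the same DNA run
#' through the genotyping platform repeatedly. Within-group discordance is
#' the empirical genotyping-error signal from which identity thresholds
#' are calibrated.
#'
#' @param library a `sim_library`.
#' @param n_groups number of replicate groups (must not exceed the number
#'   of library founders).
#' @param copies_per_group copies per group, at least 2 (default 3, i.e.
#'   triplicates).
#' @param error_rate per-allele flip probability per copy.
#' @param seed integer seed.
#' @return A list of class `sim_replicates` with `genotypes` and `records`
#'   (role `"replicate"`, `replicate_group` set).
#' @export
generate_technical_replicates <- function(library, n_groups,
                                          copies_per_group = 3,
                                          error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(library, "sim_library"))
  if (copies_per_group < 2) {
    rlang::abort("`copies_per_group` must be >= 2.")
  }
  founders <- library$founders
  if (n_groups > nrow(founders)) {
    rlang::abort("`n_groups` exceeds the number of library entries.")
  }
  set.seed(seed)
  picks <- sample(rownames(founders), n_groups)
  n <- n_groups * copies_per_group
  m <- ncol(founders)
  calls <- matrix(NA_integer_, n, m)
  ids <- character(n); grp <- character(n); src <- character(n)
  k <- 1
  for (g in seq_len(n_groups)) {
    fd <- founders[picks[g], ]
    for (cc in seq_len(copies_per_group)) {
      calls[k, ] <- .flip_alleles(fd, error_rate)
      ids[k] <- sprintf("REP%02d_%d", g, cc)
      grp[k] <- sprintf("RG%02d", g)
      src[k] <- picks[g]
      k <- k + 1
    }
  }
  rownames(calls) <- ids
  colnames(calls) <- colnames(founders)
  records <- validate_sample_records(tibble::tibble(
    sample_id = ids, role = "replicate", reported_name = src,
    replicate_group = grp))
  structure(list(genotypes = geno_matrix(calls), records = records,
                 source = stats::setNames(src, ids)),
            class = "sim_replicates")
}
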