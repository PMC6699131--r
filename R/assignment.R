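#' Normalize a variety name
#'
#' Trims and collapses whitespace, upper-cases, then applies an optional
#' synonym table so that spelling variants of one variety (e.g. `GUL96`
#' vs `GUL-96`) compare equal. Unmapped names pass through canonicalized.
#'
#' @param raw character vector of reported names.
#' @param synonyms optional data frame with columns `raw` and `canonical`;
#'   `raw` keys are matched after the same trim/case normalization.
#' @return Character vector of canonical names (`NA` stays `NA`).
#' @export
normalize_name <- function(raw, synonyms = NULL) {
  out <- toupper(gsub("\\s+", " ", trimws(raw)))
  out[!nzchar(out)] <- NA_character_
  if (!is.null(synonyms)) {
    if (!all(c("raw", "canonical") %in% names(synonyms))) {
      rlang::abort("`synonyms` must have columns raw, canonical.")
    }
    key <- toupper(gsub("\\s+", " ", trimws(synonyms$raw)))
    hit <- match(out, key)
    out[!is.na(hit)] <- synonyms$canonical[hit[!is.na(hit)]]
  }
  out
}

#' Find reference candidates above an identity threshold
#'
#' @param sample_id a field sample id present in `ibs`.
#' @param ibs an `ibs_matrix` covering field and reference samples.
#' @param records sample metadata (rows with `role == "reference"` form
#'   the library).
#' @param threshold IBS cutoff in `[0, 1]`.
#' @return A tibble with `reference_id`, `ibs`, sorted by IBS descending
#'   then id ascending; zero rows when nothing reaches the threshold.
#' @export
find_candidates <- function(sample_id, ibs, records, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  records <- validate_sample_records(records)
  ref_ids <- intersect(records$sample_id[records$role == "reference"],
                       ibs$sample_ids)
  v <- ibs$ibs[sample_id, ref_ids]
  keep <- !is.na(v) & v >= threshold
  out <- tibble::tibble(reference_id = ref_ids[keep], ibs = unname(v[keep]))
  dplyr::arrange(out, dplyr::desc(.data$ibs), .data$reference_id)
}

#' Cohesion of a set of samples
#'
#' A same-named cohort is cohesive when every pairwise IBS within it
#' reaches the threshold — the operational reading of field samples being
#' "highly identical among themselves". Singletons are cohesive by
#' convention; pairs with undefined IBS are not.
#'
#' @param sample_ids ids of the cohort.
#' @param ibs an `ibs_matrix`.
#' @param threshold IBS cutoff.
#' @return `TRUE`/`FALSE`.
#' @export
cohesion <- function(sample_ids, ibs, threshold) {
  if (length(sample_ids) < 1) rlang::abort("Need at least one sample.")
  if (length(sample_ids) == 1) return(TRUE)
  sub <- ibs$ibs[sample_ids, sample_ids]
  v <- sub[upper.tri(sub)]
  !anyNA(v) && all(v >= threshold)
}

# name-level concordance support among a set of reference entries:
# TRUE when >= 2 of them are mutually concordant (any concordant pair)
.has_concordant_pair <- function(ids, ref_ibs, thr) {
  if (length(ids) < 2) return(FALSE)
  sub <- ref_ibs[ids, ids]
  any(sub[upper.tri(sub)] >= thr, na.rm = TRUE)
}

#' Apply the six-rule varietal identification procedure
#'
#' Each field sample is compared with the reference library at the initial
#' identity threshold, then (if unresolved) at the relaxed minimum
#' threshold, and classified by the first rule that applies:
#'
#' * **R1** — matches exactly one reference variety (a name with a single
#'   library entry): identified as it.
#' * **R2** — among the matched names, exactly one is supported by multiple
#'   concordant library seed sources: identified as that name (two or more
#'   names with such support is an `ambiguous` tie, recorded distinctly).
#' * **R3** — matches one name represented two or three times in the
#'   library with discordant profiles, the sample agreeing with a subset
#'   of the sources (one source presumed wrong): identified as it.
#' * **R4** — matches only names duplicated four or more times with
#'   mutually discordant profiles (sources too uncertain to trust): the
#'   reported name is kept iff the same-reported-name field cohort is
#'   cohesive; otherwise the sample falls through to R6.
#' * **R5** — no match at either threshold but the reported-name cohort is
#'   cohesive (variety presumed absent from the library): reported name
#'   kept.
#' * **R6** — no match at the minimum threshold and the cohort is not
#'   cohesive: declared `UNKNOWN`.
#'
#' Matching names that are neither singly entered, concordantly supported,
#' nor uniformly many-duplicated discordant cannot be separated and are
#' flagged `ambiguous`. Library-source concordance ("same genomic
#' profile") means pairwise IBS at or above the initial threshold; cohort
#' cohesion uses the minimum threshold.
#'
#' @param ibs an `ibs_matrix` over field and reference samples.
#' @param records sample metadata (field + reference roles).
#' @param thresholds an [identity_thresholds()].
#' @param synonyms optional synonym table for name normalization.
#' @return A tibble of class `assignment_tbl`: `sample_id`, `status`
#'   (`identified`, `kept_reported`, `unknown`, `ambiguous`), `assigned_name`
#'   (`NA` for unknown/ambiguous), `rule` (1–6, `NA` for ambiguous),
#'   `best_ibs`, `threshold_used` (`initial`/`minimum`), and
#'   `matched_reference_ids` (`;`-separated).
#' @export
apply_decision_rules <- function(ibs, records, thresholds, synonyms = NULL) {
  stopifnot(inherits(ibs, "ibs_matrix"), inherits(thresholds, "identity_thresholds"))
  records <- validate_sample_records(records)
  records <- dplyr::filter(records, .data$sample_id %in% ibs$sample_ids)
  refs <- dplyr::filter(records, .data$role == "reference")
  flds <- dplyr::filter(records, .data$role == "field")
  if (nrow(refs) == 0) rlang::abort("No reference entries in `records`.")
  if (nrow(flds) == 0) rlang::abort("No field samples in `records`.")

  ref_name <- stats::setNames(normalize_name(refs$reported_name, synonyms),
                              refs$sample_id)
  if (anyNA(ref_name)) {
    rlang::abort("Every reference entry needs a variety name.")
  }
  name_entries <- split(names(ref_name), ref_name)
  ref_ibs <- ibs$ibs[refs$sample_id, refs$sample_id, drop = FALSE]
  t_init <- thresholds$initial
  t_min <- thresholds$minimum

  # per-name library facts
  name_facts <- purrr::map(name_entries, function(ids) {
    list(n_lib = length(ids),
         concordant = .has_concordant_pair(ids, ref_ibs, t_init))
  })

  # cohesion of reported-name cohorts among field samples (minimum threshold)
  fld_reported <- normalize_name(flds$reported_name, synonyms)
  cohorts <- split(flds$sample_id, fld_reported)
  cohort_ok <- purrr::map_lgl(cohorts, cohesion, ibs = ibs, threshold = t_min)

  resolve <- function(cands) {
    # -> list(rule, name, matched) | "ambiguous" | "r4" | NULL
    if (nrow(cands) == 0) return(NULL)
    cands$name <- ref_name[cands$reference_id]
    nms <- unique(cands$name)
    sup <- purrr::map_lgl(nms, function(nm) {
      .has_concordant_pair(cands$reference_id[cands$name == nm], ref_ibs, t_init)
    })
    if (length(nms) == 1) {
      nf <- name_facts[[nms]]
      if (nf$n_lib == 1) {
        return(list(rule = 1L, name = nms, matched = cands$reference_id))
      }
      if (sup[1] || nf$concordant) {
        return(list(rule = 2L, name = nms, matched = cands$reference_id))
      }
      if (nf$n_lib <= 3) {
        return(list(rule = 3L, name = nms, matched = cands$reference_id))
      }
      return("r4")
    }
    if (sum(sup) == 1) {
      nm <- nms[sup]
      return(list(rule = 2L, name = nm,
                  matched = cands$reference_id[cands$name == nm]))
    }
    if (sum(sup) >= 2) return("ambiguous")
    all_many <- all(purrr::map_lgl(nms, function(nm) {
      nf <- name_facts[[nm]]
      nf$n_lib >= 4 && !nf$concordant
    }))
    if (all_many) return("r4")
    "ambiguous"
  }

  one_sample <- function(sid, reported) {
    vref <- ibs$ibs[sid, refs$sample_id]
    best <- if (all(is.na(vref))) NA_real_ else max(vref, na.rm = TRUE)
    coh <- if (is.na(reported)) FALSE else cohort_ok[[reported]]
    out <- function(status, name, rule, thr, matched) {
      tibble::tibble(sample_id = sid, status = status,
                     assigned_name = name, rule = rule, best_ibs = best,
                     threshold_used = thr,
                     matched_reference_ids = if (length(matched))
                       paste(matched, collapse = ";") else NA_character_)
    }
    for (thr in c("initial", "minimum")) {
      t_use <- if (thr == "initial") t_init else t_min
      cands <- find_candidates(sid, ibs, records, t_use)
      res <- resolve(cands)
      if (is.list(res)) {
        return(out("identified", res$name, res$rule, thr, res$matched))
      }
      if (identical(res, "ambiguous")) {
        return(out("ambiguous", NA_character_, NA_integer_, thr,
                   cands$reference_id))
      }
      if (identical(res, "r4") && thr == "minimum") {
        if (coh && !is.na(reported)) {
          return(out("kept_reported", reported, 4L, thr, cands$reference_id))
        }
        return(out("unknown", NA_character_, 6L, thr, character()))
      }
      # res NULL at initial, or "r4" at initial: relax and retry
    }
    # no candidates at the minimum threshold
    if (coh && !is.na(reported)) {
      return(out("kept_reported", reported, 5L, "minimum", character()))
    }
    out("unknown", NA_character_, 6L, "minimum", character())
  }

  res <- purrr::map2(flds$sample_id, fld_reported, one_sample) |>
    dplyr::bind_rows()
  class(res) <- c("assignment_tbl", class(res))
  res
}

#' Compare DNA-determined identities with farmer-reported names
#'
#' @param assignments output of [apply_decision_rules()].
#' @param records sample metadata carrying the reported names.
#' @param synonyms optional synonym table applied to reported names.
#' @param variety_info optional tibble (`name`, `type`, `release_year`)
#'   classifying variety names (`type` in `released`, `landrace`, ...);
#'   enables the improved-variety and landrace shares by both methods.
#' @return An object of class `agreement_report`: counts `n_correct`,
#'   `n_incorrect`, `n_unknown`, `fraction_misnamed` (incorrect over
#'   determined), a reported-by-determined `flow` tibble (Sankey input),
#'   and optional method shares.
#' @export
compare_with_reported <- function(assignments, records, synonyms = NULL,
                                  variety_info = NULL) {
  records <- validate_sample_records(records)
  df <- assignments |>
    dplyr::left_join(dplyr::select(records, "sample_id", "reported_name"),
                     by = "sample_id") |>
    dplyr::mutate(
      reported = normalize_name(.data$reported_name, synonyms),
      determined = dplyr::if_else(
        .data$status %in% c("identified", "kept_reported"),
        .data$assigned_name, "UNKNOWN"))
  undet <- df$determined == "UNKNOWN"
  correct <- !undet & !is.na(df$reported) & df$reported == df$determined
  n_correct <- sum(correct)
  n_unknown <- sum(undet)
  n_incorrect <- nrow(df) - n_correct - n_unknown
  flow <- df |>
    dplyr::mutate(reported = dplyr::coalesce(.data$reported, "LOCAL/UNKNOWN")) |>
    dplyr::count(.data$reported, .data$determined, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  shares <- NULL
  if (!is.null(variety_info)) {
    type_of <- stats::setNames(variety_info$type, normalize_name(variety_info$name))
    year_of <- stats::setNames(variety_info$release_year,
                               normalize_name(variety_info$name))
    share <- function(x, what) mean(!is.na(x) & type_of[x] %in% what, na.rm = FALSE)
    shares <- tibble::tibble(
      fraction_improved_reported = share(df$reported, "released"),
      fraction_improved_determined = share(df$determined, "released"),
      fraction_landrace_reported = share(df$reported, "landrace"),
      fraction_landrace_determined = share(df$determined, "landrace"),
      fraction_post2000_determined = mean(
        !is.na(df$determined) & !is.na(year_of[df$determined]) &
          year_of[df$determined] > 2000)
    )
  }
  structure(list(
    n_correct = n_correct, n_incorrect = n_incorrect, n_unknown = n_unknown,
    n_total = nrow(df),
    fraction_correct = n_correct / nrow(df),
    fraction_misnamed = if (n_correct + n_incorrect > 0)
      n_incorrect / (n_correct + n_incorrect) else NA_real_,
    flow = flow, shares = shares
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %d samples: %d correctly named (%.1f%%), %d misnamed, %d undetermined\n",
    x$n_total, x$n_correct, 100 * x$fraction_correct, x$n_incorrect, x$n_unknown))
  invisible(x)
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_correct = x$n_correct,
                 n_incorrect = x$n_incorrect, n_unknown = x$n_unknown,
                 fraction_correct = x$fraction_correct,
                 fraction_misnamed = x$fraction_misnamed)
}

#' @export
tidy.agreement_report <- function(x, ...) x$flow

#' Summarize trait-marker calls per determined variety
#'
#' Joins functional/trait marker calls (e.g. rust resistance, dwarfing,
#' vernalization alleles) to the DNA-determined variety of each field
#' sample and reports the majority allele per variety and marker with a
#' discordance count.
#'
#' @param assignments output of [apply_decision_rules()].
#' @param trait_calls tibble with columns `sample_id`, `marker`, `allele`.
#' @return A tibble: `variety`, `marker`, `allele` (majority;
#'   lexicographic tie-break), `n_samples`, `discordance`.
#' @export
annotate_trait_markers <- function(assignments, trait_calls) {
  need <- c("sample_id", "marker", "allele")
  if (!all(need %in% names(trait_calls))) {
    rlang::abort("`trait_calls` must have columns sample_id, marker, allele.")
  }
  known <- assignments$sample_id[
    assignments$status %in% c("identified", "kept_reported")]
  stray <- setdiff(unique(trait_calls$sample_id), assignments$sample_id)
  if (length(stray)) {
    rlang::warn(sprintf(
      "%d trait-call sample(s) absent from assignments were excluded (e.g. '%s').",
      length(stray), stray[1]))
  }
  trait_calls |>
    dplyr::filter(.data$sample_id %in% known) |>
    dplyr::inner_join(
      dplyr::select(assignments, "sample_id", variety = "assigned_name"),
      by = "sample_id") |>
    dplyr::count(.data$variety, .data$marker, .data$allele, name = "n") |>
    dplyr::group_by(.data$variety, .data$marker) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$allele, .by_group = TRUE) |>
    dplyr::summarise(
      allele = .data$allele[1],
      n_samples = sum(.data$n),
      discordance = sum(.data$n) - .data$n[1],
      .groups = "drop")
}
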