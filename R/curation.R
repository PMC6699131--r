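#' Detect duplicate genomic profiles in the reference library
#'
#' Builds a graph over reference entries with an edge wherever pairwise
#' IBS reaches the identity threshold and returns its connected components
#' of size >= 2. Components that are not cliques (entries joined only
#' through a chain, with some internal pair below the threshold) are
#' flagged, since "same profile" is then a chained, not mutual, statement.
#'
#' @param ibs an `ibs_matrix` covering the reference entries.
#' @param records sample metadata; rows with `role == "reference"`.
#' @param threshold profile-identity IBS cutoff (normally the calibrated
#'   initial threshold).
#' @return A tibble with one row per duplicate set: `set_id`, `entries`
#'   (list column), `size`, `is_clique`.
#' @export
detect_duplicate_profiles <- function(ibs, records, threshold) {
  records <- validate_sample_records(records)
  ref_ids <- intersect(records$sample_id[records$role == "reference"],
                       ibs$sample_ids)
  sub <- ibs$ibs[ref_ids, ref_ids, drop = FALSE]
  adj <- !is.na(sub) & sub >= threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  sets <- split(ref_ids, comp$membership)
  sets <- sets[lengths(sets) >= 2]
  if (!length(sets)) {
    return(tibble::tibble(set_id = integer(), entries = list(),
                          size = integer(), is_clique = logical()))
  }
  tibble::tibble(
    set_id = seq_along(sets),
    entries = unname(lapply(sets, sort)),
    size = unname(lengths(sets)),
    is_clique = purrr::map_lgl(sets, function(ids) {
      s <- adj[ids, ids]
      all(s[upper.tri(s)])
    })
  )
}

.norm_text <- function(x) {
  out <- toupper(gsub("\\s+", " ", trimws(x)))
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Audit the reference library for name/profile inconsistencies
#'
#' Reduces the library by excluding entries with incomplete names or
#' pedigrees and collapsing exact duplicates (same normalized name, same
#' pedigree, same genomic profile — first entry kept). On the reduced
#' library it quantifies two inconsistency classes:
#'
#' * **class A** — entries sharing a normalized name *and* pedigree whose
#'   profiles are discordant (some same-identity pair below the
#'   threshold). Landrace entries are exempt (heterogeneity within a
#'   landrace name is expected), as are entries flagged as breeding lines
#'   (sister lines legitimately share name and pedigree).
#' * **class B** — entries within one duplicate-profile set that differ in
#'   name or pedigree. Entries already counted in class A are not counted
#'   again, so the two classes are disjoint at the entry level.
#'
#' @param ibs an `ibs_matrix` covering the reference entries.
#' @param records metadata with `reported_name` and `pedigree`; optional
#'   logical column `breeding_line`.
#' @param threshold profile-identity IBS cutoff.
#' @param synonyms optional synonym table for name normalization.
#' @return An object of class `library_audit` with the duplicate sets,
#'   class memberships, fractions (relative to the reduced library),
#'   `n_before`, `n_after`, and the removed/excluded entry ids.
#' @export
audit_library <- function(ibs, records, threshold, synonyms = NULL) {
  records <- validate_sample_records(records)
  refs <- dplyr::filter(records, .data$role == "reference",
                        .data$sample_id %in% ibs$sample_ids)
  refs$name <- normalize_name(refs$reported_name, synonyms)
  refs$ped <- .norm_text(refs$pedigree)
  n_before <- nrow(refs)
  excluded <- refs$sample_id[is.na(refs$name) | is.na(refs$ped)]
  kept <- dplyr::filter(refs, !.data$sample_id %in% excluded)

  conc <- function(a, b) {
    v <- ibs$ibs[a, b]
    !is.na(v) && v >= threshold
  }
  # collapse exact duplicates: same name + pedigree + concordant profile
  removed <- character()
  kept <- dplyr::arrange(kept, .data$sample_id)
  for (key in unique(paste(kept$name, kept$ped, sep = "\r"))) {
    ids <- kept$sample_id[paste(kept$name, kept$ped, sep = "\r") == key]
    if (length(ids) < 2) next
    keep_first <- ids[1]
    for (id in ids[-1]) {
      if (conc(keep_first, id)) removed <- c(removed, id)
    }
  }
  kept <- dplyr::filter(kept, !.data$sample_id %in% removed)
  n_after <- nrow(kept)

  # class A: same name + pedigree, discordant profiles
  exempt <- kept$germplasm_group %in% "landrace"
  if ("breeding_line" %in% names(records)) {
    bl <- stats::setNames(records$breeding_line, records$sample_id)
    exempt <- exempt | isTRUE_vec(bl[kept$sample_id])
  }
  classA <- character()
  eligible <- kept[!exempt, , drop = FALSE]
  for (key in unique(paste(eligible$name, eligible$ped, sep = "\r"))) {
    ids <- eligible$sample_id[paste(eligible$name, eligible$ped, sep = "\r") == key]
    if (length(ids) < 2) next
    sub <- ibs$ibs[ids, ids]
    v <- sub[upper.tri(sub)]
    if (any(is.na(v) | v < threshold)) classA <- c(classA, ids)
  }

  # class B: shared profile, different name or pedigree
  dup_sets <- detect_duplicate_profiles(ibs, dplyr::mutate(kept, role = "reference"),
                                        threshold)
  classB <- character()
  for (ids in dup_sets$entries) {
    sub <- kept[match(ids, kept$sample_id), ]
    if (dplyr::n_distinct(sub$name) > 1 || dplyr::n_distinct(sub$ped) > 1) {
      classB <- c(classB, ids)
    }
  }
  classA <- sort(unique(classA))
  classB <- sort(setdiff(unique(classB), classA))

  structure(list(
    duplicate_profile_sets = dup_sets,
    classA = classA, classB = classB,
    fraction_classA = length(classA) / n_after,
    fraction_classB = length(classB) / n_after,
    fraction_inconsistent = (length(classA) + length(classB)) / n_after,
    n_before = n_before, n_after = n_after,
    removed_duplicates = sort(removed),
    excluded_incomplete = sort(excluded)
  ), class = "library_audit")
}

# vectorized isTRUE
isTRUE_vec <- function(x) !is.na(x) & x == TRUE

#' @export
print.library_audit <- function(x, ...) {
  cat(sprintf(
    "<library_audit> %d -> %d entries (%d exact duplicates removed, %d incomplete excluded)\n",
    x$n_before, x$n_after, length(x$removed_duplicates),
    length(x$excluded_incomplete)))
  cat(sprintf("  class A (same name+pedigree, distinct profiles): %d (%.1f%%)\n",
              length(x$classA), 100 * x$fraction_classA))
  cat(sprintf("  class B (same profile, different name/pedigree): %d (%.1f%%)\n",
              length(x$classB), 100 * x$fraction_classB))
  cat(sprintf("  inconsistent overall: %.1f%%\n", 100 * x$fraction_inconsistent))
  invisible(x)
}

#' @export
glance.library_audit <- function(x, ...) {
  tibble::tibble(
    n_before = x$n_before, n_after = x$n_after,
    n_classA = length(x$classA), n_classB = length(x$classB),
    fraction_classA = x$fraction_classA,
    fraction_classB = x$fraction_classB,
    fraction_inconsistent = x$fraction_inconsistent
  )
}

#' @export
tidy.library_audit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(entry = x$classA, class = "A"),
    tibble::tibble(entry = x$classB, class = "B")
  )
}

#' Assign germplasm groups to library entries
#'
#' @param records sample metadata.
#' @param group_table data frame mapping `sample_id` to `germplasm_group`
#'   (one of `afghan_collection`, `landrace`, `released`, `other_elite`).
#' @return The records with `germplasm_group` populated; reference entries
#'   missing from the table are labeled `other_elite` with a warning.
#' @export
assign_germplasm_groups <- function(records, group_table) {
  records <- validate_sample_records(records)
  if (!all(c("sample_id", "germplasm_group") %in% names(group_table))) {
    rlang::abort("`group_table` must have columns sample_id, germplasm_group.")
  }
  bad <- setdiff(unique(group_table$germplasm_group), .germplasm_groups)
  if (length(bad)) {
    rlang::abort(sprintf("Unknown germplasm group label '%s'; must be one of %s.",
                         bad[1], paste(.germplasm_groups, collapse = ", ")))
  }
  g <- stats::setNames(group_table$germplasm_group, group_table$sample_id)
  is_ref <- records$role == "reference"
  unmapped <- records$sample_id[is_ref & !records$sample_id %in% names(g)]
  if (length(unmapped)) {
    rlang::warn(sprintf(
      "%d reference entr%s not in `group_table`; labeled other_elite (e.g. '%s').",
      length(unmapped), if (length(unmapped) == 1) "y" else "ies", unmapped[1]))
  }
  records$germplasm_group[is_ref] <-
    dplyr::coalesce(unname(g[records$sample_id[is_ref]]), "other_elite")
  records
}
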