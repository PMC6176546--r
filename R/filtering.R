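# Peptide confidence, ambiguity and conservation filters. Each filter is a
# row-subset predicate on the full report: a precursor is kept or removed as
# a whole (all of its samples' rows), so the filters commute.

#' Filter policy
#'
#' Confidence thresholds of the two workflows: the strict single-threshold
#' rule used for technical-replicate QC (Q <= 1e-3 in every sample) and the
#' grouped rule used for species comparisons (Q <= 1e-4 over all samples of
#' either comparison group, allowing a configurable number of outlier
#' samples per species).
#'
#' @param q_threshold_strict strict per-sample threshold.
#' @param q_threshold_grouped grouped-rule threshold.
#' @param outliers_allowed_per_species samples per species allowed above the
#'   grouped threshold.
#' @param group_mode `"either"` (qualify in group A or B) or `"both"`.
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(q_threshold_strict = 1e-3,
                          q_threshold_grouped = 1e-4,
                          outliers_allowed_per_species = 1L,
                          group_mode = c("either", "both")) {
  group_mode <- match.arg(group_mode)
  for (thr in c(q_threshold_strict, q_threshold_grouped)) {
    stop_if_not(thr > 0 && thr < 1, "thresholds must lie in (0, 1)")
  }
  stop_if_not(outliers_allowed_per_species >= 0, "outliers_allowed must be >= 0")
  structure(list(
    q_threshold_strict = q_threshold_strict,
    q_threshold_grouped = q_threshold_grouped,
    outliers_allowed_per_species = as.integer(outliers_allowed_per_species),
    group_mode = group_mode
  ), class = "filter_policy")
}

check_complete_matrix <- function(report) {
  key <- report_precursor_keys(report)
  n_samples <- length(unique(report$sample_id))
  counts <- table(key)
  if (any(counts != n_samples)) {
    stop(sprintf("precursor '%s' is missing from some samples",
                 names(counts)[which(counts != n_samples)[1L]]), call. = FALSE)
  }
  invisible(key)
}

subset_precursors <- function(report, keep_keys) {
  key <- report_precursor_keys(report)
  out <- report[key %in% keep_keys, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_precursors") <- setdiff(unique(key), keep_keys)
  out
}

#' Strict confidence filter
#'
#' Retains exactly the precursors whose Q-value is at or below the threshold
#' in every sample (used for the technical-replicate workflow).
#'
#' @param report QuantReport data.frame.
#' @param q_threshold per-sample Q-value threshold.
#' @return filtered report; removed precursor keys in attribute
#'   `"removed_precursors"`.
#' @export
strict_filter <- function(report, q_threshold = 1e-3) {
  stop_if_not(nrow(report) > 0, "report is empty")
  key <- check_complete_matrix(report)
  worst <- tapply(report$q_value, key, max)
  keep <- names(worst)[worst <= q_threshold]
  subset_precursors(report, keep)
}

#' Grouped confidence filter with per-species outlier allowance
#'
#' A precursor qualifies in a comparison group when, for every species of
#' that group, at most `outliers_allowed_per_species` samples of the species
#' have a Q-value above the grouped threshold. The precursor is kept when it
#' qualifies in either group (default) or in both. All samples' rows are
#' retained for kept precursors, outliers included: quantification uses all
#' samples.
#'
#' @param report QuantReport data.frame.
#' @param design design data.frame (sample_id, species, group).
#' @param policy a [filter_policy()].
#' @param contrast the two group labels compared; defaults to the (first
#'   two) groups present in the design.
#' @return filtered report; removed precursor keys in attribute
#'   `"removed_precursors"`.
#' @export
grouped_confidence_filter <- function(report, design, policy = filter_policy(),
                                      contrast = unique(design$group)) {
  stop_if_not(nrow(report) > 0, "report is empty")
  stop_if_not(all(report$sample_id %in% design$sample_id),
              "design does not cover all samples in the report")
  stop_if_not(length(contrast) == 2, "need exactly two comparison groups")
  key <- check_complete_matrix(report)
  species_of <- stats::setNames(design$species, design$sample_id)
  group_of <- stats::setNames(design$group, design$sample_id)
  sp_counts <- table(design$species[design$group %in% contrast])
  if (any(sp_counts < 2)) {
    warning(sprintf("species with < 2 samples: %s; outlier rule applied as stated",
                    paste(names(sp_counts)[sp_counts < 2], collapse = ", ")),
            call. = FALSE)
  }
  fail <- report$q_value > policy$q_threshold_grouped
  sp <- species_of[report$sample_id]
  grp <- group_of[report$sample_id]
  qualifies_in <- function(g) {
    in_g <- grp == g
    # per (precursor, species of the group): number of failing samples
    fails <- tapply(fail[in_g], list(key[in_g], sp[in_g]), sum)
    ok <- fails <= policy$outliers_allowed_per_species
    ok[is.na(ok)] <- TRUE  # species absent from this group
    apply(ok, 1L, all)[unique(key)]
  }
  qa <- qualifies_in(contrast[1L])
  qb <- qualifies_in(contrast[2L])
  keep_flag <- if (policy$group_mode == "either") qa | qb else qa & qb
  subset_precursors(report, unique(key)[keep_flag])
}

#' Remove precursors that map ambiguously to multiple genes
#'
#' Retains precursors whose spectral-library gene set has exactly one
#' element (the `genes` column is semicolon-separated).
#'
#' @param report QuantReport data.frame.
#' @return filtered report.
#' @export
remove_ambiguous <- function(report) {
  stop_if_not(all(nzchar(report$genes)), "precursor with empty gene set")
  key <- report_precursor_keys(report)
  singleton <- !grepl(";", report$genes, fixed = TRUE)
  keep <- setdiff(unique(key), unique(key[!singleton]))
  subset_precursors(report, keep)
}

#' Restrict a report to cross-species conserved peptides
#'
#' Retains precursors whose bare peptide sequence (modifications play no
#' role in the conservation test) occurs in the in-silico digest of every
#' species in the comparison.
#'
#' @param report QuantReport data.frame.
#' @param index a [build_conserved_index()] result.
#' @param species_subset species that must all contain the sequence;
#'   defaults to all species of the index.
#' @return filtered report.
#' @export
restrict_to_conserved <- function(report, index, species_subset = index$species) {
  key <- report_precursor_keys(report)
  cons <- is_conserved(report$sequence, index, species_subset)
  keep <- setdiff(unique(key), unique(key[!cons]))
  subset_precursors(report, keep)
}
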