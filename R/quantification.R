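# Peptide -> protein rollup, two-stage normalization (total-area then fast
# cyclic loess), iBAQ, and quality-control statistics.

#' Pivot a long-format report into a peptide abundance matrix
#'
#' @param report QuantReport data.frame (one row per sample x precursor).
#' @return linear-scale abundance matrix, precursors (keys
#'   `sequence|modifications|charge`) in rows, samples in columns, with a
#'   `peptide_gene` attribute mapping each row to its gene set string.
#' @export
peptide_matrix <- function(report) {
  key <- report_precursor_keys(report)
  samples <- unique(report$sample_id)
  feats <- unique(key)
  m <- matrix(NA_real_, length(feats), length(samples),
              dimnames = list(feats, samples))
  m[cbind(match(key, feats), match(report$sample_id, samples))] <- report$intensity
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1L]
    stop(sprintf("precursor '%s' is missing from some samples", feats[bad]),
         call. = FALSE)
  }
  gene_of <- report$genes[match(feats, key)]
  m <- abundance_matrix(m, "linear")
  attr(m, "peptide_gene") <- stats::setNames(gene_of, feats)
  m
}

#' Total-peak-area normalization across runs
#'
#' Scales each sample so its column total equals the mean of the original
#' column totals; relative intensities within a sample are unchanged.
#'
#' @param x linear-scale abundance matrix.
#' @return normalized matrix; scale factors in the `"scale_factors"`
#'   attribute.
#' @export
total_area_normalize <- function(x) {
  stop_if_not(identical(matrix_scale(x), "linear"),
              "total-area normalization requires a linear-scale matrix")
  totals <- colSums(x)
  if (any(totals <= 0)) {
    j <- which(totals <= 0)[1L]
    stop(sprintf("zero column total in sample '%s'", colnames(x)[j] %||% j),
         call. = FALSE)
  }
  f <- mean(totals) / totals
  out <- abundance_matrix(sweep(x, 2L, f, "*"), "linear")
  attr(out, "peptide_gene") <- attr(x, "peptide_gene")
  attr(out, "scale_factors") <- f
  out
}

#' Roll peptide abundances up to proteins by summation
#'
#' Protein (gene) abundance is the sum of the normalized peak areas of its
#' peptides, per sample. Every peptide must map to exactly one gene
#' (ambiguous precursors are removed beforehand, see [remove_ambiguous()]).
#'
#' @param x linear-scale peptide matrix.
#' @param peptide_gene named character vector mapping row names of `x` to a
#'   single gene symbol; defaults to the matrix's `peptide_gene` attribute.
#' @return linear-scale protein matrix, genes in rows.
#' @export
rollup_to_proteins <- function(x, peptide_gene = attr(x, "peptide_gene")) {
  stop_if_not(identical(matrix_scale(x), "linear"),
              "rollup requires a linear-scale matrix")
  stop_if_not(!is.null(peptide_gene), "no peptide -> gene map supplied")
  genes <- peptide_gene[rownames(x)]
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop(sprintf("peptide '%s' has no gene mapping",
                 rownames(x)[which(is.na(genes) | !nzchar(genes))[1L]]),
         call. = FALSE)
  }
  if (any(grepl(";", genes, fixed = TRUE))) {
    stop(sprintf("peptide '%s' maps to multiple genes; remove ambiguous precursors first",
                 rownames(x)[which(grepl(";", genes, fixed = TRUE))[1L]]),
         call. = FALSE)
  }
  out <- rowsum(x, group = genes, reorder = TRUE)
  abundance_matrix(as.matrix(out), "linear")
}

#' Fast cyclic loess normalization
#'
#' Removes intensity-dependent between-sample bias on the log scale using
#' limma's `normalizeCyclicLoess` in its `"fast"` variant: per iteration,
#' each sample's log-ratio to the mean log profile is loess-smoothed against
#' that mean profile and subtracted. Defaults: 10 iterations, span 0.7.
#'
#' @param x abundance matrix; linear-scale input must be strictly positive
#'   and is log2-transformed internally, log2 input is used directly.
#' @param iterations number of cyclic iterations.
#' @param span loess span.
#' @return matrix on the input's scale.
#' @export
cyclic_loess_normalize <- function(x, iterations = 10L, span = 0.7) {
  stop_if_not(iterations >= 1, "iterations must be >= 1")
  stop_if_not(span > 0 && span <= 1, "span must be in (0, 1]")
  was_linear <- identical(matrix_scale(x), "linear")
  lg <- to_log2(x)
  norm <- limma::normalizeCyclicLoess(lg, span = span,
                                      iterations = iterations, method = "fast")
  dimnames(norm) <- dimnames(lg)
  out <- abundance_matrix(norm, "log2")
  if (was_linear) out <- to_linear(out)
  out
}

#' iBAQ abundance
#'
#' Protein intensity divided by its count of theoretically observable
#' tryptic peptides (see [count_observable_peptides()]). With zero
#' observable peptides the iBAQ value is undefined and `NA` is returned
#' (never a division by zero).
#'
#' @param intensity non-negative protein intensity (vectorized).
#' @param observable_count observable-peptide counts.
#' @return iBAQ values; `NA` where undefined.
#' @export
compute_ibaq <- function(intensity, observable_count) {
  stop_if_not(all(intensity >= 0), "intensity must be non-negative")
  stop_if_not(all(observable_count >= 0), "observable_count must be >= 0")
  ifelse(observable_count == 0, NA_real_, intensity / observable_count)
}

#' Merge protein groups to genes by iBAQ summation
#'
#' Protein groups mapping to a single gene are merged by summing their iBAQ
#' abundances; groups whose members span different genes are ambiguous and
#' dropped.
#'
#' @param groups data.frame with columns `group_id`, `genes`
#'   (semicolon-separated gene set of the group) and `ibaq`.
#' @return data.frame with columns `gene` and `ibaq`; the number of dropped
#'   multi-gene groups is attached as attribute `"n_ambiguous_dropped"`.
#' @export
merge_groups_by_gene <- function(groups) {
  stop_if_not(all(c("group_id", "genes", "ibaq") %in% names(groups)),
              "groups needs columns group_id, genes, ibaq")
  multi <- grepl(";", groups$genes, fixed = TRUE)
  kept <- groups[!multi, , drop = FALSE]
  agg <- stats::aggregate(ibaq ~ genes, data = kept, FUN = sum)
  out <- data.frame(gene = agg$genes, ibaq = agg$ibaq, stringsAsFactors = FALSE)
  attr(out, "n_ambiguous_dropped") <- sum(multi)
  out
}

#' Per-feature coefficient of variation by species
#'
#' CoV = unbiased sample standard deviation / mean on linear-scale values,
#' reported as a percentage.
#'
#' @param x linear-scale abundance matrix.
#' @param species_of named character vector mapping sample ids to species
#'   (or any grouping with >= 2 samples per level).
#' @return list with `per_feature` (features x species matrix of CoV %) and
#'   `median` (named vector of per-species medians).
#' @export
compute_cov <- function(x, species_of) {
  stop_if_not(identical(matrix_scale(x), "linear"),
              "CoV is computed on linear-scale values")
  sp <- species_of[colnames(x)]
  stop_if_not(!anyNA(sp), "every sample needs a species assignment")
  levels_sp <- unique(sp)
  per <- sapply(levels_sp, function(s) {
    cols <- which(sp == s)
    stop_if_not(length(cols) >= 2, "species '%s' has < 2 samples", s)
    mu <- rowMeans(x[, cols, drop = FALSE])
    sdv <- apply(x[, cols, drop = FALSE], 1L, stats::sd)
    100 * sdv / mu
  })
  per <- matrix(per, nrow = nrow(x), dimnames = list(rownames(x), levels_sp))
  list(per_feature = per, median = apply(per, 2L, stats::median))
}

#' Pairwise squared Pearson correlation of samples
#'
#' Computed on log2-scale abundances (linear input is transformed first).
#'
#' @param x abundance matrix with >= 2 features.
#' @return symmetric sample x sample matrix of R-squared, unit diagonal.
#' @export
pairwise_r2 <- function(x) {
  stop_if_not(nrow(x) >= 2, "need at least two features")
  lg <- to_log2(x)
  r2 <- stats::cor(lg)^2
  diag(r2) <- 1
  r2
}

#' Scale rows by their total across samples
#'
#' Divides each feature's values by its row sum, giving relative abundance
#' profiles that sum to 1 over the samples.
#'
#' @param x non-negative matrix with at least one positive value per row.
#' @return row-stochastic matrix.
#' @export
scale_relative <- function(x) {
  rs <- rowSums(x)
  stop_if_not(all(x >= 0), "values must be non-negative")
  if (any(rs <= 0)) {
    i <- which(rs <= 0)[1L]
    stop(sprintf("row '%s' has no positive value", rownames(x)[i] %||% i),
         call. = FALSE)
  }
  sweep(unclass(x), 1L, rs, "/")
}
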