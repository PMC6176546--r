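# End-to-end orchestration: digest -> conserved index -> filters ->
# total-area normalize -> rollup -> cyclic loess -> moderated t -> BH ->
# calls -> enrichment -> QC, with a machine-readable run manifest.

#' Run the cross-species comparison pipeline
#'
#' Executes the full analysis for one two-group contrast: builds the
#' conserved-peptide index from the proteomes, applies the grouped
#' confidence filter, the ambiguity filter and the conservation filter to
#' the report, normalizes total peak areas at the peptide level, rolls up to
#' proteins, applies fast cyclic-loess normalization, fits the moderated
#' t-test with BH-FDR, and (optionally) tests a gene set for enrichment
#' among the differential proteins. Quality-control summaries (per-species
#' CoV, pairwise R-squared, sample clustering) are computed on the protein
#' matrix.
#'
#' Inputs may be in-memory objects or file paths (report/design TSV, named
#' character vector of per-species FASTA paths, gene-set file).
#'
#' @param report QuantReport data.frame or TSV path.
#' @param design design data.frame or TSV path.
#' @param proteomes named list of `proteome` objects or named character
#'   vector of FASTA paths (names = species).
#' @param contrast ordered pair of group labels (A vs B).
#' @param gene_set optional character vector of gene symbols or file path.
#' @param digest a [digest_params()] for digestion and conservation.
#' @param policy a [filter_policy()].
#' @param loess_iterations,loess_span cyclic-loess parameters; set
#'   `loess_iterations = 0` to skip loess normalization.
#' @param total_area apply total-peak-area normalization first.
#' @param alpha FDR-adjusted p-value threshold.
#' @param index optional prebuilt [build_conserved_index()] over the same
#'   proteomes (avoids re-digesting when the pipeline is run repeatedly).
#' @param out_dir optional directory; result tables and the JSON manifest
#'   are written there.
#' @return object of class `dia_pipeline_result`: filtered report, protein
#'   matrix, `fit` (a `moderated_fit`), significance `calls`, `enrichment`
#'   (or NULL), `qc`, and the run `manifest` with per-stage survival counts.
#' @export
run_pipeline <- function(report, design, proteomes, contrast,
                         gene_set = NULL,
                         digest = digest_params(),
                         policy = filter_policy(),
                         loess_iterations = 10L, loess_span = 0.7,
                         total_area = TRUE,
                         alpha = 0.005,
                         index = NULL,
                         out_dir = NULL) {
  if (is.character(report)) report <- read_quant_report(report)
  if (is.character(design)) design <- read_design(design)
  if (is.character(proteomes)) {
    stop_if_not(!is.null(names(proteomes)), "proteome paths must be named by species")
    proteomes <- mapply(read_proteome_fasta, proteomes, names(proteomes),
                        SIMPLIFY = FALSE)
  }
  if (is.character(gene_set) && length(gene_set) == 1L && file.exists(gene_set)) {
    gene_set <- read_gene_set(gene_set)
  }
  if (missing(contrast)) contrast <- unique(design$group)

  n_precursors <- function(r) length(unique(report_precursor_keys(r)))
  counts <- c(input = n_precursors(report))

  if (is.null(index)) index <- build_conserved_index(proteomes, digest)
  contrast_species <- design$species[design$group %in% contrast]
  filtered <- grouped_confidence_filter(report, design, policy, contrast)
  counts["confidence"] <- n_precursors(filtered)
  filtered <- remove_ambiguous(filtered)
  counts["ambiguity"] <- n_precursors(filtered)
  filtered <- restrict_to_conserved(filtered, index,
                                    intersect(index$species, unique(contrast_species)))
  counts["conserved"] <- n_precursors(filtered)
  stop_if_not(counts["conserved"] > 0, "no precursors survive filtering")

  pm <- peptide_matrix(filtered)
  if (total_area) pm <- total_area_normalize(pm)
  prot <- rollup_to_proteins(pm)
  if (loess_iterations > 0) {
    prot <- cyclic_loess_normalize(prot, iterations = loess_iterations,
                                   span = loess_span)
  }
  counts["proteins"] <- nrow(prot)

  fit <- fit_moderated_t(to_log2(prot), design, contrast, alpha = alpha)
  calls <- call_significant(fit)

  enrichment <- NULL
  if (!is.null(gene_set)) {
    gene_set <- unique(toupper(gene_set))
    universe <- toupper(fit$table$gene)
    de <- toupper(fit$table$gene[fit$table$significant])
    enrichment <- enrichment_chisq(de, gene_set, universe)
    enrichment$set_in_universe <- length(intersect(gene_set, universe))
  }

  species_of <- stats::setNames(design$species, design$sample_id)
  qc <- list(
    cov = compute_cov(to_linear(prot), species_of),
    r2 = pairwise_r2(prot),
    clustering = hierarchical_cluster(prot)
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("crossdia")),
    contrast = contrast,
    parameters = list(
      digest = unclass(digest), policy = unclass(policy),
      loess_iterations = loess_iterations, loess_span = loess_span,
      total_area = total_area, alpha = alpha),
    n_samples = ncol(prot),
    precursors_surviving = as.list(counts),
    significant = as.list(calls$counts)
  )

  result <- structure(list(
    filtered_report = filtered, peptide_matrix = pm, protein_matrix = prot,
    index = index, fit = fit, calls = calls, enrichment = enrichment,
    qc = qc, manifest = manifest
  ), class = "dia_pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.dia_pipeline_result <- function(x, ...) {
  cat("DIA cross-species pipeline result\n")
  cs <- x$manifest$precursors_surviving
  cat(sprintf("  precursors: %d -> confidence %d -> unambiguous %d -> conserved %d\n",
              cs$input, cs$confidence, cs$ambiguity, cs$conserved))
  cat(sprintf("  proteins quantified: %d\n", cs$proteins))
  print(x$fit)
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}

#' Write pipeline result tables and manifest
#'
#' Emits the DE results TSV, protein matrix TSV, QC JSON, the sample
#' dendrogram in Newick format, the enrichment JSON (if computed), and the
#' run manifest JSON.
#'
#' @param result a `dia_pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- result$fit$table
  utils::write.table(tab, file.path(out_dir, "de_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(result$protein_matrix, file.path(out_dir, "protein_matrix.tsv"))
  qc <- list(median_cov_percent = as.list(result$qc$cov$median),
             min_pairwise_r2 = min(result$qc$r2),
             leaf_order = result$qc$clustering$leaf_order)
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$qc$clustering$newick, file.path(out_dir, "dendrogram.nwk"))
  if (!is.null(result$enrichment)) {
    e <- result$enrichment
    jsonlite::write_json(
      list(table = as.data.frame(as.table(e$table)), statistic = e$statistic,
           df = e$df, p_value = e$p_value, odds_ratio = e$odds_ratio,
           correction_used = e$correction_used),
      file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Technical-replicate quality control
#'
#' The replicate workflow: strict confidence filter (Q <= threshold in every
#' run), total-area normalization, protein rollup and loess normalization,
#' then per-peptide and per-protein CoV and pairwise R-squared.
#'
#' @param report QuantReport of replicate runs of one preparation.
#' @param q_threshold strict Q-value threshold.
#' @param loess_iterations,loess_span cyclic-loess parameters.
#' @return list with `n_peptides`, `n_proteins`, `median_peptide_cov`,
#'   `median_protein_cov` (percent), and the replicate `r2` matrix.
#' @export
technical_qc <- function(report, q_threshold = 1e-3,
                         loess_iterations = 10L, loess_span = 0.7) {
  filtered <- strict_filter(report, q_threshold)
  filtered <- remove_ambiguous(filtered)
  pm <- total_area_normalize(peptide_matrix(filtered))
  prot <- cyclic_loess_normalize(rollup_to_proteins(pm),
                                 iterations = loess_iterations,
                                 span = loess_span)
  one_group <- stats::setNames(rep("replicate", ncol(pm)), colnames(pm))
  pep_cov <- compute_cov(pm, one_group)
  prot_cov <- compute_cov(prot, one_group)
  list(
    n_peptides = nrow(pm), n_proteins = nrow(prot),
    median_peptide_cov = unname(pep_cov$median["replicate"]),
    median_protein_cov = unname(prot_cov$median["replicate"]),
    r2 = pairwise_r2(prot)
  )
}
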