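# Differential abundance by empirical-Bayes moderated t-statistics, BH-FDR,
# gene-set chi-square enrichment, and co-expression / clustering QC.

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y` for `x > 0`, used by the
#' method-of-moments estimate of the variance-prior degrees of freedom.
#'
#' @param y positive values.
#' @return x with `trigamma(x) = y`, elementwise; `y <= 0` gives `Inf`.
#' @export
trigamma_inverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[y <= 0] <- Inf
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])   # trigamma(x) ~ 1/x^2 for small x
  todo <- which(is.na(out))
  if (length(todo)) {
    x <- 0.5 + 1 / y[todo]
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[todo]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
    out[todo] <- x
  }
  out
}

# Method-of-moments fit of the scaled inverse chi-square prior on residual
# variances: log s^2 is matched to its theoretical mean/variance through
# digamma/trigamma identities; the trigamma equation is solved by Newton
# inversion. Returns list(d0, s0_2).
fit_variance_prior <- function(s2, df) {
  pos <- s2 > 0
  if (sum(pos) < 2) {
    return(list(d0 = Inf, s0_2 = mean(s2)))
  }
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- sum((e - ebar)^2) / (n - 1) - trigamma(df / 2)
  if (evar <= 0) {
    return(list(d0 = Inf, s0_2 = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated t-test between two groups
#'
#' Fits, per protein, a two-group model on log2 abundances (group means,
#' pooled residual variance `s^2` with `d = nA + nB - 2` degrees of
#' freedom), shrinks the variances toward a prior `s0^2` with `d0` prior
#' degrees of freedom estimated from all proteins by method of moments, and
#' tests the contrast A - B with `t = log2fc / (s_tilde * sqrt(1/nA +
#' 1/nB))` on `d + d0` degrees of freedom (a normal test when `d0` is
#' infinite). P-values are BH-adjusted; the significance call at `alpha` is
#' boundary-inclusive.
#'
#' @param x log2-scale protein matrix (genes x samples).
#' @param design design data.frame covering the samples of `x`.
#' @param contrast ordered pair of group labels, A vs B (log2fc = A - B).
#' @param alpha FDR-adjusted p-value threshold for the significance call.
#' @param prior_df override for `d0`: `NULL` (estimate), a number, `0`
#'   (classical t) or `Inf`.
#' @return object of class `moderated_fit` with a per-gene results `table`,
#'   the variance-prior parameters (`d0`, `s0_2`), and the design summary.
#'   Methods: `print`, `summary`, `coef` (named log2fc vector), `plot`
#'   (volcano).
#' @export
fit_moderated_t <- function(x, design, contrast, alpha = 0.005,
                            prior_df = NULL) {
  stop_if_not(identical(matrix_scale(x), "log2"),
              "fit_moderated_t expects a log2-scale matrix (see to_log2())")
  group_of <- stats::setNames(design$group, design$sample_id)
  grp <- group_of[colnames(x)]
  stop_if_not(!anyNA(grp), "design does not cover all samples")
  if (missing(contrast)) contrast <- unique(grp)
  stop_if_not(length(contrast) == 2 && all(contrast %in% grp),
              "contrast must name two groups present in the data")
  a_cols <- which(grp == contrast[1L])
  b_cols <- which(grp == contrast[2L])
  n_a <- length(a_cols); n_b <- length(b_cols)
  stop_if_not(n_a >= 2 && n_b >= 2, "need >= 2 samples per group")
  d <- n_a + n_b - 2L
  stop_if_not(d >= 1, "zero residual degrees of freedom")

  mean_a <- rowMeans(x[, a_cols, drop = FALSE])
  mean_b <- rowMeans(x[, b_cols, drop = FALSE])
  ss_a <- rowSums((x[, a_cols, drop = FALSE] - mean_a)^2)
  ss_b <- rowSums((x[, b_cols, drop = FALSE] - mean_b)^2)
  s2 <- (ss_a + ss_b) / d

  prior <- if (is.null(prior_df)) fit_variance_prior(s2, d) else {
    list(d0 = prior_df, s0_2 = if (prior_df > 0) fit_variance_prior(s2, d)$s0_2 else NA_real_)
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
    if (d0 > 0) (d0 * s0_2 + d * s2) / (d0 + d) else s2
  }
  log2fc <- mean_a - mean_b
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  t_stat <- ifelse(se == 0, ifelse(log2fc == 0, 0, sign(log2fc) * Inf),
                   log2fc / se)
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  adj_p <- bh_adjust(p)
  direction <- ifelse(log2fc > 0, paste0("higher_in_", contrast[1L]),
                      ifelse(log2fc < 0, paste0("higher_in_", contrast[2L]),
                             "unchanged"))
  tab <- data.frame(
    gene = rownames(x),
    mean_A = mean_a, mean_B = mean_b,
    log2fc = log2fc,
    fold_change = 2^abs(log2fc),
    direction = direction,
    t = t_stat, s2 = s2, p_value = p, adj_p_value = adj_p,
    significant = adj_p <= alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    table = tab, d0 = d0, s0_2 = s0_2, df_residual = d, df_total = df_total,
    contrast = contrast, n_A = n_a, n_B = n_b, alpha = alpha
  ), class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("Moderated t fit: %s vs %s (%d vs %d samples, %d proteins)\n",
              x$contrast[1L], x$contrast[2L], x$n_A, x$n_B, nrow(x$table)))
  cat(sprintf("  prior df d0 = %.4g, prior variance s0^2 = %.4g, total df = %.4g\n",
              x$d0, x$s0_2, x$df_total))
  cat(sprintf("  significant at adjusted p <= %g: %d\n",
              x$alpha, sum(x$table$significant)))
  invisible(x)
}

#' @export
summary.moderated_fit <- function(object, alpha = object$alpha, ...) {
  calls <- call_significant(object, alpha)
  out <- list(fit = object, alpha = alpha, counts = calls$counts,
              min_sig_fold_change = if (any(object$table$adj_p_value <= alpha))
                min(object$table$fold_change[object$table$adj_p_value <= alpha])
              else NA_real_)
  class(out) <- "summary.moderated_fit"
  out
}

#' @export
print.summary.moderated_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %s: %d | %s: %d | unchanged: %d\n",
              names(x$counts)[1L], x$counts[1L],
              names(x$counts)[2L], x$counts[2L], x$counts[3L]))
  if (!is.na(x$min_sig_fold_change)) {
    cat(sprintf("  lowest significant fold change: %.3f\n", x$min_sig_fold_change))
  }
  invisible(x)
}

#' @export
coef.moderated_fit <- function(object, ...) {
  stats::setNames(object$table$log2fc, object$table$gene)
}

#' @export
plot.moderated_fit <- function(x, ...) {
  tab <- x$table
  plot(tab$log2fc, -log10(pmax(tab$adj_p_value, 1e-300)),
       pch = 20, cex = 0.5,
       col = ifelse(tab$significant, "firebrick", "grey50"),
       xlab = sprintf("log2 fold change (%s - %s)", x$contrast[1L], x$contrast[2L]),
       ylab = "-log10 adjusted p", ...)
  abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Partition genes into higher-in-A / higher-in-B / unchanged
#'
#' Significance is boundary-inclusive: adjusted p exactly equal to `alpha`
#' counts as significant.
#'
#' @param fit a [fit_moderated_t()] result.
#' @param alpha FDR threshold.
#' @return list with the three gene vectors and a named `counts` vector.
#' @export
call_significant <- function(fit, alpha = fit$alpha) {
  tab <- fit$table
  sig <- tab$adj_p_value <= alpha
  up_a <- tab$gene[sig & tab$log2fc > 0]
  up_b <- tab$gene[sig & tab$log2fc < 0]
  unchanged <- setdiff(tab$gene, c(up_a, up_b))
  counts <- stats::setNames(
    c(length(up_a), length(up_b), length(unchanged)),
    c(paste0("higher_in_", fit$contrast[1L]),
      paste0("higher_in_", fit$contrast[2L]), "unchanged"))
  list(higher_in_A = up_a, higher_in_B = up_b, unchanged = unchanged,
       counts = counts)
}

#' Gene-set enrichment among differential proteins (2x2 chi-square)
#'
#' Pearson chi-square (df 1) on the 2x2 table set/non-set x DE/non-DE, by
#' default without continuity correction (Yates available by flag). The odds
#' ratio uses the Haldane 0.5 correction when a cell is zero.
#'
#' @param de_genes genes called differentially abundant.
#' @param set_genes the gene set (e.g. synaptic plasticity proteins).
#' @param universe all analyzed genes.
#' @param correct apply the Yates continuity correction.
#' @return object of class `enrichment_result`: contingency table,
#'   statistic, df, p-value, odds ratio, correction flag.
#' @export
enrichment_chisq <- function(de_genes, set_genes, universe, correct = FALSE) {
  stop_if_not(length(universe) > 0, "empty gene universe")
  set_genes <- intersect(set_genes, universe)
  de_genes <- intersect(de_genes, universe)
  stop_if_not(length(set_genes) > 0, "gene set does not overlap the universe")
  a <- length(intersect(set_genes, de_genes))
  b <- length(set_genes) - a
  cc <- length(de_genes) - a
  dd <- length(universe) - a - b - cc
  enrichment_chisq_table(matrix(c(a, cc, b, dd), 2L,
                                dimnames = list(c("in_set", "not_in_set"),
                                                c("DE", "not_DE"))),
                         correct = correct)
}

#' @rdname enrichment_chisq
#' @param table a 2x2 contingency matrix (rows: in set / not in set,
#'   columns: DE / not DE).
#' @export
enrichment_chisq_table <- function(table, correct = FALSE) {
  stop_if_not(all(dim(table) == c(2L, 2L)), "need a 2x2 table")
  stop_if_not(all(table >= 0), "counts must be non-negative")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tb <- table
  if (any(tb == 0)) tb <- tb + 0.5  # Haldane correction for the odds ratio
  or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  structure(list(
    table = table,
    statistic = unname(ct$statistic), df = 1L,
    p_value = unname(ct$p.value), odds_ratio = unname(or),
    correction_used = correct
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("2x2 chi-square enrichment", if (x$correction_used) "(Yates-corrected)",
      "\n")
  print(x$table)
  cat(sprintf("  X-squared = %.4f, df = 1, p = %.3g, odds ratio = %.3f\n",
              x$statistic, x$p_value, x$odds_ratio))
  invisible(x)
}

#' Gene-gene Pearson correlation on log abundances
#'
#' @param x abundance matrix (>= 3 samples); linear input is
#'   log2-transformed.
#' @param genes genes (row names) to correlate; default all.
#' @return symmetric gene x gene correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, genes = rownames(x)) {
  stop_if_not(ncol(x) >= 3, "need >= 3 samples")
  missing_g <- setdiff(genes, rownames(x))
  stop_if_not(length(missing_g) == 0, "genes not in matrix: %s",
              paste(utils::head(missing_g, 3L), collapse = ", "))
  lg <- to_log2(x)
  cc <- stats::cor(t(lg[genes, , drop = FALSE]))
  diag(cc) <- 1
  cc
}

#' Unsupervised hierarchical clustering of samples
#'
#' Agglomerative average-linkage clustering on the correlation distance
#' (1 - Pearson) of log2 abundances. Samples are ordered by id before
#' clustering so the result is invariant to input column order.
#'
#' @param x abundance matrix with >= 3 samples.
#' @return object of class `sample_clustering`: the `hclust` tree, the leaf
#'   order, and the dendrogram as a Newick string.
#' @export
hierarchical_cluster <- function(x) {
  stop_if_not(ncol(x) >= 3, "need >= 3 samples")
  lg <- to_log2(x)
  lg <- lg[, order(colnames(lg)), drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(lg))
  hc <- stats::hclust(d, method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 newick = newick), class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("Average-linkage clustering (1 - Pearson) of",
      length(x$leaf_order), "samples\n")
  cat("  leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Cut the sample tree into k clusters
#'
#' @param clustering a [hierarchical_cluster()] result.
#' @param k number of clusters.
#' @return named integer vector of cluster memberships.
#' @export
cut_clusters <- function(clustering, k) {
  stats::cutree(clustering$hclust, k = k)
}
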