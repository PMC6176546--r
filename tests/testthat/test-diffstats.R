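fixture_design <- function(x, groups = c("A", "B")) {
  grp <- rep(groups, each = ncol(x) / 2)
  make_design(colnames(x), species = grp, groups = grp)
}

test_that("moderated t matches the direct-formula oracle on the fixture", {
  x <- load_modt_fixture()
  fit <- fit_moderated_t(x, fixture_design(x), c("A", "B"))
  orc <- oracle_modt(unclass(x), 1:10, 11:20)
  expect_equal(fit$d0, orc$d0, tolerance = 1e-6)
  expect_equal(fit$s0_2, orc$s0_2, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(orc$t), tolerance = 1e-6)
  expect_equal(fit$table$p_value, unname(orc$p), tolerance = 1e-6)
  expect_equal(fit$table$log2fc, unname(orc$log2fc), tolerance = 1e-12)
})

test_that("moderated t agrees with limma's empirical-Bayes implementation", {
  x <- load_modt_fixture()
  fit <- fit_moderated_t(x, fixture_design(x), c("A", "B"))
  dmat <- cbind(Intercept = 1, AvB = rep(c(1, 0), each = 10))
  lf <- limma::eBayes(limma::lmFit(unclass(x), dmat))
  expect_equal(fit$d0, lf$df.prior, tolerance = 1e-10)
  expect_equal(fit$s0_2, lf$s2.prior, tolerance = 1e-10)
  expect_equal(fit$table$t, unname(lf$t[, "AvB"]), tolerance = 1e-10)
  expect_equal(fit$table$p_value, unname(lf$p.value[, "AvB"]), tolerance = 1e-10)
})

test_that("prior-df limits recover the classical t and the z statistic", {
  x <- load_modt_fixture()
  des <- fixture_design(x)
  # d0 = 0: classical pooled-variance two-sample t for every gene
  fit0 <- fit_moderated_t(x, des, c("A", "B"), prior_df = 0)
  classical <- apply(unclass(x), 1, function(v) {
    unname(t.test(v[1:10], v[11:20], var.equal = TRUE)$statistic)
  })
  expect_equal(fit0$table$t, unname(classical), tolerance = 1e-9)
  expect_equal(fit0$df_total, 18)
  # d0 = Inf: z statistic with constant variance s0^2
  fit_inf <- fit_moderated_t(x, des, c("A", "B"), prior_df = Inf)
  se <- sqrt(fit_inf$s0_2 * (1 / 10 + 1 / 10))
  expect_equal(fit_inf$table$t, fit_inf$table$log2fc / se, tolerance = 1e-12)
  expect_equal(fit_inf$table$p_value,
               2 * pnorm(-abs(fit_inf$table$t)), tolerance = 1e-12)
  # large finite d0 approaches the d0 = Inf limit
  fit_big <- fit_moderated_t(x, des, c("A", "B"), prior_df = 1e8)
  expect_equal(fit_big$table$t, fit_inf$table$t, tolerance = 1e-4)
})

test_that("identical group means give t = 0 and p = 1", {
  set.seed(17)
  x <- matrix(rnorm(80), 4, 20, dimnames = list(paste0("g", 1:4),
                                                paste0("s", 1:20)))
  x[1, 11:20] <- x[1, 1:10]  # exactly equal group profiles
  fit <- fit_moderated_t(abundance_matrix(x, "log2"),
                         fixture_design(x), c("A", "B"))
  expect_equal(fit$table$t[1], 0)
  expect_equal(fit$table$p_value[1], 1)
})

test_that("all-identical variances give an infinite prior without overflow", {
  x <- matrix(rep(c(1, 2), each = 3), 5, 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  x <- x + rep(seq(0, 0.4, 0.1), 6) * 0  # constant within groups
  des <- make_design(paste0("s", 1:6), rep(c("A", "B"), each = 3),
                     rep(c("A", "B"), each = 3))
  fit <- fit_moderated_t(abundance_matrix(x, "log2"), des, c("A", "B"))
  expect_true(is.infinite(fit$d0))
  expect_true(all(is.finite(fit$table$p_value)))
  expect_true(all(abs(fit$table$t) == Inf | fit$table$t == 0))
})

test_that("trigamma_inverse inverts trigamma over many magnitudes", {
  y <- 10^seq(-6, 6, length.out = 40)
  x <- trigamma_inverse(y)
  expect_equal(trigamma(x), y, tolerance = 1e-7)
  expect_identical(trigamma_inverse(0), Inf)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(18)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH at alpha 0.005 controls the false discovery proportion under the null", {
  set.seed(30)
  des <- make_design(paste0("s", 1:20), rep(c("A", "B"), each = 10),
                     rep(c("A", "B"), each = 10))
  fdp <- replicate(200, {
    x <- matrix(rnorm(500 * 20, sd = rep(sqrt(0.02 * 4 / rchisq(500, 4)), 20)),
                500, 20, dimnames = list(paste0("g", 1:500), paste0("s", 1:20)))
    fit <- fit_moderated_t(abundance_matrix(x, "log2"), des, c("A", "B"))
    n_sig <- sum(fit$table$significant)
    n_sig / max(1, n_sig)
  })
  mcse <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.005 + 3 * mcse)
})

test_that("significance calls are boundary-inclusive and direction-aware", {
  fit <- structure(list(
    table = data.frame(gene = c("g1", "g2", "g3"),
                       log2fc = c(1, -1, 0.2),
                       adj_p_value = c(0.005, 0.001, 0.5)),
    contrast = c("rodent", "primate"), alpha = 0.005), class = "moderated_fit")
  calls <- call_significant(fit)
  expect_equal(calls$higher_in_A, "g1")   # adj p == alpha counts
  expect_equal(calls$higher_in_B, "g2")
  expect_equal(calls$unchanged, "g3")
  expect_equal(unname(calls$counts), c(1, 1, 1))
})

test_that("chi-square enrichment matches the closed-form 2x2 oracle", {
  # equal proportions: no association
  eq <- enrichment_chisq_table(matrix(10, 2, 2))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # random small tables against the closed form
  set.seed(19)
  for (i in 1:40) {
    tb <- matrix(sample(1:50, 4, replace = TRUE), 2)
    got <- enrichment_chisq_table(tb, correct = FALSE)
    want <- oracle_chisq_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  # Haldane-corrected odds ratio for zero cells
  z <- enrichment_chisq_table(matrix(c(5, 0, 3, 7), 2))
  expect_true(is.finite(z$odds_ratio))
  expect_error(enrichment_chisq(character(0), character(0), character(0)),
               "empty gene universe")
})

test_that("plasticity-set contingency from the cross-species comparison is enriched", {
  # quantified universe 1642 with 779 differential; plasticity set 340 genes,
  # 188 of them differential
  a <- 188; b <- 340 - 188; cc <- 779 - 188; dd <- (1642 - 340) - cc
  res <- enrichment_chisq_table(matrix(c(a, cc, b, dd), 2))
  expect_lte(res$p_value, 0.005)
  res_yates <- enrichment_chisq_table(matrix(c(a, cc, b, dd), 2), correct = TRUE)
  expect_lte(res_yates$p_value, 0.005)
  expect_gt(res$odds_ratio, 1)
})

test_that("gene-gene correlations behave on proportional profiles", {
  s <- 2^seq(1, 6)
  m <- abundance_matrix(rbind(g1 = s, g2 = 3 * s, g3 = rev(s)), "linear")
  colnames(m) <- paste0("s", 1:6)
  cc <- correlation_matrix(abundance_matrix(unclass(m), "linear"))
  expect_equal(cc["g1", "g2"], 1)
  expect_equal(cc["g1", "g3"], -1)
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_error(correlation_matrix(m, genes = "nope"), "not in matrix")
})

test_that("sample clustering is order-invariant and groups duplicates first", {
  set.seed(20)
  x <- matrix(2^rnorm(400, 10, 1), 100, 4,
              dimnames = list(paste0("f", 1:100), c("a", "b", "c", "d")))
  x[, "b"] <- x[, "a"]                      # exact duplicate pair
  x[, "d"] <- x[, "c"] * 2^rnorm(100, 0, 2) # decorrelate the others
  cl <- hierarchical_cluster(abundance_matrix(x, "linear"))
  merged_first <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-merged_first], c("a", "b"))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  # permuting the columns changes nothing
  xp <- x[, c(3, 1, 4, 2)]
  clp <- hierarchical_cluster(abundance_matrix(xp, "linear"))
  expect_identical(cl$leaf_order, clp$leaf_order)
  expect_identical(cl$newick, clp$newick)
  # the Newick string round-trips through a tree parser
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, c("a", "b", "c", "d"))
})

test_that("species are recovered by clustering when species effects dominate", {
  cfg <- small_config(seed = 21, species_effect_sd = 0.5, noise_cv = 0.1,
                      n_genes = 200)
  ds <- simulate_dataset(cfg)
  pm <- peptide_matrix(remove_ambiguous(ds$report))
  prot <- rollup_to_proteins(pm)
  cl <- hierarchical_cluster(prot)
  members <- cut_clusters(cl, 4)
  tab <- table(members, sub("_[0-9]+$", "", names(members)))
  expect_true(all(rowSums(tab > 0) == 1))
})
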