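test_that("total-area normalization equalizes column totals to the mean", {
  m <- abundance_matrix(matrix(c(40, 60, 80, 120), 2,
                               dimnames = list(c("p1", "p2"), c("a", "b"))),
                        "linear")
  out <- total_area_normalize(m)
  expect_equal(unname(attr(out, "scale_factors")), c(1.5, 0.75))
  expect_equal(unname(colSums(out)), c(150, 150))
  # relative intensities within a sample unchanged
  expect_equal(out["p1", "a"] / out["p2", "a"], m["p1", "a"] / m["p2", "a"])
  # already-equal totals: identity
  m2 <- abundance_matrix(matrix(c(1, 2, 2, 1), 2), "linear")
  expect_equal(unclass(total_area_normalize(m2))[, ],
               unclass(m2)[, ], tolerance = 1e-12)
  m3 <- abundance_matrix(matrix(c(1, 1, 0, 0), 2), "linear")
  expect_error(total_area_normalize(m3), "zero column total")
})

test_that("protein rollup sums peptide intensities per gene", {
  m <- abundance_matrix(matrix(c(10, 20, 30, 1, 2, 3), 3,
                               dimnames = list(c("p1", "p2", "p3"),
                                               c("s1", "s2"))), "linear")
  map <- c(p1 = "GA", p2 = "GA", p3 = "GA")
  out <- rollup_to_proteins(m, map)
  expect_equal(out["GA", ], c(s1 = 60, s2 = 6))
  # total signal conservation
  expect_equal(colSums(out), colSums(m))
  # single peptide per gene: identity up to row naming
  map2 <- c(p1 = "G1", p2 = "G2", p3 = "G3")
  out2 <- rollup_to_proteins(m, map2)
  expect_equal(unname(unclass(out2)), unname(unclass(m)))
  expect_error(rollup_to_proteins(m, c(p1 = "GA", p2 = "GA;GB", p3 = "GA")),
               "multiple genes")
  expect_error(rollup_to_proteins(m, c(p1 = "GA", p2 = "GA")), "no gene mapping")
})

test_that("normalization commutes with rollup (scaling vs summation)", {
  set.seed(13)
  m <- abundance_matrix(matrix(runif(60, 10, 1000), 20,
                               dimnames = list(paste0("p", 1:20),
                                               paste0("s", 1:3))), "linear")
  map <- stats::setNames(paste0("G", rep(1:5, each = 4)), paste0("p", 1:20))
  a <- rollup_to_proteins(total_area_normalize(m), map)
  f <- attr(total_area_normalize(m), "scale_factors")
  b <- sweep(rollup_to_proteins(m, map), 2, f, "*")
  expect_equal(unclass(a)[, ], unclass(b)[, ], tolerance = 1e-12)
})

test_that("cyclic loess removes constant offsets and is a fixed point", {
  set.seed(14)
  g <- 1500
  base <- 2^rnorm(g, 10, 2)
  m <- matrix(base, g, 5, dimnames = list(paste0("f", 1:g), paste0("s", 1:5)))
  m[, 1] <- m[, 1] * 2      # +1 on log2 scale
  m[, 2] <- m[, 2] / 2      # -1 on log2 scale
  m <- abundance_matrix(m, "linear")
  out <- to_log2(cyclic_loess_normalize(m, iterations = 10))
  M <- out - rowMeans(out)
  expect_lt(median(abs(M)), 0.01)
  # identical columns are left untouched
  m_flat <- abundance_matrix(matrix(base, g, 4), "linear")
  expect_equal(unclass(cyclic_loess_normalize(m_flat))[, ],
               unclass(m_flat)[, ], tolerance = 1e-9)
  # idempotence on converged data
  once <- cyclic_loess_normalize(m, iterations = 10)
  twice <- cyclic_loess_normalize(once, iterations = 10)
  expect_lt(max(abs(unclass(twice) - unclass(once)) / unclass(once)), 1e-6)
  # rank order within each sample preserved
  expect_identical(apply(unclass(out), 2, order), apply(unclass(m), 2, order))
  m_bad <- m; m_bad[3, 2] <- 0
  expect_error(cyclic_loess_normalize(abundance_matrix(m_bad, "linear")),
               "non-positive")
})

test_that("iBAQ divides by observable peptides and guards zero counts", {
  expect_equal(compute_ibaq(100, 4), 25)
  expect_equal(compute_ibaq(0, 4), 0)
  expect_true(is.na(compute_ibaq(100, 0)))
  expect_equal(compute_ibaq(c(100, 50, 10), c(4, 0, 2)), c(25, NA, 5))
})

test_that("protein groups merge to genes by iBAQ summation", {
  groups <- data.frame(group_id = c("g1", "g2", "g3", "g4"),
                       genes = c("GENEA", "GENEA", "GENEA;GENEB", "GENEC"),
                       ibaq = c(10, 5, 99, 7), stringsAsFactors = FALSE)
  out <- merge_groups_by_gene(groups)
  expect_equal(out$ibaq[out$gene == "GENEA"], 15)
  expect_equal(out$ibaq[out$gene == "GENEC"], 7)
  expect_false("GENEB" %in% out$gene)
  expect_equal(attr(out, "n_ambiguous_dropped"), 1)
  # all singleton distinct genes: identity
  g2 <- data.frame(group_id = c("a", "b"), genes = c("X", "Y"), ibaq = c(1, 2))
  expect_equal(merge_groups_by_gene(g2)$ibaq, c(1, 2))
})

test_that("CoV uses the unbiased sd on linear scale, as a percentage", {
  m <- abundance_matrix(matrix(c(9, 10, 11, 5, 5, 5), 2, byrow = TRUE,
                               dimnames = list(c("f1", "f2"),
                                               c("s1", "s2", "s3"))), "linear")
  covs <- compute_cov(m, c(s1 = "mouse", s2 = "mouse", s3 = "mouse"))
  expect_equal(unname(covs$per_feature["f1", "mouse"]), 10)
  expect_equal(unname(covs$per_feature["f2", "mouse"]), 0)
  expect_error(compute_cov(m, c(s1 = "a", s2 = "b", s3 = "b")), "< 2 samples")
})

test_that("pairwise R-squared is computed on log scale", {
  set.seed(15)
  v <- 2^rnorm(1e4, 8, 1.5)
  m <- abundance_matrix(cbind(s1 = v, s2 = v, s3 = 2^rnorm(1e4, 8, 1.5)),
                        "linear")
  r2 <- pairwise_r2(m)
  expect_equal(r2["s1", "s2"], 1)
  expect_lt(r2["s1", "s3"], 0.01)
  expect_identical(r2, t(r2))
  expect_equal(unname(diag(r2)), rep(1, 3))
})

test_that("relative scaling makes rows sum to one", {
  m <- matrix(c(2, 3, 5, 4, 4, 4), 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  out <- scale_relative(m)
  expect_equal(unname(out["f1", ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(out["f2", ]), rep(1 / 3, 3))
  expect_equal(unname(rowSums(out)), c(1, 1), tolerance = 1e-12)
  m0 <- m; m0[1, ] <- 0
  expect_error(scale_relative(m0), "no positive value")
})

test_that("rollup reduces technical noise: protein CoV <= peptide CoV", {
  cfg <- small_config(seed = 16, noise_cv = 0.08)
  tr <- simulate_technical_replicates(cfg, n_reps = 4)
  pm <- peptide_matrix(tr$report)
  prot <- rollup_to_proteins(pm)
  grp <- stats::setNames(rep("rep", ncol(pm)), colnames(pm))
  expect_lte(compute_cov(prot, grp)$median[["rep"]],
             compute_cov(pm, grp)$median[["rep"]])
})
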