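# Panel selection: LASSO CV, per-gene AUC, diagnostic gate.

test_that("Mann-Whitney AUC equals trapezoidal ROC integration", {
  set.seed(21)
  for (i in 1:200) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    pos <- rnorm(n1); neg <- rnorm(n2, mean = runif(1, -1, 1))
    if (i %% 4 == 0) { pos <- round(pos); neg <- round(neg) }  # force ties
    st <- expression_study(
      matrix(c(pos, neg), 1, dimnames = list("g",
                                             sprintf("s%02d", 1:(n1 + n2)))),
      setNames(rep(c("p", "n"), c(n1, n2)), sprintf("s%02d", 1:(n1 + n2))))
    r <- per_gene_auc(st, "g", "p", "n")
    trap <- sum(diff(r$curve$fpr) *
                  (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(tail(r$curve$tpr, 1), 1)
  }
})

test_that("per-gene AUC hand examples and symmetry", {
  m <- matrix(c(3, 1, 2, 0), 1, dimnames = list("g", paste0("s", 1:4)))
  st <- expression_study(m, setNames(c("p", "p", "n", "n"), colnames(m)))
  expect_equal(per_gene_auc(st, "g", "p", "n")$auc, 0.75)
  expect_equal(per_gene_auc(st, "g", "n", "p")$auc, 0.25)  # AUC + AUC' = 1
  # perfect separation
  m2 <- matrix(c(5, 6, 1, 2), 1, dimnames = list("g", paste0("s", 1:4)))
  st2 <- expression_study(m2, setNames(c("p", "p", "n", "n"), colnames(m2)))
  expect_equal(per_gene_auc(st2, "g", "p", "n")$auc, 1)
  # constant expression is flagged at 0.5
  m3 <- matrix(2, 1, 4, dimnames = list("g", paste0("s", 1:4)))
  st3 <- expression_study(m3, setNames(c("p", "p", "n", "n"), colnames(m3)))
  r3 <- per_gene_auc(st3, "g", "p", "n")
  expect_true(r3$flagged)
  expect_equal(r3$auc, 0.5)
})

test_that("lasso_cv recovers planted genes with the sparser 1se panel nested", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_study(sim_config(
      n_genes = 200, n_de_genes = 5, effect_size_log2 = 3, noise_sd = 0.5,
      n_modules = 0, group_sizes = c(MM = 10, MM_ONJ = 11), seed = s))
    lp <- suppressWarnings(lasso_cv(sim$study, "MM_ONJ", "MM", seed = s))
    # invariant that must always hold
    expect_gte(lp$lambda_1se, lp$lambda_min)
    # nesting of the 1se panel inside the lambda_min panel (and matching
    # size ordering) is the typical regime but not a lasso-path theorem:
    # variables can drop and re-enter along the path, so it is asserted
    # only for the seed majority together with planted recovery
    all(lp$panel_1se %in% lp$panel_min) &&
      sum(sim$truth_de_genes %in% lp$panel_min) >= 4
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("pure-noise studies keep the lambda_1se panel small", {
  # With the 100-point grid reaching lambda_max * 1e-4, occasional CV minima
  # at deep lambdas pull lambda_1se below the entry point, so the null 1se
  # panel is empty in about half the draws (measured over 40 seeds) rather
  # than always: assert emptiness in a nontrivial fraction plus a tight
  # bound on the mean panel size.
  sizes <- vapply(1:20, function(s) {
    sim <- simulate_study(sim_config(
      n_genes = 150, n_de_genes = 0, n_modules = 0,
      group_sizes = c(MM = 10, MM_ONJ = 11), seed = 100 + s))
    lp <- suppressWarnings(lasso_cv(sim$study, "MM_ONJ", "MM", seed = s))
    length(lp$panel_1se)
  }, numeric(1))
  expect_gte(mean(sizes == 0), 0.3)
  expect_lte(mean(sizes), 2)
})

test_that("the largest lambda zeroes every coefficient", {
  sim <- simulate_study(sim_config(n_genes = 80, n_de_genes = 3,
                                   effect_size_log2 = 2, n_modules = 0,
                                   group_sizes = c(A = 8, B = 8), seed = 2))
  lp <- suppressWarnings(lasso_cv(sim$study, "B", "A", seed = 1))
  expect_equal(unname(lp$n_nonzero[1]), 0L)
})

test_that("lasso_cv is seed-reproducible and invariant to sample order", {
  sim <- simulate_study(sim_config(n_genes = 100, n_de_genes = 4,
                                   effect_size_log2 = 3, noise_sd = 0.5,
                                   n_modules = 0,
                                   group_sizes = c(A = 9, B = 9), seed = 3))
  st <- sim$study
  a <- suppressWarnings(lasso_cv(st, "B", "A", seed = 5))
  b <- suppressWarnings(lasso_cv(st, "B", "A", seed = 5))
  expect_identical(a$panel_min, b$panel_min)
  expect_identical(a$cv_mean, b$cv_mean)
  set.seed(1)
  perm <- sample(ncol(st$matrix))
  st2 <- expression_study(st$matrix[, perm], st$groups[perm])
  c2 <- suppressWarnings(lasso_cv(st2, "B", "A", seed = 5))
  expect_setequal(c2$panel_min, a$panel_min)
})

test_that("single-feature input falls back to plain logistic regression", {
  sim <- simulate_study(sim_config(n_genes = 10, n_de_genes = 1,
                                   effect_size_log2 = 2, n_modules = 0,
                                   group_sizes = c(A = 8, B = 8), seed = 4))
  expect_warning(
    lp <- lasso_cv(sim$study, "B", "A", genes = sim$truth_de_genes,
                   n_folds = 5, seed = 1),
    "single usable feature")
  expect_true(lp$fallback)
  expect_identical(lp$panel_1se, sim$truth_de_genes)
})

test_that("diagnostic gate is strict, sorted and monotone", {
  sim <- simulate_study(sim_config(n_genes = 30, n_de_genes = 3,
                                   effect_size_log2 = 3, noise_sd = 0.5,
                                   n_modules = 0,
                                   group_sizes = c(Healthy = 5, MM_ONJ = 11),
                                   seed = 5))
  st <- sim$study
  genes <- rownames(st$matrix)
  gate <- diagnostic_gate(st, genes, "MM_ONJ", "Healthy",
                          auc_cut = 0.9, padj_cut = 0.05)
  expect_true(all(sim$truth_de_genes %in% gate$genes))
  expect_false(any(setdiff(genes, sim$truth_de_genes)[1:5] %in% gate$genes))
  expect_equal(gate$table$auc, sort(gate$table$auc, decreasing = TRUE))
  # strict boundary: auc_cut = 1 excludes even perfect separators
  gate1 <- diagnostic_gate(st, genes, "MM_ONJ", "Healthy", auc_cut = 1)
  expect_length(gate1$genes, 0)
  # monotone: lowering auc_cut never removes genes
  lower <- diagnostic_gate(st, genes, "MM_ONJ", "Healthy",
                           auc_cut = 0.5, padj_cut = 0.05)
  expect_true(all(gate$genes %in% lower$genes))
})
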