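# Co-expression: TOM, scale-free fit, module detection/merging, eigengenes,
# module-trait correlation.

test_that("TOM matches the triple-loop oracle and hand examples", {
  # complete triangle: TOM_ij = (1+1)/(2+1-1) = 1
  a <- matrix(1, 3, 3); diag(a) <- 0
  expect_equal(topological_overlap(a), matrix(1, 3, 3))
  # disconnected pair with no shared neighbors
  b <- matrix(0, 4, 4); b[1, 2] <- b[2, 1] <- 0  # all zero
  b[3, 4] <- b[4, 3] <- 0.5
  tomb <- topological_overlap(b)
  expect_equal(tomb[1, 2], 0)
  expect_equal(tomb[1, 3], 0)
  set.seed(3)
  for (i in 1:5) {
    n <- 15
    r <- matrix(runif(n * n), n, n)
    adj <- (r + t(r)) / 2
    diag(adj) <- 0
    tom <- topological_overlap(adj)
    expect_equal(tom, tom_naive(adj), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
  bad <- matrix(runif(9), 3, 3)
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("scale-free fit matches an independent binned regression", {
  set.seed(4)
  # strongly power-law connectivity scores near 1; oracle agrees exactly
  k <- round(exp(rnorm(2000, mean = 2, sd = 1)))
  k <- k[k >= 1]
  fit <- scale_free_fit(k)
  oracle <- {
    cut_k <- cut(k, breaks = 10, include.lowest = TRUE)
    freq <- as.vector(table(cut_k)) / length(k)
    mk <- tapply(k, cut_k, mean)
    ok <- !is.na(mk) & freq > 0 & mk > 0
    f <- lm(log10(freq[ok]) ~ log10(mk[ok]))
    unname(-sign(coef(f)[2]) * summary(f)$r.squared)
  }
  expect_equal(fit, oracle, tolerance = 1e-12)
  expect_gt(fit, 0.8)
  expect_true(is.na(scale_free_fit(rep(2, 50))))  # constant connectivity
})

test_that("soft-threshold scan obeys connectivity monotonicity and fallback", {
  sim <- simulate_study(sim_config(n_genes = 60, n_de_genes = 0,
                                   n_modules = 2, module_size = 15,
                                   module_loading = 0.8,
                                   group_sizes = c(A = 15, B = 15), seed = 2))
  scan <- scan_soft_threshold(sim$study, powers = c(1, 2, 4, 6))
  expect_gte(scan$mean_connectivity[1], scan$mean_connectivity[4])
  expect_true(scan$chosen_power %in% c(1, 2, 4, 6))
  # degenerate input: identical genes -> warning and NA-safe result
  m <- matrix(rep(rnorm(10), each = 5), 5, 10, byrow = FALSE)
  m <- m + matrix(rnorm(50, sd = 1e-8), 5, 10)
  dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:10))
  st <- expression_study(m, setNames(rep("x", 10), colnames(m)))
  expect_warning(scan_soft_threshold(st, powers = c(1, 2)))
})

test_that("planted modules are recovered with high Jaccard overlap", {
  sim <- simulate_study(sim_config(n_genes = 80, n_de_genes = 0,
                                   n_modules = 2, module_size = 20,
                                   module_loading = 0.9,
                                   group_sizes = c(A = 30, B = 30), seed = 3))
  dec <- detect_modules(sim$study, power = 6, min_module_size = 10)
  found <- split(names(dec$assignment), dec$assignment)
  found <- found[setdiff(names(found), "grey")]
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (truth in sim$truth_modules)
    expect_gte(max(vapply(found, jac, numeric(1), b = truth)), 0.8)
})

test_that("no co-expression structure leaves most genes grey", {
  sim <- simulate_study(sim_config(n_genes = 100, n_de_genes = 0,
                                   n_modules = 0,
                                   group_sizes = c(A = 13, B = 13), seed = 4))
  dec <- detect_modules(sim$study, power = 6, min_module_size = 10)
  expect_gte(mean(dec$assignment == "grey"), 0.9)
})

test_that("module recovery is stable in adjusted Rand index across seeds", {
  ari <- vapply(1:10, function(s) {
    sim <- simulate_study(sim_config(n_genes = 60, n_de_genes = 0,
                                     n_modules = 3, module_size = 15,
                                     module_loading = 0.8,
                                     group_sizes = c(A = 30, B = 30),
                                     seed = s))
    dec <- detect_modules(sim$study, power = 6, min_module_size = 8)
    truth <- setNames(rep("grey", 60), rownames(sim$study$matrix))
    for (nm in names(sim$truth_modules)) truth[sim$truth_modules[[nm]]] <- nm
    adjusted_rand(truth, dec$assignment[names(truth)])
  }, numeric(1))
  expect_gte(mean(ari), 0.7)
})

test_that("gene order does not change the decomposition", {
  sim <- simulate_study(sim_config(n_genes = 50, n_de_genes = 0,
                                   n_modules = 2, module_size = 12,
                                   module_loading = 0.9,
                                   group_sizes = c(A = 20, B = 20), seed = 5))
  st <- sim$study
  set.seed(1)
  perm <- sample(nrow(st$matrix))
  st_perm <- expression_study(st$matrix[perm, ], st$groups)
  d1 <- detect_modules(st, 6, min_module_size = 8)
  d2 <- detect_modules(st_perm, 6, min_module_size = 8)
  expect_identical(d1$assignment[sort(names(d1$assignment))],
                   d2$assignment[sort(names(d2$assignment))])
})

test_that("eigengenes have unit variance and track the latent factor", {
  sim <- simulate_study(sim_config(n_genes = 40, n_de_genes = 0,
                                   n_modules = 1, module_size = 20,
                                   module_loading = 0.9,
                                   group_sizes = c(A = 25, B = 25), seed = 6))
  assignment <- setNames(rep("grey", 40), rownames(sim$study$matrix))
  assignment[sim$truth_modules[[1]]] <- "M1"
  me <- module_eigengenes(sim$study, assignment)
  expect_equal(unname(apply(me, 1, var)), 1, tolerance = 1e-12)
  # the eigengene recovers the factor: proxy = module mean profile
  module_mean <- rowMeans(scale(t(sim$study$matrix[sim$truth_modules[[1]], ])))
  expect_gte(abs(cor(me["M1", ], module_mean)), 0.95)
  expect_gte(cor(me["M1", ], module_mean), 0)  # sign-aligned
  # single-gene module: the gene's standardized profile
  a2 <- setNames(c("M1", rep("grey", 39)), names(assignment))
  me2 <- module_eigengenes(sim$study, a2)
  z <- scale(sim$study$matrix[names(a2)[1], ])[, 1]
  expect_equal(abs(cor(me2[1, ], z)), 1, tolerance = 1e-12)
})

test_that("modules sharing a factor merge; cut 0 merges nothing", {
  sim <- simulate_study(sim_config(n_genes = 60, n_de_genes = 0,
                                   n_modules = 1, module_size = 30,
                                   module_loading = 0.9,
                                   group_sizes = c(A = 25, B = 25), seed = 7))
  # split the one true module into two artificial halves
  genes <- sim$truth_modules[[1]]
  assignment <- setNames(rep("grey", 60), rownames(sim$study$matrix))
  assignment[genes[1:15]] <- "A"
  assignment[genes[16:30]] <- "B"
  dec <- structure(list(assignment = assignment,
                        eigengenes = module_eigengenes(sim$study, assignment),
                        merged_from = list(A = "A", B = "B"),
                        power = 6,
                        study_samples = colnames(sim$study$matrix)),
                   class = "module_decomposition")
  merged <- merge_modules(sim$study, dec, 0.25)
  expect_equal(nrow(merged$eigengenes), 1)
  expect_setequal(merged$merged_from[["M1"]], c("A", "B"))
  none <- merge_modules(sim$study, dec, 0)
  expect_equal(nrow(none$eigengenes), 2)
})

test_that("module-trait correlation behaves on constructed eigengenes", {
  groups <- setNames(rep(c("case", "ctrl"), each = 6), sprintf("s%02d", 1:12))
  trait <- as.numeric(groups == "case")
  me <- rbind(M1 = trait, M2 = rnorm(12))
  colnames(me) <- names(groups)
  dec <- structure(list(assignment = NULL, eigengenes = me,
                        merged_from = NULL, power = 6,
                        study_samples = names(groups)),
                   class = "module_decomposition")
  tab <- module_trait_correlation(dec, groups, list(t1 = c("case", "ctrl")))
  expect_equal(tab$r[tab$module == "M1"], 1, tolerance = 1e-12)
  expect_lt(tab$p[tab$module == "M1"], 1e-6)
  flipped <- module_trait_correlation(dec, groups, list(t1 = c("ctrl", "case")))
  expect_equal(flipped$r, -tab$r, tolerance = 1e-12)
  expect_equal(flipped$p, tab$p, tolerance = 1e-12)
})

test_that("planted trait-linked module correlates with its trait", {
  sim <- simulate_study(sim_config(n_genes = 80, n_de_genes = 0,
                                   n_modules = 1, module_size = 30,
                                   module_loading = 0.9, noise_sd = 0.5,
                                   module_de_shift = 3, seed = 8))
  dec <- detect_modules(sim$study, power = 6, min_module_size = 10)
  tab <- module_trait_correlation(dec, sim$study$groups,
                                  list(onj = c("MM_ONJ", "Healthy")))
  expect_gt(max(abs(tab$r), na.rm = TRUE), 0.7)
})
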