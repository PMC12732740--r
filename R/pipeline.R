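# Pipeline orchestration: the discovery workflow (differential expression
# -> co-expression modules -> DEG/module intersection -> LASSO panel +
# centrality consensus) and the validation workflow (nested CV + 0.632+
# bootstrap), each producing a manifest of stage decisions and, when an
# output directory is given, TSV artifacts with content hashes.

write_stage_table <- function(df, out_dir, name, manifest) {
  if (is.null(out_dir)) return(manifest)
  path <- file.path(out_dir, paste0(name, ".tsv"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$hashes[[name]] <- file_hash(path)
  manifest
}

#' Run the discovery workflow
#'
#' Stages, in order: moderated-t differential expression and the
#' |log2FC| / p screen; variance filtering, soft-threshold selection and
#' module detection with eigengene merging; module-trait correlation for
#' the requested comparison; intersection of the DEGs with the genes of
#' trait-significant modules (the candidate pool); LASSO panel selection on
#' the pool; and, when an interaction graph is supplied, centrality
#' consensus hubs on the graph restricted to the pool. An empty DEG set or
#' empty pool skips the downstream stages with explicit manifest notes.
#'
#' @param study an `expression_study` (gene-level; collapse probes first).
#' @param group_pos,group_neg the comparison (`group_pos` is the case).
#' @param graph optional `igraph` interaction network.
#' @param lfc_cut,p_cut DEG screen cuts (defaults 1, 0.05).
#' @param keep_fraction variance-filter fraction for the module stage.
#' @param min_module_size,merge_cut module detection parameters.
#' @param power soft-thresholding power (NULL = choose by scan).
#' @param n_folds LASSO CV folds.
#' @param top_k,min_methods centrality consensus parameters.
#' @param seed master seed.
#' @param out_dir optional directory for TSV artifacts (created if needed).
#' @return list with `degs`, `modules` (`module_decomposition`),
#'   `trait_table`, `pool`, `lasso` (`regularization_path` or NULL),
#'   `hubs`, `manifest`.
#' @export
run_discovery <- function(study, group_pos, group_neg, graph = NULL,
                          lfc_cut = 1, p_cut = 0.05, keep_fraction = 0.75,
                          min_module_size = 20, merge_cut = 0.25,
                          power = NULL, n_folds = 10, top_k = 10,
                          min_methods = 3, seed = 1, out_dir = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list(notes = character(0), hashes = list(), timings = list(),
                   config = list(group_pos = group_pos, group_neg = group_neg,
                                 lfc_cut = lfc_cut, p_cut = p_cut,
                                 seed = seed))
  note <- function(msg) manifest$notes <<- c(manifest$notes, msg)
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    manifest$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  dex <- timed("dex", moderated_t(study, group_pos, group_neg))
  degs <- screen_degs(dex, lfc_cut, p_cut)
  note(sprintf("dex: %d DEGs at |log2FC| > %g and p < %g",
               length(degs), lfc_cut, p_cut))
  manifest <- write_stage_table(dex, out_dir, "dex", manifest)

  filtered <- variance_filter(study, keep_fraction)
  scan <- timed("soft_threshold",
                suppressWarnings(scan_soft_threshold(filtered)))
  beta <- if (is.null(power)) scan$chosen_power else power
  note(sprintf("coexpr: beta = %d (criterion %s)", beta,
               if (scan$reached_criterion) "reached" else "fallback"))
  decomp <- timed("modules",
                  detect_modules(filtered, beta,
                                 min_module_size = min_module_size))
  decomp <- merge_modules(filtered, decomp, merge_cut)
  note(sprintf("coexpr: %d modules after merging (cut %g), %d genes grey",
               nrow(decomp$eigengenes), merge_cut,
               sum(decomp$assignment == "grey")))
  assign_df <- data.frame(gene = names(decomp$assignment),
                          module = decomp$assignment)
  manifest <- write_stage_table(assign_df, out_dir, "modules", manifest)

  traits <- list(); traits[[paste0(group_pos, "_vs_", group_neg)]] <-
    c(group_pos, group_neg)
  trait_tab <- if (nrow(decomp$eigengenes))
    module_trait_correlation(decomp, study$groups, traits) else NULL
  sig_modules <- if (!is.null(trait_tab))
    unique(trait_tab$module[trait_tab$significant]) else character(0)
  module_genes <- names(decomp$assignment)[
    decomp$assignment %in% sig_modules]
  note(sprintf("coexpr: %d trait-significant modules spanning %d genes",
               length(sig_modules), length(module_genes)))
  if (!is.null(trait_tab))
    manifest <- write_stage_table(trait_tab, out_dir, "module_trait", manifest)

  pool <- intersect(degs, module_genes)
  note(sprintf("pool: %d genes in DEGs x significant-module intersection",
               length(pool)))

  lasso <- NULL; hubs <- NULL
  if (!length(degs)) {
    note("dex: empty DEG set; downstream selection skipped")
  } else if (length(pool) < 2) {
    note("pool too small (< 2 genes); LASSO and netrank skipped")
  } else {
    lasso <- timed("lasso",
                   tryCatch(lasso_cv(study, group_pos, group_neg,
                                     genes = pool, n_folds = n_folds,
                                     seed = seed),
                            error = function(e) { note(paste("lasso failed:",
                                                             conditionMessage(e))); NULL }))
    if (!is.null(lasso))
      note(sprintf("lasso: %d genes at lambda_min, %d at lambda_1se",
                   length(lasso$panel_min), length(lasso$panel_1se)))
    if (!is.null(graph)) {
      sub_nodes <- intersect(igraph::V(graph)$name, pool)
      if (length(sub_nodes) >= 2) {
        sub <- igraph::induced_subgraph(graph, sub_nodes)
        ct <- timed("netrank",
                    compute_centralities(sub, k = top_k,
                                         seed = child_seed(seed, 9)))
        hubs <- consensus_hubs(ct, min_methods)
        note(sprintf("netrank: %d consensus hubs (>= %d of %d methods)",
                     length(hubs$hubs), min_methods, length(ct$top_k)))
        manifest <- write_stage_table(hubs$counts, out_dir, "hubs", manifest)
      } else {
        note("netrank skipped: fewer than 2 pool genes in the graph")
      }
    }
  }
  list(degs = degs, dex = dex, soft_threshold = scan, modules = decomp,
       trait_table = trait_tab, pool = pool, lasso = lasso, hubs = hubs,
       manifest = manifest)
}

#' Run the validation workflow
#'
#' Runs [nested_cv_firth()] (feature selection from the panel pool inside
#' each outer fold) and [boot632_validate()] (fixed panel) on one
#' comparison, returning both results and a manifest; with `out_dir`, a
#' single JSON report is written.
#'
#' @param study an `expression_study`.
#' @param panel gene panel (non-empty after intersection with features).
#' @param group_pos,group_neg the comparison.
#' @param B,P bootstrap / permutation iterations (default 200 each).
#' @param outer_folds,top_m nested-CV parameters (defaults 5, 5).
#' @param seed master seed.
#' @param out_dir optional output directory for the JSON report.
#' @return list with `nested` (`nested_cv_result`), `boot`
#'   (`validation_report`), `manifest`.
#' @export
run_validation <- function(study, panel, group_pos, group_neg,
                           B = 200, P = 200, outer_folds = 5, top_m = 5,
                           seed = 1, out_dir = NULL) {
  stopifnot(inherits(study, "expression_study"))
  present <- intersect(panel, rownames(study$matrix))
  if (!length(present))
    stopf("none of the %d panel genes are present in the study",
          length(panel))
  nested <- nested_cv_firth(study, present, group_pos, group_neg,
                            outer_folds = outer_folds,
                            top_m = min(top_m, length(present)), seed = seed)
  boot <- boot632_validate(study, present, group_pos, group_neg,
                           B = B, P = P, seed = seed)
  manifest <- list(
    config = list(panel = present, group_pos = group_pos,
                  group_neg = group_neg, B = B, P = P,
                  outer_folds = outer_folds, top_m = top_m, seed = seed),
    notes = sprintf(
      "nested AUC %.3f; OOB median %.3f; empirical p %.4f; d %.2f",
      nested$auc, boot$boot$oob_median, boot$empirical_p, boot$cohens_d))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    report <- list(
      nested = list(auc = nested$auc,
                    oof_scores = as.list(nested$oof_scores)),
      boot = list(iterations = boot$boot$iterations,
                  oob_mean = boot$boot$oob_mean,
                  oob_median = boot$boot$oob_median,
                  ci95 = boot$boot$ci95,
                  mean_632plus = boot$boot$mean_632plus,
                  n_accepted = boot$boot$n_accepted),
      perm_aucs = boot$perm_aucs,
      empirical_p = boot$empirical_p,
      cohens_d = boot$cohens_d,
      config = manifest$config)
    path <- file.path(out_dir, "validation_report.json")
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
    manifest$hashes <- list(validation_report = file_hash(path))
  }
  list(nested = nested, boot = boot, manifest = manifest)
}
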