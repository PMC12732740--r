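# Sparse panel selection: L1-penalized logistic regression with stratified
# k-fold cross-validation (lambda_min / lambda_1se rules, via glmnet), plus
# per-gene ROC/AUC diagnostics and the AUC + adjusted-p gate.

#' LASSO logistic panel selection with cross-validation
#'
#' Fits the L1-penalized logistic path over a 100-point log-spaced lambda
#' grid from lambda_max down to `lambda_max * lambda_min_ratio`, with
#' stratified k-fold cross-validation on binomial deviance. Reports both
#' the lambda_min panel (CV minimum) and the sparser lambda_1se panel
#' (largest lambda with CV loss within one standard error of the minimum).
#' Features are standardized internally; coefficients are reported on the
#' original scale. If a class has fewer members than `n_folds`, the fold
#' count is reduced (minimum 3) with a warning. With a single usable
#' feature, an unpenalized logistic fit is used instead and flagged.
#'
#' @param study an `expression_study`.
#' @param group1,group2 group labels; `group1` is coded 1.
#' @param genes optional candidate gene pool (default: all features).
#' @param n_folds CV folds (default 10).
#' @param seed seed for the fold assignment.
#' @param loss `"deviance"` (default) or `"class"`.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @return a `regularization_path`: list with `lambdas`, `cv_mean`,
#'   `cv_se`, `n_nonzero`, `lambda_min`, `lambda_1se`, `panel_min`,
#'   `panel_1se`, `coef_min`, `coef_1se`, `fallback`.
#' @export
lasso_cv <- function(study, group1, group2, genes = NULL, n_folds = 10,
                     seed = 1, loss = c("deviance", "class"),
                     lambda_min_ratio = 1e-4) {
  stopifnot(inherits(study, "expression_study"))
  loss <- match.arg(loss)
  keep <- names(study$groups)[study$groups %in% c(group1, group2)]
  if (!length(keep)) stopf("no samples in the requested groups")
  m <- study$matrix
  if (!is.null(genes)) {
    absent <- setdiff(genes, rownames(m))
    if (length(absent)) stopf("unknown genes: %s",
                              paste(head(absent, 3), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  x <- t(m[, keep, drop = FALSE])
  y <- as.numeric(study$groups[keep] == group1)
  n_min <- min(table(y))
  if (n_min < 3) stopf("smallest class has %d samples; need >= 3", n_min)
  if (n_min < n_folds) {
    n_folds <- max(3, n_min)
    warnf("reducing CV folds to %d (smallest class size)", n_folds)
  }
  if (ncol(x) == 1) {
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    b <- coef(fit)[2]
    warnf("single usable feature: unpenalized logistic fit used")
    return(structure(list(
      lambdas = NA_real_, cv_mean = NA_real_, cv_se = NA_real_,
      n_nonzero = 1L, lambda_min = NA_real_, lambda_1se = NA_real_,
      panel_min = colnames(x), panel_1se = colnames(x),
      coef_min = b, coef_1se = b, fallback = TRUE),
      class = "regularization_path"))
  }
  foldid <- stratified_folds(y, n_folds, seed = child_seed(seed, 6))
  fit0 <- glmnet::glmnet(x, y, family = "binomial", standardize = TRUE)
  lmax <- max(fit0$lambda)
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = 100))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", lambda = grid,
                          foldid = foldid, standardize = TRUE,
                          type.measure = loss)
  panel_at <- function(s) {
    b <- as.matrix(coef(cv, s = s))[-1, 1]
    names(b)[b != 0]
  }
  coefs_at <- function(s) {
    b <- as.matrix(coef(cv, s = s))[, 1]
    b[b != 0 | names(b) == "(Intercept)"]
  }
  structure(list(
    lambdas = cv$lambda, cv_mean = cv$cvm, cv_se = cv$cvsd,
    n_nonzero = cv$nzero,
    lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
    panel_min = panel_at(cv$lambda.min),
    panel_1se = panel_at(cv$lambda.1se),
    coef_min = coefs_at(cv$lambda.min),
    coef_1se = coefs_at(cv$lambda.1se),
    fallback = FALSE), class = "regularization_path")
}

#' @export
print.regularization_path <- function(x, ...) {
  if (isTRUE(x$fallback)) {
    cat("regularization_path (unpenalized fallback, 1 feature)\n")
  } else {
    cat(sprintf(
      "regularization_path: lambda_min = %.4g (%d genes), lambda_1se = %.4g (%d genes)\n",
      x$lambda_min, length(x$panel_min), x$lambda_1se, length(x$panel_1se)))
  }
  invisible(x)
}

#' Per-gene ROC curve and AUC
#'
#' AUC by the Mann-Whitney formulation (0.5 credit for ties), the curve by
#' threshold sweep; higher expression scores toward the positive group.
#'
#' @param study an `expression_study`.
#' @param gene a feature id.
#' @param group_pos,group_neg group labels.
#' @return list with `auc`, `curve` (data.frame fpr, tpr), `flagged`
#'   (TRUE when expression is constant across both groups).
#' @export
per_gene_auc <- function(study, gene, group_pos, group_neg) {
  stopifnot(inherits(study, "expression_study"))
  if (!gene %in% rownames(study$matrix)) stopf("unknown gene: %s", gene)
  pos <- study$matrix[gene, study$groups == group_pos]
  neg <- study$matrix[gene, study$groups == group_neg]
  if (!length(pos) || !length(neg)) stopf("empty group")
  if (sd(c(pos, neg)) == 0)
    return(list(auc = 0.5, curve = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                flagged = TRUE))
  list(auc = auc_mann_whitney(pos, neg), curve = roc_points(pos, neg),
       flagged = FALSE)
}

#' Screen genes by AUC and adjusted Wilcoxon p
#'
#' Computes, for every candidate gene, the Mann-Whitney AUC and the
#' Wilcoxon rank-sum p (BH-adjusted across the candidates), and keeps genes
#' with `auc > auc_cut` and `p_adj < padj_cut` (both strict), sorted by
#' decreasing AUC.
#'
#' @param study an `expression_study`.
#' @param genes candidate gene ids.
#' @param group_pos,group_neg group labels.
#' @param auc_cut AUC gate (default 0.9).
#' @param padj_cut adjusted-p gate (default 0.003).
#' @return list with `genes` (passing, by decreasing AUC) and `table`
#'   (gene, auc, p_raw, p_adj, pass).
#' @export
diagnostic_gate <- function(study, genes, group_pos, group_neg,
                            auc_cut = 0.9, padj_cut = 0.003) {
  stopifnot(inherits(study, "expression_study"))
  absent <- setdiff(genes, rownames(study$matrix))
  if (length(absent)) stopf("unknown genes: %s",
                            paste(head(absent, 3), collapse = ", "))
  idx_pos <- which(study$groups == group_pos)
  idx_neg <- which(study$groups == group_neg)
  auc <- vapply(genes, function(g)
    auc_mann_whitney(study$matrix[g, idx_pos], study$matrix[g, idx_neg]),
    numeric(1))
  p <- vapply(genes, function(g)
    wilcoxon_rank_sum(study$matrix[g, idx_pos],
                      study$matrix[g, idx_neg])$p_two_sided, numeric(1))
  p_adj <- bh_adjust(p)
  tab <- data.frame(gene = genes, auc = auc, p_raw = p, p_adj = p_adj,
                    pass = auc > auc_cut & p_adj < padj_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$auc, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  list(genes = tab$gene[tab$pass], table = tab)
}
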