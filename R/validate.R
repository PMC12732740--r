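# Small-sample predictive validation:
#  (a) nested cross-validation with inner Welch-t feature selection and
#      Firth-penalized logistic regression, pooling out-of-fold scores;
#  (b) a safe stratified 0.632+ bootstrap of a PCA + ridge-logistic
#      classifier with a matched stratified permutation null, empirical p,
#      bootstrap CI and Cohen's d.
#
# "Safe" means every resampling draw is checked for class representation
# before any model sees it; draws that cannot support the inner CV are
# rejected and redrawn.

#' Cohen's d standardized mean difference
#'
#' (mean_a - mean_b) / s_pooled with the pooled (n-2 df) standard
#' deviation. A zero pooled SD yields a signed infinity with a warning.
#'
#' @param sample_a,sample_b numeric vectors (>= 2 values each).
#' @return Cohen's d.
#' @export
cohens_d <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2 || nb < 2) stopf("both samples need >= 2 values")
  sp2 <- ((na - 1) * var(sample_a) + (nb - 1) * var(sample_b)) / (na + nb - 2)
  dm <- mean(sample_a) - mean(sample_b)
  if (sp2 == 0) {
    warnf("zero pooled SD in cohens_d; returning signed infinity")
    return(sign(dm) * Inf)
  }
  dm / sqrt(sp2)
}

#' 0.632+ correction on the error scale
#'
#' err = 1 - AUC, no-information error `gamma`; the out-of-bag error is
#' clipped at gamma, the relative overfitting rate
#' R = (err_oob' - err_app) / (gamma - err_app) is clipped to [0, 1] (0 when
#' the denominator is <= 0), the weight is w = 0.632 / (1 - 0.368 R), and
#' err_632+ = (1 - w) err_app + w err_oob'. Returned on the AUC scale.
#'
#' @param auc_app apparent (training) AUC.
#' @param auc_oob out-of-bag AUC.
#' @param gamma no-information error rate (default 0.5).
#' @return the 0.632+-corrected AUC.
#' @export
auc_632plus <- function(auc_app, auc_oob, gamma = 0.5) {
  err_app <- 1 - auc_app
  err_oob <- min(1 - auc_oob, gamma)
  denom <- gamma - err_app
  r <- if (denom <= 0) 0 else (err_oob - err_app) / denom
  r <- min(max(r, 0), 1)
  w <- 0.632 / (1 - 0.368 * r)
  1 - ((1 - w) * err_app + w * err_oob)
}

# ---------------------------------------------------------------------------
# Ridge logistic regression (IRLS), used on PCA scores inside the bootstrap.

ridge_logistic_fit <- function(X, y, lambda, beta0 = NULL, max_iter = 50,
                               tol = 1e-8) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  for (i in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    pi <- plogis(eta)
    w <- pmax(pi * (1 - pi), 1e-10)
    grad <- drop(crossprod(Xd, y - pi)) - pen %*% beta
    hess <- crossprod(Xd, Xd * w) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

ridge_predict <- function(beta, X) plogis(drop(cbind(1, X) %*% beta))

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# Pick the ridge penalty by stratified k-fold CV on deviance, warm-starting
# along the descending lambda grid.
ridge_cv_lambda <- function(X, y, k, lambda_grid, seed) {
  folds <- stratified_folds(y, k, seed = seed)
  dev <- matrix(NA_real_, k, length(lambda_grid))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) next
    beta <- NULL
    for (j in seq_along(lambda_grid)) {
      beta <- ridge_logistic_fit(X[tr, , drop = FALSE], y[tr],
                                 lambda_grid[j], beta0 = beta)
      dev[f, j] <- binomial_deviance(y[!tr],
                                     ridge_predict(beta, X[!tr, , drop = FALSE]))
    }
  }
  cvm <- colMeans(dev, na.rm = TRUE)
  if (all(!is.finite(cvm))) return(lambda_grid[ceiling(length(lambda_grid) / 2)])
  lambda_grid[which.min(cvm)]
}

# One PCA + ridge pipeline run on given train (multiset) / test indices of
# a samples x genes matrix. Returns apparent and OOB AUC.
pca_ridge_run <- function(X, y, train_idx, test_idx, lambda_grid,
                          max_components = 3, var_explained = 0.95,
                          inner_seed = 1) {
  Xtr <- X[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  Xte <- X[test_idx, , drop = FALSE];  yte <- y[test_idx]
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd); sdv[sdv == 0] <- 1
  Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Zte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  pc <- prcomp(Ztr, center = FALSE, scale. = FALSE)
  varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- min(which(varfrac >= var_explained))
  ncomp <- min(ncomp, max_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  Str <- Ztr %*% rot
  Ste <- Zte %*% rot
  k_inner <- min(3, min(table(ytr)))
  lambda <- ridge_cv_lambda(Str, ytr, k_inner, lambda_grid, seed = inner_seed)
  beta <- ridge_logistic_fit(Str, ytr, lambda)
  p_tr <- ridge_predict(beta, Str)
  p_te <- ridge_predict(beta, Ste)
  list(auc_app = auc_mann_whitney(p_tr[ytr == 1], p_tr[ytr == 0]),
       auc_oob = auc_mann_whitney(p_te[yte == 1], p_te[yte == 0]),
       n_components = ncomp, lambda = lambda)
}

# Stratified 63.2% draw with replacement; returns train multiset and OOB.
draw_632 <- function(y) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_draw <- round(0.632 * length(idx))
    if (n_draw >= 1)
      train <- c(train, sample(idx, n_draw, replace = TRUE))
  }
  list(train = train, oob = setdiff(seq_along(y), unique(train)))
}

# Safety constraints for one draw: both classes in train and OOB, >= 2 per
# class in the training multiset (so the inner stratified CV has >= 2 folds).
draw_is_safe <- function(y, draw) {
  tr_tab <- table(y[draw$train])
  oob_tab <- table(y[draw$oob])
  length(tr_tab) == 2 && length(oob_tab) == 2 && all(tr_tab >= 2)
}

#' Safe stratified 0.632+ bootstrap validation of a fixed gene panel
#'
#' For each of `B` bootstrap iterations a stratified draw selects
#' round(0.632 n_c) samples per class with replacement as the training
#' multiset; samples never drawn form the out-of-bag (OOB) test set. Draws
#' violating the safety constraints (both classes in train and OOB, >= 2
#' per class in train) are redrawn up to 50 times, then recorded
#' unaccepted. Each accepted draw runs a PCA (components explaining >= 95%
#' variance, capped at 3, fitted on training only) + ridge-logistic
#' pipeline with the penalty chosen by inner stratified cross-validation on
#' deviance (3 folds, reduced to 2 when a class has fewer than 3 training
#' members). Apparent and OOB AUCs feed the 0.632+ correction
#' ([auc_632plus()], gamma = 0.5). `P` stratified label permutations each
#' run the identical pipeline for one accepted draw, giving the null AUC
#' distribution; the empirical p is the fraction of permutation AUCs at
#' least the median accepted 0.632+ AUC; the 95% CI comes from OOB AUC
#' quantiles; Cohen's d contrasts the bootstrap and permutation 0.632+
#' distributions.
#'
#' @param study an `expression_study`.
#' @param panel fixed gene panel (intersected with available features;
#'   missing genes are reported in a message).
#' @param group_pos,group_neg group labels (`group_pos` coded 1).
#' @param B bootstrap iterations (>= 50, default 200).
#' @param P permutation iterations (>= 50, default 200).
#' @param seed master seed.
#' @param lambda_grid ridge penalty grid (default 50 log-spaced values).
#' @return a `validation_report`: list with `boot` (per-iteration
#'   data.frame and summaries), `perm_aucs`, `empirical_p`, `cohens_d`,
#'   `config`.
#' @export
boot632_validate <- function(study, panel, group_pos, group_neg,
                             B = 200, P = 200, seed = 1,
                             lambda_grid = 10^seq(2, -4, length.out = 50)) {
  stopifnot(inherits(study, "expression_study"))
  if (B < 50 || P < 50) stopf("B and P must both be >= 50")
  present <- intersect(panel, rownames(study$matrix))
  if (!length(present)) stopf("no panel gene present in the study")
  if (length(present) < length(panel))
    message(sprintf("dropping %d panel gene(s) absent from the study",
                    length(panel) - length(present)))
  keep <- names(study$groups)[study$groups %in% c(group_pos, group_neg)]
  X <- t(study$matrix[present, keep, drop = FALSE])
  y <- as.numeric(study$groups[keep] == group_pos)
  if (min(table(y)) < 4)
    stopf(paste0("cohort too small: a class has %d samples, but the ",
                 "stratified 63.2%% draw needs >= 4 per class to leave ",
                 ">= 2 in training and a non-empty out-of-bag set"),
          min(table(y)))
  set.seed(child_seed(seed, 7))

  run_once <- function(yy, iter_seed) {
    for (attempt in 1:50) {
      draw <- draw_632(yy)
      if (draw_is_safe(yy, draw)) {
        res <- pca_ridge_run(X, yy, draw$train, draw$oob, lambda_grid,
                             inner_seed = iter_seed)
        return(c(accepted = 1, auc_app = res$auc_app, auc_oob = res$auc_oob,
                 auc_632plus = auc_632plus(res$auc_app, res$auc_oob),
                 n_components = res$n_components))
      }
    }
    c(accepted = 0, auc_app = NA, auc_oob = NA, auc_632plus = NA,
      n_components = NA)
  }

  boot <- t(vapply(seq_len(B), function(b) run_once(y, b),
                   numeric(5)))
  boot_df <- as.data.frame(boot)
  acc <- boot_df$accepted == 1
  if (!any(acc)) stopf("no bootstrap iteration satisfied the safety checks")
  oob <- boot_df$auc_oob[acc]
  a632 <- boot_df$auc_632plus[acc]

  perm <- vapply(seq_len(P), function(p) {
    yp <- sample(y)  # label shuffle preserves class counts
    run_once(yp, B + p)[["auc_632plus"]]
  }, numeric(1))
  perm_ok <- perm[!is.na(perm)]
  if (length(perm_ok) < P)
    warnf("%d of %d permutations never produced a safe draw", P - length(perm_ok), P)

  med632 <- stats::median(a632)
  empirical_p <- mean(perm_ok >= med632)
  d <- cohens_d(a632, perm_ok)
  structure(list(
    boot = list(iterations = boot_df,
                oob_mean = mean(oob), oob_median = stats::median(oob),
                ci95 = unname(quantile(oob, c(0.025, 0.975))),
                mean_632plus = mean(a632), median_632plus = med632,
                n_accepted = sum(acc)),
    perm_aucs = perm_ok,
    empirical_p = empirical_p,
    cohens_d = d,
    config = list(panel = present, B = B, P = P, seed = seed,
                  group_pos = group_pos, group_neg = group_neg)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "0.632+ bootstrap validation (%s vs %s, panel of %d genes)\n",
    x$config$group_pos, x$config$group_neg, length(x$config$panel)))
  cat(sprintf("  OOB AUC mean %.3f, median %.3f, 95%% CI [%.3f, %.3f]\n",
              x$boot$oob_mean, x$boot$oob_median,
              x$boot$ci95[1], x$boot$ci95[2]))
  cat(sprintf("  mean 0.632+ AUC %.3f; empirical p = %.4f; Cohen's d = %.2f\n",
              x$boot$mean_632plus, x$empirical_p, x$cohens_d))
  invisible(x)
}

#' Nested cross-validation with Firth logistic regression
#'
#' Stratified `outer_folds`-fold cross-validation: inside each outer fold a
#' Welch two-sample t-test on the training samples only, BH-adjusted,
#' selects the `top_m` genes by adjusted p (ties broken by raw p then gene
#' id; when fewer than `top_m` genes reach adj. p < 0.05 the top `top_m`
#' are still taken and a warning is emitted). A Firth-penalized logistic
#' model fitted on the training samples scores the held-out samples; all
#' out-of-fold probabilities are pooled into one ROC/AUC.
#'
#' @param study an `expression_study`.
#' @param genes candidate gene pool.
#' @param group_pos,group_neg group labels (`group_pos` coded 1).
#' @param outer_folds outer folds (default 5).
#' @param top_m genes selected per fold (default 5).
#' @param seed master seed.
#' @return a `nested_cv_result`: list with `auc`, `roc` (data.frame),
#'   `oof_scores` (named per-sample probabilities), `fold_assignments`,
#'   `selected_genes_per_fold`.
#' @export
nested_cv_firth <- function(study, genes, group_pos, group_neg,
                            outer_folds = 5, top_m = 5, seed = 1) {
  stopifnot(inherits(study, "expression_study"))
  absent <- setdiff(genes, rownames(study$matrix))
  if (length(absent)) stopf("unknown genes: %s",
                            paste(head(absent, 3), collapse = ", "))
  keep <- names(study$groups)[study$groups %in% c(group_pos, group_neg)]
  m <- study$matrix[genes, keep, drop = FALSE]
  y <- as.numeric(study$groups[keep] == group_pos)
  if (min(table(y)) < 2) stopf("each class needs >= 2 samples")
  folds <- NULL
  for (attempt in seq_len(10)) {
    cand <- stratified_folds(y, outer_folds,
                             seed = child_seed(seed, 8 + attempt))
    ok <- all(vapply(seq_len(outer_folds), function(f)
      length(unique(y[cand != f])) == 2, logical(1)))
    if (ok) { folds <- cand; break }
  }
  if (is.null(folds))
    stopf("could not build outer folds with both classes in every training set")
  oof <- rep(NA_real_, length(y))
  sel_per_fold <- vector("list", outer_folds)
  warned <- FALSE
  for (f in seq_len(outer_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (!length(te)) next
    idx_pos <- which(y[tr] == 1); idx_neg <- which(y[tr] == 0)
    tt <- welch_t(m[, tr, drop = FALSE], idx_pos, idx_neg)
    o <- order(tt$p_adj, tt$p_raw, tt$gene)
    sel <- tt$gene[o][seq_len(min(top_m, nrow(tt)))]
    if (sum(tt$p_adj < 0.05) < top_m && !warned) {
      warnf("fewer than %d genes reached adj. p < 0.05 in at least one fold; taking the top %d by adjusted p", top_m, top_m)
      warned <- TRUE
    }
    sel_per_fold[[f]] <- sel
    fit <- firth_fit(t(m[sel, tr, drop = FALSE]), y[tr])
    oof[te] <- predict(fit, t(m[sel, te, drop = FALSE]))
  }
  pos <- oof[y == 1]; neg <- oof[y == 0]
  structure(list(
    auc = auc_mann_whitney(pos, neg),
    roc = roc_points(pos, neg),
    oof_scores = setNames(oof, keep),
    fold_assignments = setNames(folds, keep),
    selected_genes_per_fold = sel_per_fold),
    class = "nested_cv_result")
}
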