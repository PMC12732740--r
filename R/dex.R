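# Two-group differential expression: moderated and ordinary t statistics,
# exact / normal-approximation Wilcoxon rank-sum tests, Benjamini-Hochberg
# FDR, the |log2FC| + p screening gate, and tidy summary tables.

# ---------------------------------------------------------------------------
# Exact Mann-Whitney null distribution.

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for group sizes `n1` and `n2` without ties, the number of
#' labelings realizing each value of U. The count for U = u equals the
#' number of partitions of u into at most `n1` parts, each at most `n2`,
#' computed by the recursion c(m, n, u) = c(m, n-1, u) + c(m-1, n, u-n).
#'
#' @param n1,n2 group sizes.
#' @return numeric vector of counts for U = 0, 1, ..., n1*n2; sums to
#'   choose(n1 + n2, n1).
#' @export
wilcoxon_u_counts <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  L <- n1 * n2 + 1L
  # prev[[m+1]] holds c(m, n-1, .); build up n = 0..n2
  prev <- lapply(0:n1, function(m) {
    v <- rep(0, L); v[1] <- 1; v  # c(m, 0, u) = [u == 0]
  })
  for (n in seq_len(n2)) {
    cur <- vector("list", n1 + 1L)
    v0 <- rep(0, L); v0[1] <- 1
    cur[[1]] <- v0                 # c(0, n, u) = [u == 0]
    for (m in seq_len(n1)) {
      shifted <- c(rep(0, n), head(cur[[m]], L - n))
      cur[[m + 1L]] <- prev[[m + 1L]] + shifted
    }
    prev <- cur
  }
  prev[[n1 + 1L]]
}

#' Wilcoxon rank-sum test for two small samples
#'
#' Uses the exact combinatorial null distribution of U when there are no
#' ties across the two groups and `n1 + n2 <= exact_max`; otherwise a normal
#' approximation with tie-corrected variance and continuity correction. The
#' two-sided exact p is the doubled smaller tail, capped at 1.
#'
#' @param values1,values2 numeric vectors (group 1 and group 2).
#' @param exact_max largest combined sample size for the exact method.
#' @return list with `u_stat` (U of group 1), `n1`, `n2`, `p_two_sided`,
#'   and `method` (`"exact"` or `"normal_tie_corrected"`).
#' @export
wilcoxon_rank_sum <- function(values1, values2, exact_max = 30) {
  n1 <- length(values1); n2 <- length(values2)
  if (n1 == 0L || n2 == 0L) stopf("both groups need at least one value")
  r <- rank(c(values1, values2), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cross_ties <- any(values1 %in% values2)
  if (!cross_ties && (n1 + n2) <= exact_max) {
    counts <- wilcoxon_u_counts(n1, n2)
    total <- sum(counts)
    cdf <- cumsum(counts)
    lower <- cdf[round(u) + 1L] / total          # P(U <= u)
    upper <- (total - c(0, cdf)[round(u) + 1L]) / total  # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(c(values1, values2))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    mu <- n1 * n2 / 2
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (v <= 0) return(list(u_stat = u, n1 = n1, n2 = n2, p_two_sided = 1,
                            method = "normal_tie_corrected"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
    if (u == mu) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_tie_corrected"
  }
  list(u_stat = u, n1 = n1, n2 = n2, p_two_sided = p, method = method)
}

#' Exact two-sided Wilcoxon p-value at a given U
#'
#' Convenience wrapper around the exact null distribution: the two-sided
#' p-value 2 * min(P(U <= u), P(U >= u)) capped at 1, for group sizes
#' `n1`, `n2` and an observed Mann-Whitney U of `u`.
#'
#' @param u observed U (integer in 0..n1*n2).
#' @param n1,n2 group sizes.
#' @return the two-sided exact p-value.
#' @export
wilcoxon_exact_p <- function(u, n1, n2) {
  stopifnot(u >= 0, u <= n1 * n2)
  counts <- wilcoxon_u_counts(n1, n2)
  total <- sum(counts)
  cdf <- cumsum(counts)
  lower <- cdf[u + 1L] / total
  upper <- (total - c(0, cdf)[u + 1L]) / total
  min(1, 2 * min(lower, upper))
}

# ---------------------------------------------------------------------------
# Benjamini-Hochberg.

#' Benjamini-Hochberg step-up adjustment
#'
#' adj_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' input order.
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || any(is.na(p_values)))
    stopf("p-values must be in [0, 1]")
  m <- length(p_values)
  if (m <= 1) return(p_values)
  o <- order(p_values)
  scaled <- p_values[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# ---------------------------------------------------------------------------
# Moderated t (empirical-Bayes variance shrinkage).

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-8) break
    }
    y
  }, numeric(1))
}

# Fit the scaled inverse chi-square prior (d0, s0^2) for gene variances by
# moment matching on log sample variances, the standard empirical-Bayes
# construction for the moderated t.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- mean((e - ebar)^2) * length(e) / (length(e) - 1)
  excess <- evar - trigamma(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s02 <- exp(ebar)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    if (d0 > 1e6) d0 <- Inf
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    if (!is.finite(d0)) s02 <- exp(ebar)
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t differential expression between two groups
#'
#' Per-gene two-sample t statistics with empirical-Bayes variance
#' moderation: the pooled sample variance s2_g (df d_g) is shrunk toward a
#' prior s0^2 with prior df d0, fitted by moment matching on the log sample
#' variances; the moderated statistic is referred to a t distribution on
#' d0 + d_g degrees of freedom. With `d0 = 0` the ordinary pooled t is
#' recovered; if the fit diverges (d0 -> infinity) variances shrink to s0^2
#' and a message is emitted.
#'
#' @param study an `expression_study`.
#' @param group1,group2 group labels; log2FC is mean(group1) - mean(group2).
#' @param d0 optional prior df override (0 = ordinary t, NULL = fitted).
#' @param s02 optional prior variance override.
#' @return data.frame with columns gene, log2fc, t_stat, p_raw, p_adj, test.
#' @export
moderated_t <- function(study, group1, group2, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(study, "expression_study"))
  idx1 <- which(study$groups == group1)
  idx2 <- which(study$groups == group2)
  if (length(idx1) < 2 || length(idx2) < 2)
    stopf("both groups need >= 2 samples (got %d and %d)",
          length(idx1), length(idx2))
  m <- study$matrix
  x1 <- m[, idx1, drop = FALSE]; x2 <- m[, idx2, drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2)
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - mu1)^2); ss2 <- rowSums((x2 - mu2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, dg)
    d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
    if (!is.finite(d0))
      message("variance prior df diverged (d0 -> Inf); ",
              "all variances shrunk to s0^2")
  } else if (is.null(s02)) {
    s02 <- mean(s2)
  }
  if (d0 == 0) {
    s2_tilde <- s2
    df_total <- dg
    test <- "ordinary_t"
  } else if (!is.finite(d0)) {
    s2_tilde <- rep(s02, length(s2))
    df_total <- Inf
    test <- "moderated_t"
  } else {
    s2_tilde <- (d0 * s02 + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
    test <- "moderated_t"
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- (mu1 - mu2) / se
  tstat[se == 0] <- 0
  p <- 2 * pt(-abs(tstat), df = df_total)
  data.frame(gene = rownames(m), log2fc = mu1 - mu2, t_stat = tstat,
             p_raw = p, p_adj = bh_adjust(p), test = test,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch two-sample t-test across all genes
#'
#' Vectorized unequal-variance t; used by the inner feature-selection loop
#' of the nested cross-validation.
#'
#' @param m numeric matrix (genes x samples).
#' @param idx1,idx2 column indices of the two groups.
#' @return data.frame with gene, log2fc, t_stat, p_raw, p_adj.
#' @export
welch_t <- function(m, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2 || n2 < 2) stopf("Welch t needs >= 2 samples per group")
  x1 <- m[, idx1, drop = FALSE]; x2 <- m[, idx2, drop = FALSE]
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  v1 <- rowSums((x1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - mu2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  bad <- !is.finite(tstat)
  tstat[bad] <- 0; df[bad] <- n1 + n2 - 2
  p <- 2 * pt(-abs(tstat), df = df)
  data.frame(gene = rownames(m), log2fc = mu1 - mu2, t_stat = tstat,
             p_raw = p, p_adj = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum differential expression across all genes
#'
#' @param study an `expression_study`.
#' @param group1,group2 group labels.
#' @param exact_max passed to [wilcoxon_rank_sum()].
#' @return data.frame with gene, log2fc, u_stat, p_raw, p_adj, test.
#' @export
wilcoxon_dex <- function(study, group1, group2, exact_max = 30) {
  stopifnot(inherits(study, "expression_study"))
  idx1 <- which(study$groups == group1)
  idx2 <- which(study$groups == group2)
  if (!length(idx1) || !length(idx2)) stopf("empty group")
  m <- study$matrix
  res <- lapply(seq_len(nrow(m)), function(i)
    wilcoxon_rank_sum(m[i, idx1], m[i, idx2], exact_max))
  p <- vapply(res, `[[`, numeric(1), "p_two_sided")
  data.frame(
    gene = rownames(m),
    log2fc = rowMeans(m[, idx1, drop = FALSE]) -
      rowMeans(m[, idx2, drop = FALSE]),
    u_stat = vapply(res, `[[`, numeric(1), "u_stat"),
    p_raw = p, p_adj = bh_adjust(p),
    test = vapply(res, function(r)
      if (r$method == "exact") "wilcoxon_exact" else "wilcoxon_normal",
      character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Screening gate and summary tables.

#' Screen differentially expressed genes
#'
#' Genes with `|log2fc| > lfc_cut` and raw `p < p_cut`, both strict
#' inequalities. The screen uses the raw p-value.
#'
#' @param dex_records data.frame from [moderated_t()] or [wilcoxon_dex()].
#' @param lfc_cut absolute log2 fold-change cut (default 1).
#' @param p_cut raw p-value cut (default 0.05).
#' @return character vector of passing gene ids.
#' @export
screen_degs <- function(dex_records, lfc_cut = 1, p_cut = 0.05) {
  stopifnot(all(c("gene", "log2fc", "p_raw") %in% colnames(dex_records)))
  dex_records$gene[abs(dex_records$log2fc) > lfc_cut &
                     dex_records$p_raw < p_cut]
}

#' Volcano and heatmap summary tables
#'
#' The volcano table carries (gene, log2fc, neg_log10_p); the heatmap table
#' holds the top `top_n` genes by |log2fc| (ties by gene id) with rows
#' z-scored across samples (mean 0, SD 1).
#'
#' @param dex_records output of a differential-expression operation.
#' @param study the `expression_study` the records came from.
#' @param top_n number of genes for the heatmap table (default 30).
#' @return list with `volcano` (data.frame) and `heatmap` (matrix).
#' @export
dex_summary_tables <- function(dex_records, study, top_n = 30) {
  stopifnot(top_n >= 1, inherits(study, "expression_study"))
  volcano <- data.frame(gene = dex_records$gene,
                        log2fc = dex_records$log2fc,
                        neg_log10_p = -log10(dex_records$p_raw))
  o <- order(-abs(dex_records$log2fc), dex_records$gene)
  top <- dex_records$gene[o][seq_len(min(top_n, nrow(dex_records)))]
  sub <- study$matrix[top, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, sd)
  sdv[sdv == 0] <- 1  # constant rows stay at 0 rather than NaN
  hm <- (sub - mu) / sdv
  list(volcano = volcano, heatmap = hm)
}
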