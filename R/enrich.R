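# Preranked gene-set enrichment (weighted Kolmogorov-Smirnov-like running
# sum, permutation-normalized scores) and hypergeometric over-representation.

#' Build a ranked gene list
#'
#' @param genes gene ids.
#' @param metric numeric ranking metric (e.g. signed -log10(p)); the list is
#'   sorted by decreasing metric, ties kept in input order.
#' @return a `ranked_list` (genes + metric, metric non-increasing).
#' @export
ranked_list <- function(genes, metric) {
  if (length(genes) != length(metric)) stopf("genes and metric must align")
  if (anyDuplicated(genes)) stopf("duplicate genes in ranked list")
  o <- order(-metric)  # stable: ties stay in input order
  structure(list(genes = as.character(genes[o]), metric = as.numeric(metric[o])),
            class = "ranked_list")
}

#' Ranking metric from differential-expression records
#'
#' @param dex_records data.frame with gene, log2fc, p_raw (and t_stat).
#' @param rank_by one of `"signed_logp"` (default: -log10(p) * sign(log2fc)),
#'   `"log2fc"`, `"t"`.
#' @return a [ranked_list()].
#' @export
rank_genes <- function(dex_records, rank_by = c("signed_logp", "log2fc", "t")) {
  rank_by <- match.arg(rank_by)
  metric <- switch(rank_by,
    signed_logp = -log10(pmax(dex_records$p_raw, 1e-300)) *
      sign(dex_records$log2fc),
    log2fc = dex_records$log2fc,
    t = dex_records$t_stat)
  ranked_list(dex_records$gene, metric)
}

#' Weighted enrichment score of one gene set
#'
#' The running sum increments by |metric|^weight (normalized to total 1 over
#' the set's hits) at each hit and decrements by 1/(N - n_set) at each miss;
#' ES is the signed maximum deviation from zero. If all hit weights are zero
#' the hit increments fall back to equal mass.
#'
#' @param ranked a [ranked_list()].
#' @param gene_set character vector of member genes.
#' @param weight exponent on |metric| (0, 1, 1.5 or 2; default 1).
#' @return list with `es` and `profile` (running sum, length N).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$genes %in% gene_set
  if (!any(hit)) stopf("gene set does not intersect the ranked list")
  N <- length(ranked$genes)
  n_set <- sum(hit)
  if (n_set == N) stopf("gene set covers the whole ranked list")
  w <- abs(ranked$metric)^weight
  hit_mass <- w * hit
  if (sum(hit_mass) == 0) hit_mass <- as.numeric(hit)
  steps <- hit_mass / sum(hit_mass) - (!hit) / (N - n_set)
  profile <- cumsum(steps)
  es <- profile[which.max(abs(profile))]
  list(es = es, profile = profile)
}

#' Preranked gene-set enrichment with a random-set permutation null
#'
#' For every set passing the size filter, the enrichment score is compared
#' with `n_perm` random gene sets of the same size drawn from the ranked
#' universe. NES = ES / mean(|null ES| of the same sign); the raw p is the
#' fraction of same-sign null scores at least as extreme; the q-value is the
#' GSEA-style ratio of null to observed tail fractions over pooled same-sign
#' NES, capped at 1.
#'
#' @param ranked a [ranked_list()].
#' @param collection a [gene_set_collection()].
#' @param n_perm permutations (>= 100; default 1000).
#' @param min_size,max_size set-size filter after restriction to the ranked
#'   universe.
#' @param weight KS weight exponent.
#' @param seed integer seed.
#' @return data.frame (set_name, size, es, nes, p_raw, fdr_q) sorted by
#'   decreasing NES.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000,
                           min_size = 5, max_size = 500, weight = 1,
                           seed = 1) {
  stopifnot(inherits(ranked, "ranked_list"),
            inherits(collection, "gene_set_collection"))
  if (n_perm < 100) stopf("n_perm must be >= 100")
  sets <- lapply(collection$sets, intersect, ranked$genes)
  sizes <- vapply(sets, length, 1L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    warnf("all gene sets removed by the size filter")
    return(data.frame(set_name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_raw = numeric(0), fdr_q = numeric(0)))
  }
  sets <- sets[keep]; sizes <- sizes[keep]
  set.seed(child_seed(seed, 4))
  N <- length(ranked$genes)
  es_obs <- vapply(sets, function(s)
    enrichment_score(ranked, s, weight)$es, numeric(1))
  # one null matrix per distinct set size
  null_by_size <- lapply(unique(sizes), function(sz) {
    vapply(seq_len(n_perm), function(b)
      enrichment_score(ranked, sample(ranked$genes, sz), weight)$es,
      numeric(1))
  })
  names(null_by_size) <- as.character(unique(sizes))

  nes <- p_raw <- numeric(length(sets))
  nes_null_all <- list()
  for (i in seq_along(sets)) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    same <- if (es_obs[i] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    denom <- mean(abs(same))
    if (!length(same) || denom == 0) { nes[i] <- 0; p_raw[i] <- 1; next }
    nes[i] <- es_obs[i] / denom
    p_raw[i] <- mean(abs(same) >= abs(es_obs[i]))
    pos <- null_es[null_es >= 0]; neg <- null_es[null_es < 0]
    nes_null_all[[i]] <- c(if (length(pos)) pos / mean(pos) else numeric(0),
                           if (length(neg)) neg / mean(abs(neg)) else numeric(0))
  }
  null_nes <- unlist(nes_null_all)
  fdr_q <- vapply(seq_along(sets), function(i) {
    if (nes[i] >= 0) {
      null_frac <- mean(null_nes >= nes[i])
      obs_frac <- mean(nes >= nes[i])
    } else {
      null_frac <- mean(null_nes <= nes[i])
      obs_frac <- mean(nes <= nes[i])
    }
    if (obs_frac == 0) return(1)
    min(1, null_frac / obs_frac)
  }, numeric(1))
  out <- data.frame(set_name = names(sets), size = sizes, es = es_obs,
                    nes = nes, p_raw = p_raw, fdr_q = fdr_q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$nes), , drop = FALSE]
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail probability of observing at least the seen
#' overlap between the query and each set, with BH adjustment across sets.
#'
#' @param query gene-id set (subset of the universe).
#' @param collection a [gene_set_collection()].
#' @param universe gene universe (defaults to the collection's).
#' @return data.frame (set_name, size, overlap, p_raw, p_adj) sorted by p.
#' @export
hypergeom_ora <- function(query, collection, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(query)) stopf("query gene set is empty")
  if (is.null(universe)) universe <- collection$universe
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stopf("query contains genes outside the universe")
  M <- length(universe)
  q <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    k <- length(intersect(s, query))
    # P(X >= k), X ~ Hypergeom(M, |s|, q)
    p <- phyper(k - 1, length(s), M - length(s), q, lower.tail = FALSE)
    data.frame(set_name = nm, size = length(s), overlap = k, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out[order(out$p_raw, out$set_name), , drop = FALSE]
}
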