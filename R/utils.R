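# Shared internal helpers: error formatting, child seeds, stratified folds,
# rank-based AUC. Nothing here is exported.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible child seed from a master seed
#'
#' Stages of the pipeline draw their own random numbers; deriving a distinct
#' child seed per stage from one master seed keeps stages independently
#' re-runnable while the whole run stays reproducible. The derivation is a
#' fixed affine map modulo 2^31 - 1 (a Lehmer-style multiplier), so child
#' seeds stay inside R's 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param index stage index (integer >= 0).
#' @return an integer seed.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + index * 16807 + 12345) %% m)
}

# Stratified fold assignment: samples within each class are shuffled and
# dealt round-robin into k folds, so class proportions are as balanced as
# integer arithmetic allows. Returns an integer vector of fold ids.
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Mann-Whitney AUC of `pos` scores against `neg` scores, ties get half
# credit. Identical to the normalized U statistic.
auc_mann_whitney <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0L || n2 == 0L) stopf("AUC needs scores in both classes")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# ROC curve by threshold sweep (predict positive when score >= threshold),
# returned as a data.frame stepping from (0,0) to (1,1).
roc_points <- function(pos, neg) {
  sc <- c(pos, neg)
  y <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  o <- order(sc, decreasing = TRUE)
  sc <- sc[o]; y <- y[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # one point per distinct threshold
  data.frame(
    fpr = c(0, fp[keep] / sum(y == 0L)),
    tpr = c(0, tp[keep] / sum(y == 1L))
  )
}

# md5 of a written text file; used for run manifests.
file_hash <- function(path) unname(tools::md5sum(path))
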