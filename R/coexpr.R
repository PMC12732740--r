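# Weighted co-expression analysis: soft-threshold scan against the
# scale-free topology criterion, unsigned adjacency, topological overlap,
# average-linkage module detection with a static tree cut, module
# eigengenes, eigengene-based module merging, and module-trait correlation.
#
# The static cut at a fixed dendrogram height deliberately replaces the
# dynamic hybrid tree cut: module recovery here is validated against
# planted latent-factor truth, and the cut height is an exposed parameter.

#' Unsigned co-expression adjacency
#' @param study an `expression_study`.
#' @param power soft-thresholding exponent beta (>= 1).
#' @return symmetric matrix |cor|^beta with zero diagonal.
#' @export
adjacency_matrix <- function(study, power) {
  stopifnot(inherits(study, "expression_study"), power >= 1)
  a <- abs(cor(t(study$matrix)))^power
  a[is.na(a)] <- 0
  diag(a) <- 0
  a
}

#' Signed scale-free topology fit of a connectivity vector
#'
#' Regresses log10 frequency on log10 mean connectivity over `bins`
#' equal-width connectivity bins (empty bins dropped); the returned R^2
#' carries -sign(slope), so a decreasing degree distribution scores
#' positively. Equal-width (not equal-count) bins are required: with
#' equal-count bins the frequency is constant by construction and the
#' regression is vacuous. Returns NA for (near-)constant connectivity.
#'
#' @param k per-node connectivity vector.
#' @param bins number of bins (default 10).
#' @return signed R^2 in [-1, 1], or NA.
#' @export
scale_free_fit <- function(k, bins = 10) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 3 || sd(k) < 1e-12) return(NA_real_)
  cut_k <- cut(k, breaks = bins, include.lowest = TRUE)
  freq <- as.vector(table(cut_k)) / length(k)
  mean_k <- tapply(k, cut_k, mean)
  ok <- !is.na(mean_k) & freq > 0 & mean_k > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  unname(-sign(coef(fit)[2]) * r2)
}

#' Scan soft-thresholding powers against the scale-free criterion
#'
#' For each power beta the unsigned adjacency |cor|^beta is formed, per-gene
#' connectivity k_i = sum_j a_ij computed, and the signed scale-free fit
#' estimated from the log10 frequency vs log10 connectivity regression on
#' up to 10 equal-count bins. The chosen power is the smallest beta whose
#' fit reaches `r2_cut`; when no power qualifies the argmax fit is used and
#' a message notes the fallback.
#'
#' @param study an `expression_study` (>= 3 genes; a warning is issued
#'   below 8 samples).
#' @param powers integer vector of candidate powers.
#' @param r2_cut scale-free fit criterion (default 0.85).
#' @return list with `powers`, `r_squared`, `mean_connectivity`,
#'   `chosen_power`, `reached_criterion`.
#' @export
scan_soft_threshold <- function(study, powers = c(1:10, seq(12, 20, 2)),
                                r2_cut = 0.85) {
  stopifnot(inherits(study, "expression_study"))
  if (nrow(study$matrix) < 3) stopf("soft-threshold scan needs >= 3 genes")
  if (ncol(study$matrix) < 8)
    warnf("fewer than 8 samples: correlation estimates will be noisy")
  cmat <- abs(cor(t(study$matrix)))
  cmat[is.na(cmat)] <- 0
  diag(cmat) <- 0
  if (all(cmat > 1 - 1e-10)) warnf("degenerate input: all genes identical")
  r2 <- meank <- numeric(length(powers))
  for (i in seq_along(powers)) {
    a <- cmat^powers[i]
    k <- rowSums(a)
    meank[i] <- mean(k)
    r2[i] <- scale_free_fit(k)
  }
  reached <- !is.na(r2) & r2 >= r2_cut
  if (any(reached)) {
    chosen <- powers[which(reached)[1]]
    flag <- TRUE
  } else {
    if (all(is.na(r2))) {
      warnf("scale-free fit undefined at every power; defaulting to power 6")
      chosen <- 6
    } else {
      chosen <- powers[which.max(r2)]
      message(sprintf(
        "no power reached R^2 >= %.2f; falling back to argmax fit (beta = %d)",
        r2_cut, chosen))
    }
    flag <- FALSE
  }
  list(powers = powers, r_squared = r2, mean_connectivity = meank,
       chosen_power = chosen, reached_criterion = flag)
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj and unit diagonal.
#'
#' @param adjacency square symmetric matrix, entries in [0, 1], zero
#'   diagonal (asymmetry beyond 1e-10 is an error).
#' @return the TOM matrix.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  if (!is.matrix(a) || nrow(a) != ncol(a)) stopf("adjacency must be square")
  if (max(abs(a - t(a))) > 1e-10) stopf("adjacency is not symmetric")
  if (any(a < -1e-12 | a > 1 + 1e-12)) stopf("adjacency entries outside [0, 1]")
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' cut statically at `cut_height`; clusters smaller than `min_module_size`
#' are assigned to "grey". Module labels are `M1`, `M2`, ... in order of
#' decreasing size (ties broken by the lexicographically first member).
#'
#' @param study an `expression_study`.
#' @param power soft-thresholding power (see [scan_soft_threshold()]).
#' @param min_module_size minimum module size (default 20).
#' @param cut_height static cut height on 1 - TOM (default 0.95).
#' @return a `module_decomposition`: list with `assignment` (named character
#'   vector gene -> module), `eigengenes` (modules x samples),
#'   `merged_from`, `power`, `study_samples`.
#' @export
detect_modules <- function(study, power, min_module_size = 20,
                           cut_height = 0.95) {
  stopifnot(inherits(study, "expression_study"), power >= 1)
  a <- adjacency_matrix(study, power)
  tom <- topological_overlap(a)
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  genes <- rownames(study$matrix)
  assignment <- setNames(rep("grey", length(genes)), genes)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  # deterministic labels: by decreasing size, tie -> first gene id
  if (length(big)) {
    first_gene <- vapply(big, function(b) min(genes[cl == as.integer(b)]),
                         character(1))
    ord <- big[order(-sizes[big], first_gene)]
    for (i in seq_along(ord))
      assignment[cl == as.integer(ord[i])] <- sprintf("M%d", i)
  }
  me <- module_eigengenes(study, assignment)
  structure(
    list(assignment = assignment, eigengenes = me,
         merged_from = setNames(as.list(rownames(me)), rownames(me)),
         power = power, study_samples = colnames(study$matrix)),
    class = "module_decomposition")
}

#' Module eigengenes
#'
#' Per module: the first principal component across samples of the
#' gene-standardized submatrix, scaled to unit variance and sign-aligned so
#' its correlation with the module's mean expression profile is
#' non-negative. A single-gene module yields that gene's standardized
#' profile. The "grey" pool gets no eigengene.
#'
#' @param study an `expression_study`.
#' @param assignment named character vector gene -> module label.
#' @return matrix, modules x samples, each row unit variance.
#' @export
module_eigengenes <- function(study, assignment) {
  stopifnot(inherits(study, "expression_study"))
  mods <- setdiff(sort(unique(assignment)), "grey")
  n <- ncol(study$matrix)
  me <- matrix(NA_real_, length(mods), n,
               dimnames = list(mods, colnames(study$matrix)))
  for (mod in mods) {
    sub <- study$matrix[names(assignment)[assignment == mod], , drop = FALSE]
    mu <- rowMeans(sub); sdv <- apply(sub, 1, sd)
    sdv[sdv == 0] <- 1
    z <- (sub - mu) / sdv
    if (nrow(z) == 1) {
      e <- as.numeric(z)
    } else {
      e <- svd(z, nu = 0, nv = 1)$v[, 1]
    }
    if (sd(e) > 0) e <- e / sd(e)
    mean_prof <- colMeans(z)
    if (sum(e * mean_prof) < 0) e <- -e
    me[mod, ] <- e
  }
  me
}

#' Merge modules with similar eigengenes
#'
#' Rounds of average-linkage clustering on the eigengene dissimilarity
#' 1 - cor(ME_a, ME_b): clusters whose members sit below `dissimilarity_cut`
#' are unioned, eigengenes recomputed, and the process repeated until no
#' pair qualifies. `merged_from` records the full provenance partition of
#' the original module labels.
#'
#' @param study the `expression_study` used to build `decomposition`.
#' @param decomposition a `module_decomposition`.
#' @param dissimilarity_cut eigengene dissimilarity below which modules
#'   merge (default 0.25, i.e. eigengene correlation > 0.75).
#' @return the merged `module_decomposition`.
#' @export
merge_modules <- function(study, decomposition, dissimilarity_cut = 0.25) {
  stopifnot(inherits(decomposition, "module_decomposition"))
  assignment <- decomposition$assignment
  merged_from <- decomposition$merged_from
  if (dissimilarity_cut <= 0) return(decomposition)
  repeat {
    me <- module_eigengenes(study, assignment)
    if (nrow(me) < 2) break
    d <- 1 - cor(t(me))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, h = dissimilarity_cut)
    if (max(cl) == nrow(me)) break  # nothing below the cut
    new_assignment <- assignment
    new_from <- list()
    for (grp in unique(cl)) {
      members <- rownames(me)[cl == grp]
      # keep the label of the largest member (tie -> first gene id)
      sz <- vapply(members, function(mm) sum(assignment == mm), 1L)
      lead <- members[order(-sz, members)][1]
      for (mm in members) new_assignment[assignment == mm] <- lead
      new_from[[lead]] <- sort(unique(unlist(merged_from[members])))
    }
    assignment <- new_assignment
    merged_from <- new_from
  }
  me <- module_eigengenes(study, assignment)
  # relabel deterministically by decreasing size
  mods <- rownames(me)
  if (length(mods)) {
    sz <- vapply(mods, function(mm) sum(assignment == mm), 1L)
    first_gene <- vapply(mods, function(mm)
      min(names(assignment)[assignment == mm]), character(1))
    ord <- mods[order(-sz, first_gene)]
    relabel <- setNames(sprintf("M%d", seq_along(ord)), ord)
    out_assign <- assignment
    for (mm in ord) out_assign[assignment == mm] <- relabel[mm]
    names(merged_from) <- relabel[names(merged_from)]
    assignment <- out_assign
    me <- module_eigengenes(study, assignment)
  }
  structure(
    list(assignment = assignment, eigengenes = me, merged_from = merged_from,
         power = decomposition$power,
         study_samples = decomposition$study_samples),
    class = "module_decomposition")
}

#' Correlate module eigengenes with binary clinical traits
#'
#' Each trait is a pair of group labels encoded 0/1 over the samples that
#' belong to either group; Pearson correlation with each eigengene and the
#' two-sided t-distribution p on n - 2 df are reported.
#'
#' @param decomposition a `module_decomposition`.
#' @param groups named character vector sample -> group.
#' @param traits named list; each element `c(positive_group, negative_group)`.
#' @param p_cut significance flag threshold (default 0.05).
#' @return data.frame (module, trait, r, p, significant).
#' @export
module_trait_correlation <- function(decomposition, groups, traits,
                                     p_cut = 0.05) {
  stopifnot(inherits(decomposition, "module_decomposition"))
  me <- decomposition$eigengenes
  rows <- list()
  for (tn in names(traits)) {
    pair <- traits[[tn]]
    keep <- names(groups)[groups %in% pair]
    keep <- intersect(colnames(me), keep)
    if (length(keep) < 3) stopf("trait '%s' spans fewer than 3 samples", tn)
    y <- as.numeric(groups[keep] == pair[1])
    for (mod in rownames(me)) {
      e <- me[mod, keep]
      if (sd(e) == 0 || sd(y) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          module = mod, trait = tn, r = NA_real_, p = NA_real_,
          significant = FALSE)
        next
      }
      r <- cor(e, y)
      n <- length(keep)
      tval <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
      p <- 2 * pt(-abs(tval), df = n - 2)
      rows[[length(rows) + 1]] <- data.frame(
        module = mod, trait = tn, r = r, p = p, significant = p < p_cut)
    }
  }
  do.call(rbind, rows)
}
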