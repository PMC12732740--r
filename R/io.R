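# Expression containers and plain-text I/O.
#
# The central container is the `expression_study`: a log2 expression matrix
# (features x samples), a sample -> group map, and an optional feature ->
# gene-symbol map for probe-level data. Everything downstream consumes it.
# Orientation is fixed as features x samples throughout the package; the only
# transposition happens inside the validation classifiers.

#' Construct an expression study
#'
#' @param matrix numeric matrix, features x samples, log2 scale, with unique
#'   rownames (feature ids) and colnames (sample ids).
#' @param groups named character vector or factor mapping sample id -> group
#'   label; must cover every column of `matrix`.
#' @param feature_to_gene optional named character vector mapping feature id
#'   -> gene symbol (for probe-level matrices).
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(matrix, groups, feature_to_gene = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stopf("expression matrix must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stopf("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stopf("duplicate feature ids: %s",
          paste(unique(rownames(matrix)[duplicated(rownames(matrix))])[1:3],
                collapse = ", "))
  if (anyDuplicated(colnames(matrix)))
    stopf("duplicate sample ids")
  if (any(!is.finite(matrix)))
    stopf("expression matrix contains non-finite values")
  groups <- setNames(as.character(groups), names(groups))
  missing <- setdiff(colnames(matrix), names(groups))
  if (length(missing))
    stopf("samples missing from phenotype: %s", paste(missing, collapse = ", "))
  groups <- groups[colnames(matrix)]
  if (!is.null(feature_to_gene)) {
    absent <- setdiff(rownames(matrix), names(feature_to_gene))
    if (length(absent))
      stopf("feature_to_gene mapping missing for: %s",
            paste(head(absent, 3), collapse = ", "))
    feature_to_gene <- feature_to_gene[rownames(matrix)]
  }
  structure(
    list(matrix = matrix, groups = groups, feature_to_gene = feature_to_gene),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d features x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$feature_to_gene))
    cat(sprintf("probe->gene map: %d genes\n",
                length(unique(x$feature_to_gene))))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$matrix)

# Subset an expression study by feature ids and/or sample ids.
#' Subset an expression study
#' @param study an `expression_study`.
#' @param features character vector of feature ids to keep (NULL = all).
#' @param samples character vector of sample ids to keep (NULL = all).
#' @return the subsetted `expression_study`.
#' @export
subset_study <- function(study, features = NULL, samples = NULL) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$matrix
  if (!is.null(features)) {
    absent <- setdiff(features, rownames(m))
    if (length(absent))
      stopf("unknown features: %s", paste(head(absent, 3), collapse = ", "))
    m <- m[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    absent <- setdiff(samples, colnames(m))
    if (length(absent))
      stopf("unknown samples: %s", paste(head(absent, 3), collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  f2g <- study$feature_to_gene
  if (!is.null(f2g)) f2g <- f2g[rownames(m)]
  expression_study(m, study$groups[colnames(m)], f2g)
}

# ---------------------------------------------------------------------------
# Plain-text readers/writers. All readers accept '#'-comment lines and CRLF.

read_table_clean <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read an expression study from TSV files
#'
#' Expression file: first column feature id, remaining columns one per
#' sample, header row of sample ids. Phenotype file: columns `sample_id`,
#' `group`. Samples are ordered as in the phenotype file; samples present in
#' the matrix but absent from the phenotype are an error.
#'
#' @param path expression TSV.
#' @param phenotype_path phenotype TSV.
#' @param gene_map_path optional two-column TSV (feature_id, gene) with
#'   probe -> gene mapping.
#' @return an `expression_study`.
#' @export
read_expression <- function(path, phenotype_path, gene_map_path = NULL) {
  tab <- read_table_clean(path)
  if (ncol(tab) < 2) stopf("expression file %s has no sample columns", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stopf("duplicate feature ids in %s (e.g. %s)", path,
          ids[duplicated(ids)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(tab[, -1, drop = FALSE], 2, is.numeric))[1]
    stopf("non-numeric cells in %s, column '%s'", path, colnames(tab)[bad + 1])
  }
  rownames(m) <- ids
  ph <- read_table_clean(phenotype_path)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(ph)))
    stopf("phenotype file must have columns: %s", paste(need, collapse = ", "))
  groups <- setNames(as.character(ph$group), as.character(ph$sample_id))
  extra <- setdiff(colnames(m), names(groups))
  if (length(extra))
    stopf("sample(s) in expression but not phenotype: %s",
          paste(extra, collapse = ", "))
  keep <- intersect(names(groups), colnames(m))
  m <- m[, keep, drop = FALSE]
  f2g <- NULL
  if (!is.null(gene_map_path)) {
    gm <- read_table_clean(gene_map_path)
    f2g <- setNames(as.character(gm[[2]]), as.character(gm[[1]]))
  }
  expression_study(m, groups, f2g)
}

#' Write an expression study to TSV files
#' @param study an `expression_study`.
#' @param path expression TSV destination.
#' @param phenotype_path phenotype TSV destination.
#' @param gene_map_path optional destination for the probe -> gene map.
#' @return invisibly, the paths written.
#' @export
write_expression <- function(study, path, phenotype_path,
                             gene_map_path = NULL) {
  df <- data.frame(feature_id = rownames(study$matrix),
                   study$matrix, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(sample_id = names(study$groups), group = study$groups)
  write.table(ph, phenotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(path, phenotype_path)
  if (!is.null(gene_map_path) && !is.null(study$feature_to_gene)) {
    gm <- data.frame(feature_id = names(study$feature_to_gene),
                     gene = study$feature_to_gene)
    write.table(gm, gene_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, gene_map_path)
  }
  invisible(paths)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT dialect: set name, description, then member
#' gene ids. Returns a list with `sets` (named list of character vectors)
#' and `universe` (union of members unless supplied).
#'
#' @param path GMT file.
#' @param universe optional gene universe to restrict against.
#' @return a `gene_set_collection` (list with `sets`, `universe`).
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stopf("malformed GMT line: %s", substr(ln, 1, 40))
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  gene_set_collection(sets, universe)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (set name -> members).
#' @param universe optional gene universe; defaults to the union of members.
#'   Sets are restricted to the universe; emptied sets are dropped with a
#'   warning.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!length(sets) || is.null(names(sets)))
    stopf("sets must be a non-empty named list")
  if (is.null(universe)) universe <- unique(unlist(sets))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) {
    warnf("dropping %d empty gene set(s) after universe restriction",
          sum(empty))
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path destination file.
#' @return invisibly, the path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction graph from an edge-list TSV
#'
#' Two columns (gene_a, gene_b); self-loops and duplicate edges are removed.
#'
#' @param path edge-list TSV.
#' @return an `igraph` undirected simple graph.
#' @export
read_edge_list <- function(path) {
  tab <- read_table_clean(path)
  if (ncol(tab) < 2) stopf("edge list needs two columns")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(tab[[1]]), to = as.character(tab[[2]])),
    directed = FALSE)
  igraph::simplify(g)
}

#' Write an undirected graph as an edge-list TSV
#' @param graph an `igraph` graph.
#' @param path destination file.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Preprocessing.

#' Quantile-normalize an expression study
#'
#' After normalization every sample's sorted values equal the across-sample
#' mean of sorted values (the reference distribution). Tied values within a
#' sample receive the mean of the reference quantiles they span, so the
#' operation is well defined and idempotent in the presence of ties.
#'
#' @param study an `expression_study` with at least two samples.
#' @return the normalized `expression_study`.
#' @export
quantile_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$matrix
  if (ncol(m) < 2) stopf("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  n <- nrow(m)
  for (j in seq_len(ncol(m))) {
    xj <- m[, j]
    pos <- integer(n)
    pos[order(xj)] <- seq_len(n)
    # tie groups share the mean of the reference quantiles they occupy
    out[, j] <- ave(ref[pos], match(xj, xj), FUN = mean)
  }
  expression_study(out, study$groups, study$feature_to_gene)
}

#' Collapse probe-level features to genes
#'
#' `max_mean` keeps, per gene, the probe with the highest mean expression
#' (ties broken by feature id); `mean` averages all probes of a gene
#' elementwise.
#'
#' @param study an `expression_study` with a `feature_to_gene` map.
#' @param method `"max_mean"` (default) or `"mean"`.
#' @return an `expression_study` with one row per gene.
#' @export
collapse_to_genes <- function(study, method = c("max_mean", "mean")) {
  stopifnot(inherits(study, "expression_study"))
  method <- match.arg(method)
  f2g <- study$feature_to_gene
  if (is.null(f2g)) stopf("collapse_to_genes requires a feature_to_gene map")
  m <- study$matrix
  genes <- unique(unname(f2g))
  if (method == "max_mean") {
    means <- rowMeans(m)
    keep <- vapply(genes, function(g) {
      probes <- names(f2g)[f2g == g]
      probes <- probes[order(-means[probes], probes)]
      probes[1]
    }, character(1))
    out <- m[keep, , drop = FALSE]
  } else {
    out <- t(vapply(genes, function(g) {
      probes <- names(f2g)[f2g == g]
      colMeans(m[probes, , drop = FALSE])
    }, numeric(ncol(m))))
    colnames(out) <- colnames(m)
  }
  rownames(out) <- genes
  expression_study(out, study$groups, NULL)
}

#' Keep the most variable features
#'
#' Retains `ceiling(keep_fraction * n_features)` features with the largest
#' sample variance (n-1 denominator); ties broken by feature id. Original
#' row order of the retained features is preserved.
#'
#' @param study an `expression_study`.
#' @param keep_fraction fraction of features to keep, in (0, 1].
#' @return the filtered `expression_study`.
#' @export
variance_filter <- function(study, keep_fraction = 0.75) {
  stopifnot(inherits(study, "expression_study"))
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stopf("keep_fraction must be in (0, 1]")
  m <- study$matrix
  n_keep <- ceiling(keep_fraction * nrow(m))
  v <- apply(m, 1, var)
  sel <- rownames(m)[order(-v, rownames(m))][seq_len(n_keep)]
  subset_study(study, features = rownames(m)[rownames(m) %in% sel])
}
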