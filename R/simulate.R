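# Synthetic-data generation.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: three patient groups of sizes 5 / 10 / 11 (healthy controls,
# disease controls, cases), ~20,000 log2-intensity features, a handful of
# planted differentially expressed genes with a fixed log2 mean shift in the
# case group, latent-factor co-expression modules, gaussian residual noise,
# and optional probe multiplicity so probe -> gene collapsing is exercised.
# Everything is driven by one master seed; each component derives its own
# child seed (see child_seed) so stages are independently reproducible.

#' Simulation configuration
#'
#' Defaults describe the emulated cohort: three groups sized 5 (Healthy),
#' 10 (MM) and 11 (MM_ONJ, the case group, always the *last* label),
#' 20,000 genes on the log2-intensity scale, 100 planted DE genes shifted
#' by 2 log2 units in the case group, five latent-factor modules of 100
#' genes with loading 0.8, residual SD 0.5 and one probe per gene.
#'
#' @param n_genes number of genes.
#' @param group_sizes named integer vector, group label -> size; the last
#'   label is the case group receiving the DE shift.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param effect_size_log2 planted group-mean shift (log2 units).
#' @param n_modules number of latent-factor co-expression modules.
#' @param module_size genes per module.
#' @param module_loading latent-factor loading in [0, 1].
#' @param noise_sd gaussian residual SD (log2 units), > 0.
#' @param probes_per_gene probes replicating each gene (>= 1).
#' @param module_de_shift optional shift of module 1's latent factor in the
#'   case group (0 = no trait-linked module).
#' @param seed master seed.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 20000,
                       group_sizes = c(Healthy = 5, MM = 10, MM_ONJ = 11),
                       n_de_genes = 100,
                       effect_size_log2 = 2,
                       n_modules = 5,
                       module_size = 100,
                       module_loading = 0.8,
                       noise_sd = 0.5,
                       probes_per_gene = 1,
                       module_de_shift = 0,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, group_sizes = group_sizes,
              n_de_genes = n_de_genes, effect_size_log2 = effect_size_log2,
              n_modules = n_modules, module_size = module_size,
              module_loading = module_loading, noise_sd = noise_sd,
              probes_per_gene = probes_per_gene,
              module_de_shift = module_de_shift, seed = seed)
  chk <- function(cond, field, msg)
    if (!cond) stopf("invalid sim_config field '%s': %s", field, msg)
  chk(n_genes >= 1, "n_genes", "must be positive")
  chk(length(group_sizes) >= 2 && all(group_sizes >= 1) &&
        !is.null(names(group_sizes)), "group_sizes",
      "needs >= 2 named positive sizes")
  chk(n_de_genes >= 0 && n_de_genes <= n_genes, "n_de_genes",
      "must be in [0, n_genes]")
  chk(n_modules >= 0 && module_size >= 1 &&
        n_modules * module_size <= n_genes, "n_modules",
      "n_modules * module_size must be <= n_genes")
  chk(module_loading >= 0 && module_loading <= 1, "module_loading",
      "must be in [0, 1]")
  chk(noise_sd > 0, "noise_sd", "must be > 0")
  chk(probes_per_gene >= 1, "probes_per_gene", "must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate an expression study with planted structure
#'
#' Gene profiles are built as baseline + module signal + DE shift + noise,
#' all on the log2 scale:
#' * baseline intensity per gene ~ N(7, 1.5^2), constant across samples;
#' * module genes: `loading * latent_factor + sqrt(1 - loading^2) * eps`,
#'   scaled by `noise_sd`, with one standard-normal latent factor per module
#'   per sample;
#' * non-module genes: `noise_sd`-scaled i.i.d. gaussian noise;
#' * the `n_de_genes` planted DE genes (drawn from non-module genes when
#'   possible) are shifted by `effect_size_log2` in the case group (the last
#'   group label);
#' * each gene is replicated into `probes_per_gene` probes, each adding its
#'   own independent `noise_sd` gaussian noise on top of the gene profile.
#'
#' @param config a [sim_config()].
#' @return a `simulated_study`: list with `study` (an
#'   [expression_study()]), `truth_de_genes`, `truth_modules` (named list),
#'   `truth_panel` (the planted discriminative genes, ordered), `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1))
  ng <- config$n_genes
  sizes <- config$group_sizes
  n <- sum(sizes)
  gene_ids <- sprintf("G%05d", seq_len(ng))
  group_vec <- rep(names(sizes), times = sizes)
  sample_ids <- sprintf("S%02d_%s", seq_len(n), group_vec)
  case_group <- names(sizes)[length(sizes)]

  baseline <- rnorm(ng, mean = 7, sd = 1.5)
  expr <- matrix(rnorm(ng * n, sd = config$noise_sd), ng, n)

  # latent-factor modules occupy the first n_modules*module_size genes
  truth_modules <- list()
  mod_genes <- integer(0)
  if (config$n_modules > 0) {
    lam <- config$module_loading
    for (k in seq_len(config$n_modules)) {
      rows <- ((k - 1) * config$module_size + 1):(k * config$module_size)
      factor_k <- rnorm(n)
      if (k == 1 && config$module_de_shift != 0)
        factor_k[group_vec == case_group] <-
          factor_k[group_vec == case_group] + config$module_de_shift
      eps <- matrix(rnorm(length(rows) * n), length(rows), n)
      expr[rows, ] <- config$noise_sd *
        (lam * matrix(factor_k, length(rows), n, byrow = TRUE) +
           sqrt(1 - lam^2) * eps)
      truth_modules[[sprintf("mod%02d", k)]] <- gene_ids[rows]
      mod_genes <- c(mod_genes, rows)
    }
  }

  # planted DE genes: prefer genes outside modules so truths stay disjoint
  de_rows <- integer(0)
  if (config$n_de_genes > 0) {
    free <- setdiff(seq_len(ng), mod_genes)
    if (length(free) >= config$n_de_genes) {
      de_rows <- sort(sample(free, config$n_de_genes))
    } else {
      de_rows <- sort(c(free, sample(mod_genes,
                                     config$n_de_genes - length(free))))
    }
    expr[de_rows, group_vec == case_group] <-
      expr[de_rows, group_vec == case_group] + config$effect_size_log2
  }

  expr <- expr + baseline
  rownames(expr) <- gene_ids
  colnames(expr) <- sample_ids
  groups <- setNames(group_vec, sample_ids)

  f2g <- NULL
  if (config$probes_per_gene > 1) {
    pp <- config$probes_per_gene
    probe_ids <- as.vector(t(outer(gene_ids, seq_len(pp),
                                   function(g, j) sprintf("%s_p%d", g, j))))
    expr <- expr[rep(seq_len(ng), each = pp), , drop = FALSE] +
      matrix(rnorm(ng * pp * n, sd = config$noise_sd), ng * pp, n)
    rownames(expr) <- probe_ids
    f2g <- setNames(rep(gene_ids, each = pp), probe_ids)
  }

  de_genes <- gene_ids[de_rows]
  structure(
    list(study = expression_study(expr, groups, f2g),
         truth_de_genes = de_genes,
         truth_modules = truth_modules,
         truth_panel = de_genes,
         config = config),
    class = "simulated_study")
}

#' Simulate an interaction graph with planted hubs
#'
#' Builds a connected preferential-attachment graph over the given genes,
#' with the first `planted_hubs` genes receiving strongly boosted
#' attachment weight and then extra edges until each hub's degree is at
#' least three times the median degree of the non-hub nodes.
#'
#' @param genes character vector of node ids.
#' @param planted_hubs number of hub nodes (taken from the head of `genes`).
#' @param seed integer seed.
#' @param m edges added per incoming node (default 2).
#' @return an `igraph` undirected simple graph with a `hubs` graph
#'   attribute naming the planted hubs.
#' @export
simulate_graph <- function(genes, planted_hubs = 1, seed = 1, m = 2) {
  if (!length(genes)) stopf("gene list must be non-empty")
  if (planted_hubs > length(genes))
    stopf("planted_hubs exceeds number of genes")
  set.seed(child_seed(seed, 2))
  ng <- length(genes)
  hubs <- genes[seq_len(planted_hubs)]
  # grow a preferential-attachment graph; hubs carry 20x attachment weight
  edges <- character(0)
  deg <- setNames(rep(0, ng), genes)
  wt_boost <- ifelse(genes %in% hubs, 20, 1)
  order_in <- sample(ng)  # random arrival order
  first <- genes[order_in[1]]
  present <- first
  for (i in order_in[-1]) {
    v <- genes[i]
    w <- (deg[present] + 1) * wt_boost[match(present, genes)]
    k <- min(m, length(present))
    targets <- sample(present, k, prob = w)
    edges <- c(edges, rbind(v, targets))
    deg[v] <- deg[v] + k
    deg[targets] <- deg[targets] + 1
    present <- c(present, v)
  }
  g <- igraph::simplify(igraph::graph_from_edgelist(
    matrix(edges, ncol = 2, byrow = TRUE), directed = FALSE))
  # top up hub degree to >= 3x median non-hub degree and above every
  # non-hub, so planted hubs genuinely dominate degree rankings; the target
  # is capped at n-1 (a hub cannot exceed full connectivity) and the loop
  # stops when no further edge can be added
  repeat {
    degs <- igraph::degree(g)
    nonhub <- degs[setdiff(names(degs), hubs)]
    target <- min(max(3 * stats::median(nonhub), max(nonhub) + 1, 3),
                  ng - 1)
    lacking <- hubs[degs[hubs] < target]
    if (!length(lacking)) break
    progress <- FALSE
    for (h in lacking) {
      nb <- igraph::neighbors(g, h)$name
      pool <- setdiff(genes, c(h, nb))
      need <- ceiling(target - degs[h])
      if (!length(pool)) next
      add <- sample(pool, min(need, length(pool)))
      g <- igraph::add_edges(g, as.vector(rbind(h, add)))
      progress <- TRUE
    }
    g <- igraph::simplify(g)
    if (!progress) break
  }
  g <- igraph::simplify(g)
  g$hubs <- hubs
  g
}

#' Simulate gene-set collections with planted enrichment
#'
#' `n_enriched` sets are drawn preferentially from the top of the ranking
#' metric (the top `2 * set_size` genes by metric), the remaining sets
#' uniformly from the whole universe.
#'
#' @param genes gene universe (character).
#' @param n_sets number of sets.
#' @param set_size genes per set.
#' @param n_enriched how many sets are planted at the top of the ranking.
#' @param ranked_metric numeric metric per gene (same length as `genes`).
#' @param seed integer seed.
#' @return a `gene_set_collection`; planted set names start `enriched_`.
#' @export
simulate_gene_sets <- function(genes, n_sets, set_size, n_enriched,
                               ranked_metric, seed = 1) {
  if (set_size > length(genes)) stopf("set_size exceeds universe size")
  if (n_enriched > n_sets) stopf("n_enriched exceeds n_sets")
  if (length(ranked_metric) != length(genes))
    stopf("ranked_metric must align with genes")
  set.seed(child_seed(seed, 3))
  top_pool <- genes[order(-ranked_metric)][seq_len(min(2 * set_size,
                                                       length(genes)))]
  sets <- list()
  for (k in seq_len(n_sets)) {
    if (k <= n_enriched) {
      sets[[sprintf("enriched_%02d", k)]] <- sample(top_pool, set_size)
    } else {
      sets[[sprintf("random_%02d", k)]] <- sample(genes, set_size)
    }
  }
  gene_set_collection(sets, universe = genes)
}

#' Write a simulated study to fixture files
#'
#' Writes the expression TSV, phenotype TSV and (if probes are simulated)
#' the probe -> gene map into `dir`.
#'
#' @param sim a `simulated_study`.
#' @param dir destination directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_simulated_study <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr <- file.path(dir, "expression.tsv")
  pheno <- file.path(dir, "phenotype.tsv")
  gmap <- if (!is.null(sim$study$feature_to_gene))
    file.path(dir, "probe_map.tsv") else NULL
  write_expression(sim$study, expr, pheno, gmap)
  invisible(c(expression = expr, phenotype = pheno,
              probe_map = if (is.null(gmap)) NA_character_ else gmap))
}
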