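# Hub-gene ranking: the eleven named node centralities and the
# >= m-method top-k consensus intersection.
#
# Conventions for disconnected graphs: Closeness is harmonic (unreachable
# nodes contribute 0), EcCentricity and Radiality are computed within a
# node's connected component, and path-based scores only see paths inside
# components. MNC/DMNC of a node without neighbors are 0; MCC of an
# isolated node is 0 while each maximal 2-clique (a plain edge) contributes
# 1! to its endpoints.

CENTRALITY_METHODS <- c("Degree", "MNC", "DMNC", "MCC", "EPC", "BottleNeck",
                        "EcCentricity", "Closeness", "Radiality",
                        "Betweenness", "Stress")

# Single-source BFS returning distances, path counts and predecessor lists
# (Brandes bookkeeping) on an adjacency list representation.
bfs_brandes <- function(adj, s, n) {
  dist <- rep(-1L, n); sigma <- rep(0, n)
  preds <- vector("list", n)
  dist[s] <- 0L; sigma[s] <- 1
  queue <- integer(n); qh <- 1L; qt <- 1L
  queue[qt] <- s; qt <- qt + 1L
  order_visited <- integer(0)
  while (qh < qt) {
    v <- queue[qh]; qh <- qh + 1L
    order_visited <- c(order_visited, v)
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        queue[qt] <- w; qt <- qt + 1L
      }
      if (dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_visited)
}

# Betweenness and Stress by Brandes accumulation (undirected: halved).
betweenness_stress <- function(adj, n) {
  bc <- rep(0, n); st <- rep(0, n)
  for (s in seq_len(n)) {
    b <- bfs_brandes(adj, s, n)
    delta_b <- rep(0, n); delta_s <- rep(0, n)
    for (w in rev(b$order)) {
      for (v in b$preds[[w]]) {
        frac <- b$sigma[v] / b$sigma[w]
        delta_b[v] <- delta_b[v] + frac * (1 + delta_b[w])
        delta_s[v] <- delta_s[v] + frac * (b$sigma[w] + delta_s[w])
      }
      if (w != s) {
        bc[w] <- bc[w] + delta_b[w]
        st[w] <- st[w] + delta_s[w]
      }
    }
  }
  list(betweenness = bc / 2, stress = st / 2)
}

# BottleNeck: for each source, a deterministic BFS shortest-path tree
# (parent = first-discovered predecessor); a non-root tree node scores 1
# when its subtree (including itself) holds more than n_tree/4 nodes.
bottleneck_scores <- function(adj, n) {
  bn <- rep(0, n)
  for (s in seq_len(n)) {
    b <- bfs_brandes(adj, s, n)
    parent <- rep(NA_integer_, n)
    for (w in b$order) if (w != s) parent[w] <- b$preds[[w]][1]
    in_tree <- b$order
    sub <- rep(1L, n)
    for (w in rev(in_tree)) {
      p <- parent[w]
      if (!is.na(p)) sub[p] <- sub[p] + sub[w]
    }
    thresh <- length(in_tree) / 4
    for (w in in_tree)
      if (w != s && sub[w] > thresh) bn[w] <- bn[w] + 1
  }
  bn
}

#' Compute node centralities
#'
#' Scores the requested subset of the eleven centralities: Degree, MNC
#' (largest connected component of the open neighborhood), DMNC
#' (|E(C)| / |V(C)|^1.7 of that component), MCC (sum over maximal cliques
#' containing the node of (|C| - 1)!), EPC (mean size of the node's
#' component over `epc_R` random edge-percolated copies at keep probability
#' `epc_p`), BottleNeck, EcCentricity (1 / eccentricity), harmonic
#' Closeness, Radiality, Betweenness and Stress.
#'
#' @param graph an `igraph` undirected graph.
#' @param methods character vector of method names, or `"all"`.
#' @param k top-list length per method (default 10).
#' @param epc_R percolation replicates for EPC (default 1000).
#' @param epc_p edge keep probability for EPC (default 0.5).
#' @param seed seed for the EPC percolation draws.
#' @return a `centrality_table`: list with `scores` (nodes x methods
#'   matrix), `top_k` (named list of ordered node vectors), `k`.
#' @export
compute_centralities <- function(graph, methods = "all", k = 10,
                                 epc_R = 1000, epc_p = 0.5, seed = 1) {
  stopifnot(k >= 1)
  if (identical(methods, "all")) methods <- CENTRALITY_METHODS
  bad <- setdiff(methods, CENTRALITY_METHODS)
  if (length(bad))
    stopf("unknown centrality method(s): %s; valid: %s",
          paste(bad, collapse = ", "),
          paste(CENTRALITY_METHODS, collapse = ", "))
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(igraph::vcount(graph)))
    igraph::V(graph)$name <- nodes
  }
  n <- length(nodes)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  scores <- matrix(0, n, length(methods), dimnames = list(nodes, methods))

  need_paths <- any(c("Betweenness", "Stress") %in% methods)
  if (need_paths) bs <- betweenness_stress(adj, n)
  need_dist <- any(c("EcCentricity", "Closeness", "Radiality") %in% methods)
  if (need_dist) D <- igraph::distances(graph)

  for (m in methods) {
    scores[, m] <- switch(m,
      Degree = igraph::degree(graph),
      MNC = vapply(seq_len(n), function(v) {
        nb <- adj[[v]]
        if (!length(nb)) return(0)
        sub <- igraph::induced_subgraph(graph, nb)
        max(igraph::components(sub)$csize)
      }, numeric(1)),
      DMNC = vapply(seq_len(n), function(v) {
        nb <- adj[[v]]
        if (!length(nb)) return(0)
        sub <- igraph::induced_subgraph(graph, nb)
        comp <- igraph::components(sub)
        biggest <- which.max(comp$csize)
        cg <- igraph::induced_subgraph(sub, which(comp$membership == biggest))
        igraph::ecount(cg) / igraph::vcount(cg)^1.7
      }, numeric(1)),
      MCC = {
        sc <- rep(0, n)
        cliques <- igraph::max_cliques(graph, min = 2)
        for (cl in cliques) {
          idx <- as.integer(cl)
          sc[idx] <- sc[idx] + factorial(length(idx) - 1)
        }
        sc
      },
      EPC = {
        set.seed(child_seed(seed, 5))
        el <- igraph::as_edgelist(graph, names = FALSE)
        acc <- rep(0, n)
        for (r in seq_len(epc_R)) {
          keep <- rbinom(nrow(el), 1, epc_p) == 1
          gs <- igraph::graph_from_edgelist(el[keep, , drop = FALSE],
                                            directed = FALSE)
          gs <- igraph::add_vertices(gs, max(0, n - igraph::vcount(gs)))
          comp <- igraph::components(gs)
          acc <- acc + comp$csize[comp$membership[seq_len(n)]]
        }
        acc / epc_R
      },
      BottleNeck = bottleneck_scores(adj, n),
      EcCentricity = {
        ecc <- apply(D, 1, function(d) max(d[is.finite(d)]))
        ifelse(ecc > 0, 1 / ecc, 0)
      },
      Closeness = {
        Di <- 1 / D; diag(Di) <- 0; Di[!is.finite(Di)] <- 0
        rowSums(Di)
      },
      Radiality = {
        comp <- igraph::components(graph)
        rad <- rep(0, n)
        for (ci in seq_len(comp$no)) {
          mem <- which(comp$membership == ci)
          if (length(mem) < 2) next
          Dc <- D[mem, mem, drop = FALSE]
          diam <- max(Dc)
          rad[mem] <- rowSums(diam + 1 - Dc) - (diam + 1)  # drop self term
          rad[mem] <- rad[mem] / (n - 1)
        }
        rad
      },
      Betweenness = bs$betweenness,
      Stress = bs$stress)
  }
  top_k <- lapply(methods, function(m) {
    nodes[order(-scores[, m], nodes)][seq_len(min(k, n))]
  })
  names(top_k) <- methods
  structure(list(scores = scores, top_k = top_k, k = k),
            class = "centrality_table")
}

#' Consensus hubs across centrality methods
#'
#' Nodes appearing in the top-k list of at least `m_threshold` methods,
#' together with an UpSet-style per-node method-count table.
#'
#' @param table a `centrality_table` from [compute_centralities()].
#' @param m_threshold minimum number of supporting methods (default 3).
#' @return list with `hubs` (character vector) and `counts` (data.frame
#'   node, n_methods, methods; sorted by decreasing support).
#' @export
consensus_hubs <- function(table, m_threshold = 3) {
  stopifnot(inherits(table, "centrality_table"))
  if (m_threshold > length(table$top_k))
    stopf("m_threshold exceeds the %d computed methods", length(table$top_k))
  all_nodes <- sort(unique(unlist(table$top_k)))
  counts <- vapply(all_nodes, function(v)
    sum(vapply(table$top_k, function(tk) v %in% tk, logical(1))), 1L)
  membership <- vapply(all_nodes, function(v)
    paste(names(table$top_k)[vapply(table$top_k, function(tk)
      v %in% tk, logical(1))], collapse = ","), character(1))
  df <- data.frame(node = all_nodes, n_methods = counts,
                   methods = membership, stringsAsFactors = FALSE)
  df <- df[order(-df$n_methods, df$node), , drop = FALSE]
  rownames(df) <- NULL
  list(hubs = df$node[df$n_methods >= m_threshold], counts = df)
}
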