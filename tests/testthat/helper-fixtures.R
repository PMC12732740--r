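# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (enumeration, triple loops, grid search)
# and independent of the implementation paths they check.

# A tiny deterministic study: `n_genes` x (n1 + n2) samples in groups
# "case"/"ctrl", optional mean shift of the first `n_shift` genes in "case".
tiny_study <- function(n_genes = 20, n1 = 6, n2 = 6, shift = 0,
                       n_shift = 0, sd = 1, seed = 42) {
  set.seed(seed)
  n <- n1 + n2
  m <- matrix(rnorm(n_genes * n, mean = 7, sd = sd), n_genes, n)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  groups <- setNames(rep(c("case", "ctrl"), c(n1, n2)), colnames(m))
  if (n_shift > 0)
    m[seq_len(n_shift), groups == "case"] <-
      m[seq_len(n_shift), groups == "case"] + shift
  expression_study(m, groups)
}

# Exact two-sided Wilcoxon p by full enumeration over all C(n1+n2, n1)
# labelings of the ranks 1..N (no ties).
wilcoxon_p_enum <- function(u_obs, n1, n2) {
  N <- n1 + n2
  combos <- combn(N, n1)
  u_all <- colSums(matrix(seq_len(N)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  min(1, 2 * min(lower, upper))
}

# Naive O(m^2) BH oracle: adj_i = min over sorted-tail of p_(j) * m / j.
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Triple-loop TOM oracle.
tom_naive <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# All-pairs brute-force betweenness and stress for small graphs: enumerate
# every shortest path by DFS over the BFS predecessor DAG.
paths_between <- function(adj_list, s, t) {
  n <- length(adj_list)
  dist <- rep(Inf, n); dist[s] <- 0
  q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj_list[[v]]) if (dist[w] == Inf) {
      dist[w] <- dist[v] + 1; q <- c(q, w)
    }
  }
  if (!is.finite(dist[t])) return(list())
  out <- list()
  walk <- function(v, acc) {
    if (v == s) { out[[length(out) + 1]] <<- rev(acc); return(invisible()) }
    for (p in adj_list[[v]]) if (dist[p] == dist[v] - 1) walk(p, c(acc, p))
  }
  walk(t, t)
  out
}

brute_betweenness_stress <- function(graph) {
  n <- igraph::vcount(graph)
  adj_list <- lapply(igraph::as_adj_list(graph), as.integer)
  bc <- st <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- paths_between(adj_list, s, t)
    if (!length(paths)) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      st[interior] <- st[interior] + 1
      bc[interior] <- bc[interior] + 1 / length(paths)
    }
  }
  list(betweenness = bc, stress = st)
}

# Brute-force MCC: enumerate all vertex subsets, keep maximal cliques.
brute_mcc <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  subsets <- lapply(seq_len(2^n - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0))
  is_clique <- vapply(subsets, function(ss) {
    if (length(ss) < 2) return(FALSE)
    all(A[ss, ss][upper.tri(diag(length(ss)))] == 1)
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    ci <- cliques[[i]]
    !any(vapply(cliques, function(cj)
      length(cj) > length(ci) && all(ci %in% cj), logical(1)))
  }, logical(1))
  sc <- rep(0, n)
  for (cl in cliques[maximal]) sc[cl] <- sc[cl] + factorial(length(cl) - 1)
  sc
}

# Coarse-to-fine 2-d grid maximization oracle for the 1-predictor Firth fit.
firth_grid_oracle <- function(x, y) {
  obj <- function(b0, b1) {
    eta <- b0 + b1 * x
    pi <- plogis(eta)
    w <- pi * (1 - pi)
    X <- cbind(1, x)
    info <- crossprod(X, X * w)
    sum(y * eta - log1p(exp(eta))) +
      0.5 * determinant(info, logarithm = TRUE)$modulus
  }
  b0s <- seq(-3, 3, by = 0.05); b1s <- seq(-4, 4, by = 0.05)
  vals <- outer(b0s, b1s, Vectorize(obj))
  idx <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  ctr <- c(b0s[idx[1]], b1s[idx[2]])
  b0s <- seq(ctr[1] - 0.1, ctr[1] + 0.1, by = 0.002)
  b1s <- seq(ctr[2] - 0.1, ctr[2] + 0.1, by = 0.002)
  vals <- outer(b0s, b1s, Vectorize(obj))
  idx <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  c(b0s[idx[1]], b1s[idx[2]])
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
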