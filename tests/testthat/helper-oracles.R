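# Independent brute-force oracles for the graph metrics, used to check the
# package implementations on small random graphs.

# all simple paths between two nodes, as vectors of node indices
all_simple_paths <- function(adj, from, to) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (adj[v, u] > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(from)
  paths
}

path_len <- function(adj, path, hops = FALSE) {
  if (length(path) < 2) return(0)
  steps <- cbind(path[-length(path)], path[-1])
  if (hops) nrow(steps) else sum(1 / adj[steps])
}

# exhaustive shortest-path length between two nodes (Inf if disconnected)
oracle_spl <- function(adj, from, to) {
  if (from == to) return(0)
  paths <- all_simple_paths(adj, from, to)
  if (!length(paths)) return(Inf)
  min(vapply(paths, function(p) path_len(adj, p), 0))
}

oracle_spl_matrix <- function(adj) {
  n <- nrow(adj)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) L[i, j] <- oracle_spl(adj, i, j)
  }
  L
}

oracle_char_path_length <- function(adj) {
  L <- oracle_spl_matrix(adj)
  off <- L[row(L) != col(L)]
  mean(off[is.finite(off)])
}

oracle_global_efficiency <- function(adj) {
  L <- oracle_spl_matrix(adj)
  off <- L[row(L) != col(L)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

oracle_clustering <- function(adj, i) {
  n <- nrow(adj)
  num <- 0; den <- 0
  for (k in seq_len(n)) for (l in seq_len(n)) {
    if (k == i || l == i || l == k) next
    num <- num + adj[i, k] * adj[i, l] * adj[k, l]
    den <- den + adj[i, k] * adj[i, l]
  }
  if (den <= 0) 0 else num / den
}

oracle_local_efficiency <- function(adj, i) {
  nb <- which(adj[i, ] > 0)
  if (length(nb) < 2) return(0)
  oracle_global_efficiency(adj[nb, nb, drop = FALSE])
}

# standard betweenness over unordered pairs, counting length-tied paths
# as shortest within relative tolerance
oracle_betweenness <- function(adj, i, tol = 1e-9) {
  n <- nrow(adj)
  b <- 0
  for (m in seq_len(n - 1)) for (nn in seq.int(m + 1L, n)) {
    if (m == i || nn == i) next
    paths <- all_simple_paths(adj, m, nn)
    if (!length(paths)) next
    lens <- vapply(paths, function(p) path_len(adj, p), 0)
    best <- min(lens)
    short <- paths[lens <= best * (1 + tol) + tol]
    via <- vapply(short, function(p) i %in% p[-c(1, length(p))], TRUE)
    b <- b + sum(via) / length(short)
  }
  b
}

# random connected-ish weighted graph with weights in (0.2, 1) and a given
# fraction of absent edges
random_weighted_adj <- function(n, sparsity = 0.2) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  w <- stats::runif(sum(up), 0.2, 1)
  w[stats::runif(sum(up)) < sparsity] <- 0
  a[up] <- w
  a + t(a)
}
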