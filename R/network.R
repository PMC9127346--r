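#' Weighted brain functional-connectivity network
#'
#' Treats a PLV matrix as the weighted adjacency of an undirected graph on
#' the EEG channels. Edge traversal length is the reciprocal weight `1/c_ij`
#' (infinite for absent edges), the usual convention for synchrony-weighted
#' brain graphs: strong phase locking means a short functional path. A
#' hop-count mode (`lengths = "hops"`) treats every present edge as length 1.
#'
#' @param plv a `plv_matrix` from [plv_matrix()], or a plain symmetric
#'   non-negative matrix (diagonal is ignored and zeroed).
#' @param lengths `"reciprocal"` (default) or `"hops"`.
#' @param tie_tol relative tolerance under which two path lengths count as
#'   tied when counting shortest paths (default 1e-9).
#' @return a `brain_network`: adjacency, node labels, all-pairs shortest-path
#'   length matrix `L`.
#' @export
from_plv <- function(plv, lengths = c("reciprocal", "hops"), tie_tol = 1e-9) {
  lengths <- match.arg(lengths)
  if (inherits(plv, "plv_matrix")) {
    validate_plv(plv)
    adj <- plv$values
    labels <- plv$channel_labels
  } else {
    adj <- as.matrix(plv)
    labels <- rownames(adj)
    if (is.null(labels)) labels <- paste0("n", seq_len(nrow(adj)))
    if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
    if (max(abs(adj - t(adj))) > 1e-9) stop("adjacency must be symmetric")
    if (any(adj < 0)) stop("adjacency weights must be non-negative")
  }
  diag(adj) <- 0
  dimnames(adj) <- list(labels, labels)
  el <- if (lengths == "reciprocal") ifelse(adj > 0, 1 / adj, Inf)
        else ifelse(adj > 0, 1, Inf)
  diag(el) <- 0
  structure(list(adjacency = adj, node_labels = labels,
                 edge_lengths = el, L = floyd_warshall(el),
                 tie_tol = tie_tol),
            class = "brain_network")
}

# All-pairs shortest path lengths by Floyd-Warshall (dense, small N).
floyd_warshall <- function(el) {
  d <- el
  n <- nrow(d)
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    upd <- dk < d
    d[upd] <- dk[upd]
  }
  d
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("<brain_network> %d nodes, %d weighted edges\n",
              nrow(x$adjacency), sum(x$adjacency[upper.tri(x$adjacency)] > 0)))
  invisible(x)
}

node_idx <- function(net, node) {
  if (is.numeric(node)) {
    i <- as.integer(node)
    if (i < 1L || i > length(net$node_labels)) stop("node index out of range")
    return(i)
  }
  i <- match(node, net$node_labels)
  if (is.na(i)) stop("unknown node: ", node)
  i
}

#' Weighted clustering coefficient
#'
#' Ratio of the weighted closed-triple sum around a node to the weighted
#' open-triple sum:
#' `C_i = sum_{k != l} c_ik c_il c_kl / sum_{k != l} c_ik c_il`
#' (indices exclude i). Returns 0 when the denominator vanishes. For weights
#' in \[0, 1\] the value lies in \[0, 1\].
#'
#' @param net a `brain_network`.
#' @param node node label or index; omit for all nodes.
#' @return scalar, or named vector over all nodes when `node` is `NULL`.
#' @export
clustering_coefficient <- function(net, node = NULL) {
  C <- net$adjacency
  if (nrow(C) < 3) stop("clustering needs at least 3 nodes")
  one_node <- function(i) {
    w <- C[i, ]
    num <- drop(t(w) %*% C %*% w)          # k = l terms vanish (diag 0)
    den <- sum(w)^2 - sum(w^2)
    if (den <= 0) 0 else num / den
  }
  if (!is.null(node)) return(one_node(node_idx(net, node)))
  stats::setNames(vapply(seq_along(net$node_labels), one_node, 0),
                  net$node_labels)
}

#' Characteristic path length
#'
#' Mean shortest-path length over ordered node pairs. Disconnected pairs are
#' excluded from the mean; if no pair is connected the result is `Inf`.
#'
#' @param net a `brain_network`.
#' @return scalar >= 0.
#' @export
characteristic_path_length <- function(net) {
  L <- net$L
  if (nrow(L) < 2) stop("path length needs at least 2 nodes")
  off <- L[row(L) != col(L)]
  finite <- off[is.finite(off)]
  if (!length(finite)) return(Inf)
  mean(finite)
}

#' Global efficiency
#'
#' Mean reciprocal shortest-path length over ordered node pairs, with
#' `1/L_ij := 0` for disconnected pairs. Equals 1 on the complete unit-weight
#' graph and 0 on the empty graph.
#'
#' @param net a `brain_network`.
#' @return scalar >= 0.
#' @export
global_efficiency <- function(net) {
  L <- net$L
  if (nrow(L) < 2) stop("efficiency needs at least 2 nodes")
  off <- L[row(L) != col(L)]
  mean(ifelse(is.finite(off) & off > 0, 1 / off, 0))
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbours (the
#' node itself excluded); 0 when the node has fewer than 2 neighbours.
#'
#' @param net a `brain_network`.
#' @param node node label or index; omit for all nodes.
#' @return scalar, or named vector over all nodes.
#' @export
local_efficiency <- function(net, node = NULL) {
  one_node <- function(i) {
    nb <- which(net$adjacency[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- from_plv(net$adjacency[nb, nb, drop = FALSE],
                    lengths = if (all(net$edge_lengths[net$adjacency > 0] == 1))
                      "hops" else "reciprocal",
                    tie_tol = net$tie_tol)
    global_efficiency(sub)
  }
  if (!is.null(node)) return(one_node(node_idx(net, node)))
  stats::setNames(vapply(seq_along(net$node_labels), one_node, 0),
                  net$node_labels)
}

# Shortest-path counts sigma[s, v] from every source, with tolerance-tied
# path lengths: a dynamic program over nodes in order of distance.
sigma_matrix <- function(net) {
  el <- net$edge_lengths
  n <- nrow(el)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    D <- net$L[s, ]
    ord <- order(D)
    ord <- ord[is.finite(D[ord])]
    sigma <- numeric(n); sigma[s] <- 1
    for (v in ord) {
      if (v == s) next
      tol <- net$tie_tol * max(1, abs(D[v]))
      u <- which(is.finite(el[, v]) & el[, v] > 0 &
                   abs(D + el[, v] - D[v]) <= tol)
      sigma[v] <- sum(sigma[u])
    }
    sig[s, ] <- sigma
  }
  sig
}

# Through-count sigma_mn(i): shortest m-n paths via i. Zero unless i lies on
# a shortest path, in which case it is sigma_mi * sigma_in.
through_count <- function(net, sig, m, i, n) {
  D <- net$L
  if (m == i || n == i || m == n) return(0)
  if (!is.finite(D[m, n]) || sig[m, n] == 0) return(0)
  tol <- net$tie_tol * max(1, abs(D[m, n]))
  if (abs(D[m, i] + D[i, n] - D[m, n]) > tol) return(0)
  sig[m, i] * sig[i, n]
}

betweenness_all <- function(net) {
  n <- length(net$node_labels)
  sig <- sigma_matrix(net)
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (m in seq_len(n - 1)) for (nn in seq.int(m + 1L, n)) {
      if (m == i || nn == i) next
      tc <- through_count(net, sig, m, i, nn)
      if (tc > 0) b[i] <- b[i] + tc / sig[m, nn]
    }
  }
  stats::setNames(b, net$node_labels)
}

# Relative through-share reproducing the worked two-branch arithmetic:
# over the ordered pairs (m, n) that route through node i, node i's
# fractional through-count divided by the total fractional through-counts
# of every intermediate node (i and its competitors) on those same pairs.
betweenness_share <- function(net) {
  n <- length(net$node_labels)
  sig <- sigma_matrix(net)
  share <- numeric(n)
  for (i in seq_len(n)) {
    t_own <- 0; t_all <- 0
    for (m in seq_len(n)) for (nn in seq_len(n)) {
      if (m == nn || m == i || nn == i) next
      tc <- through_count(net, sig, m, i, nn)
      if (tc == 0) next
      t_own <- t_own + tc / sig[m, nn]
      for (k in seq_len(n)) {
        if (k == m || k == nn) next
        t_all <- t_all + through_count(net, sig, m, k, nn) / sig[m, nn]
      }
    }
    share[i] <- if (t_all > 0) t_own / t_all else 0
  }
  stats::setNames(share, net$node_labels)
}

#' Betweenness centrality
#'
#' Standard mode: for each unordered node pair (m, n) with m, n != i, the
#' fraction of shortest m-n paths passing through i, summed over pairs;
#' paths tied in total length within a relative tolerance all count as
#' shortest. `paper_fig2` mode reports a relative through-share instead:
#' over the pairs that route through node i, i's fractional through-count
#' divided by the total fractional through-counts of all intermediate
#' nodes on those pairs. On a two-branch relay network, where each of the
#' two relays carries half of the source-to-sink traffic, each relay's
#' share is one half.
#'
#' @param net a `brain_network`.
#' @param node node label or index; omit for all nodes.
#' @param normalization `"standard"` (default) or `"paper_fig2"`.
#' @return scalar, or named vector over all nodes.
#' @export
betweenness <- function(net, node = NULL,
                        normalization = c("standard", "paper_fig2")) {
  normalization <- match.arg(normalization)
  b <- if (normalization == "paper_fig2") betweenness_share(net)
       else betweenness_all(net)
  if (!is.null(node)) return(unname(b[node_idx(net, node)]))
  b
}

#' Network-metric feature vector
#'
#' Deterministic concatenation `[C_1..C_N, L, G, Le_1..Le_N, b_1..b_N]`
#' (clustering per node, characteristic path length, global efficiency,
#' local efficiency per node, standard betweenness per node); length 3N + 2.
#'
#' @param net a `brain_network`.
#' @return named numeric vector.
#' @export
network_feature_vector <- function(net) {
  n <- length(net$node_labels)
  c(stats::setNames(clustering_coefficient(net), paste0("C_", net$node_labels)),
    L = characteristic_path_length(net),
    G = global_efficiency(net),
    stats::setNames(local_efficiency(net), paste0("Le_", net$node_labels)),
    stats::setNames(betweenness(net), paste0("b_", net$node_labels)))
}

#' The two-branch relay network used as a betweenness worked example
#'
#' A source and a sink joined by two parallel two-edge branches with unit
#' weights: source - relay1 - sink and source - relay2 - sink. Each branch
#' carries one of the two shortest source-sink paths, so each relay's share
#' of total through-traffic is one half.
#'
#' @return a `brain_network` on nodes F1, n2, n4, F3.
#' @export
two_branch_network <- function() {
  labels <- c("F1", "n2", "n4", "F3")
  adj <- matrix(0, 4, 4, dimnames = list(labels, labels))
  adj["F1", "n2"] <- adj["n2", "F3"] <- 1
  adj["F1", "n4"] <- adj["n4", "F3"] <- 1
  adj <- adj + t(adj)
  from_plv(adj)
}
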