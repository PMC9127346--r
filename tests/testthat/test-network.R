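complete_net <- function(n) {
  a <- matrix(1, n, n); diag(a) <- 0
  from_plv(a)
}

test_that("from_plv builds reciprocal edge lengths and shortest paths", {
  net <- complete_net(4)
  expect_equal(unname(net$L[row(net$L) != col(net$L)]), rep(1, 12))

  a2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(from_plv(a2)$L[1, 2], 2)

  set.seed(11)
  for (rep in 1:10) {
    adj <- random_weighted_adj(5)
    net <- from_plv(adj)
    expect_equal(unname(net$L), oracle_spl_matrix(adj), tolerance = 1e-12)
  }
})

test_that("clustering coefficient matches the double-sum definition", {
  expect_equal(unname(clustering_coefficient(complete_net(5))), rep(1, 5))

  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(clustering_coefficient(from_plv(star), 1), 0)

  set.seed(12)
  for (rep in 1:10) {
    adj <- random_weighted_adj(6)
    net <- from_plv(adj)
    for (i in 1:6) {
      expect_equal(clustering_coefficient(net, i), oracle_clustering(adj, i),
                   tolerance = 1e-12)
    }
  }
  expect_error(clustering_coefficient(complete_net(4), "nope"), "unknown node")
})

test_that("path length and efficiencies match enumeration oracles", {
  expect_equal(characteristic_path_length(complete_net(6)), 1)
  expect_equal(global_efficiency(complete_net(6)), 1)
  expect_equal(unname(local_efficiency(complete_net(6))), rep(1, 6))

  # 3-node path graph: ordered pairs (1,2),(2,1),(2,3),(3,2) at length 1
  # and (1,3),(3,1) at length 2
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  expect_equal(characteristic_path_length(from_plv(path3)), 4 / 3)

  empty <- from_plv(matrix(0, 3, 3))
  expect_equal(global_efficiency(empty), 0)

  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(local_efficiency(from_plv(star), 1), 0)

  set.seed(13)
  for (rep in 1:10) {
    adj <- random_weighted_adj(6)
    net <- from_plv(adj)
    expect_equal(characteristic_path_length(net),
                 oracle_char_path_length(adj), tolerance = 1e-12)
    expect_equal(global_efficiency(net), oracle_global_efficiency(adj),
                 tolerance = 1e-12)
    for (i in 1:6) {
      expect_equal(local_efficiency(net, i), oracle_local_efficiency(adj, i),
                   tolerance = 1e-12)
    }
  }
})

test_that("standard betweenness matches enumeration and closed forms", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  expect_equal(betweenness(from_plv(path3), 2), 1)

  # star: center (N-1)(N-2)/2, leaves 0
  for (N in c(4, 6)) {
    star <- matrix(0, N, N); star[1, 2:N] <- star[2:N, 1] <- 1
    b <- betweenness(from_plv(star))
    expect_equal(unname(b[1]), (N - 1) * (N - 2) / 2)
    expect_equal(unname(b[-1]), rep(0, N - 1))
  }

  set.seed(14)
  for (rep in 1:8) {
    adj <- random_weighted_adj(6)
    net <- from_plv(adj)
    for (i in 1:6) {
      expect_equal(betweenness(net, i), oracle_betweenness(adj, i),
                   tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant / equivariant under node relabeling", {
  set.seed(15)
  adj <- random_weighted_adj(6, sparsity = 0.3)
  perm <- sample(6)
  net <- from_plv(adj)
  netp <- from_plv(adj[perm, perm])
  expect_equal(characteristic_path_length(netp),
               characteristic_path_length(net), tolerance = 1e-12)
  expect_equal(global_efficiency(netp), global_efficiency(net),
               tolerance = 1e-12)
  expect_equal(unname(clustering_coefficient(netp)),
               unname(clustering_coefficient(net))[perm], tolerance = 1e-12)
  expect_equal(unname(betweenness(netp)), unname(betweenness(net))[perm],
               tolerance = 1e-12)
})

test_that("global efficiency dominates the reciprocal path length", {
  set.seed(16)
  for (rep in 1:100) {
    adj <- random_weighted_adj(6, sparsity = 0)   # connected
    net <- from_plv(adj)
    expect_gte(global_efficiency(net),
               1 / characteristic_path_length(net) - 1e-12)
  }
})

test_that("network feature vector composes the metrics deterministically", {
  net <- complete_net(4)
  fv <- network_feature_vector(net)
  expect_length(fv, 3 * 4 + 2)
  expect_equal(unname(fv), c(rep(1, 4), 1, 1, rep(1, 4), rep(0, 4)))

  set.seed(17)
  adj <- random_weighted_adj(5)
  perm <- sample(5)
  f1 <- network_feature_vector(from_plv(adj))
  f2 <- network_feature_vector(from_plv(adj[perm, perm]))
  expect_equal(unname(f2[5 + 1:2]), unname(f1[5 + 1:2]), tolerance = 1e-12)
  expect_equal(unname(f2[1:5]), unname(f1[1:5])[perm], tolerance = 1e-12)
})

test_that("hop-count mode treats every present edge as unit length", {
  a <- matrix(c(0, 0.2, 0.2, 0), 2)
  expect_equal(from_plv(a, lengths = "hops")$L[1, 2], 1)
})
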