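test_that("degree centrality matches hand-drawn graphs and the handshake identity", {
  tri <- toy_net(c("A", "B", "B", "C", "A", "C"))
  expect_equal(degree_centrality(tri), c(A = 2L, B = 2L, C = 2L))

  star <- toy_net(c("HUB", "L1", "HUB", "L2", "HUB", "L3"))
  deg <- degree_centrality(star)
  expect_equal(deg[["HUB"]], 3L)
  expect_equal(unname(deg[c("L1", "L2", "L3")]), c(1L, 1L, 1L))

  set.seed(42)
  for (i in 1:10) {
    net <- net_from_adjacency(random_adjacency(sample(4:12, 1), runif(1, 0.2, 0.8)))
    expect_equal(sum(degree_centrality(net)), 2L * n_edges(net))
  }
})

test_that("betweenness matches hand-enumerated path graphs", {
  path3 <- toy_net(c("A", "B", "B", "C"))
  expect_equal(betweenness_centrality(path3, normalized = FALSE),
               c(A = 0, B = 1, C = 0))
  expect_equal(betweenness_centrality(path3, normalized = TRUE),
               c(A = 0, B = 1, C = 0))

  k4 <- toy_net(c("A", "B", "A", "C", "A", "D", "B", "C", "B", "D", "C", "D"))
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))

  # 4-cycle: each opposite pair has two shortest paths, each interior
  # node carries half of one pair -> raw 0.5
  c4 <- toy_net(c("A", "B", "B", "C", "C", "D", "D", "A"))
  expect_equal(unname(betweenness_centrality(c4, normalized = FALSE)),
               rep(0.5, 4))
  expect_equal(unname(betweenness_centrality(c4, normalized = TRUE)),
               rep(0.5 / 3, 4))
})

test_that("closeness matches the component-adjusted formula on hand examples", {
  path3 <- toy_net(c("A", "B", "B", "C"))
  clo <- closeness_centrality(path3)
  expect_equal(clo[["B"]], 1)
  expect_equal(clo[["A"]], 2 / 3)

  k4 <- toy_net(c("A", "B", "A", "C", "A", "D", "B", "C", "B", "D", "C", "D"))
  expect_equal(unname(closeness_centrality(k4)), rep(1, 4))

  # two disconnected edges: (1/1) * (1/3) for every node
  two <- toy_net(c("A", "B", "C", "D"))
  expect_equal(unname(closeness_centrality(two)), rep(1 / 3, 4))

  iso <- toy_net(c("A", "B"), extra_nodes = "LONER")
  expect_equal(closeness_centrality(iso)[["LONER"]], 0)
})

test_that("betweenness and closeness agree with brute-force oracles", {
  set.seed(7)
  for (i in 1:25) {
    adj <- random_adjacency(sample(4:8, 1), runif(1, 0.2, 0.7))
    net <- net_from_adjacency(adj)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(adj),
                 tolerance = 1e-12)
    expect_equal(unname(closeness_centrality(net)), oracle_closeness(adj),
                 tolerance = 1e-12)
    # independent library cross-check on the raw values
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(betweenness_centrality(net, normalized = FALSE)),
                 unname(igraph::betweenness(g, directed = FALSE)),
                 tolerance = 1e-12)
  }
})

test_that("centralities are equivariant under node relabelling", {
  set.seed(11)
  adj <- random_adjacency(7, 0.4)
  ids <- sprintf("N%02d", 1:7)
  perm <- sample(7)
  net1 <- net_from_adjacency(adj, ids)
  net2 <- net_from_adjacency(adj[perm, perm], ids[perm])
  for (f in list(degree_centrality, betweenness_centrality, closeness_centrality)) {
    v1 <- f(net1)
    v2 <- f(net2)
    expect_equal(v2[names(v1)], v1, tolerance = 1e-12)
  }
})

test_that("adding an edge never lowers degree or endpoint closeness", {
  set.seed(19)
  for (i in 1:10) {
    adj <- random_adjacency(8, 0.3)
    free <- which(upper.tri(adj) & adj == 0)
    if (length(free) == 0) next
    pick <- sample(free, 1)
    adj2 <- adj
    adj2[pick] <- 1L
    adj2 <- pmax(adj2, t(adj2))
    rc <- arrayInd(pick, dim(adj))
    net1 <- net_from_adjacency(adj)
    net2 <- net_from_adjacency(adj2)
    expect_true(all(degree_centrality(net2) >= degree_centrality(net1)))
    c1 <- closeness_centrality(net1)
    c2 <- closeness_centrality(net2)
    ends <- sprintf("N%02d", rc)
    expect_true(all(c2[ends] >= c1[ends] - 1e-12))
  }
})

test_that("centrality table carries exact network means", {
  net <- toy_net(c("HUB", "L1", "HUB", "L2", "HUB", "L3"))
  tab <- centrality_table(net)
  means <- attr(tab, "means")
  expect_equal(means[["mean_degree"]], 2 * n_edges(net) / n_nodes(net))
  expect_equal(means[["mean_degree"]], 1.5)
  expect_equal(means[["mean_betweenness"]], 0.25)
  expect_equal(means[["mean_closeness"]], 0.7)
  expect_equal(means[["mean_betweenness"]], mean(tab$betweenness))
  expect_equal(means[["mean_closeness"]], mean(tab$closeness))
})

test_that("major-node selection applies the inclusive mean rule", {
  star <- toy_net(c("HUB", "L1", "HUB", "L2", "HUB", "L3"))
  sel <- select_major_nodes(centrality_table(star))
  expect_equal(sel$nodes, "HUB")

  # regular graph: everyone sits exactly at the mean, >= keeps all
  c5 <- toy_net(c("A", "B", "B", "C", "C", "D", "D", "E", "E", "A"))
  sel5 <- select_major_nodes(centrality_table(c5))
  expect_setequal(sel5$nodes, c("A", "B", "C", "D", "E"))

  # scope restricts eligibility but not the means
  net <- pharm_network(
    nodes = data.frame(node_id = c("HUB", "L1", "L2", "L3"),
                       role = c("compound", rep("other_protein", 3))),
    edges = data.frame(from = rep("HUB", 3), to = c("L1", "L2", "L3")))
  sel2 <- select_major_nodes(centrality_table(net), scope = "other_protein")
  expect_length(sel2$nodes, 0L)
  expect_equal(unname(sel2$thresholds["mean_degree"]), 1.5)

  expect_error(select_major_nodes(centrality_table(net)[0, ]),
               class = "netpharm_validation_error")
})
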