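ct_records <- function(...) {
  pairs <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(compound_id = pairs[, 1],
             compound_name = pairs[, 1],
             target_symbol = pairs[, 2],
             rank = stats::ave(seq_len(nrow(pairs)), pairs[, 1], FUN = seq_along),
             fit_score = NA_real_, stringsAsFactors = FALSE)
}

ppi_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(protein_a = pmin(m[, 1], m[, 2]), protein_b = pmax(m[, 1], m[, 2]),
             combined_score = 0.9, stringsAsFactors = FALSE)
}

test_that("compound-target network is the bipartite graph of distinct pairs", {
  net <- build_compound_target_network(ct_records("c1", "T1"))
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_edges(net), 1L)

  net2 <- build_compound_target_network(ct_records("c1", "T1", "c2", "T1"))
  expect_equal(n_nodes(net2), 3L)
  expect_equal(n_edges(net2), 2L)
  roles <- node_roles(net2)
  expect_equal(sum(roles == "compound"), 2L)
  expect_equal(sum(roles == "compound_target"), 1L)

  expect_error(build_compound_target_network(ct_records("c1", "T1")[0, ]),
               class = "netpharm_validation_error")
})

test_that("disease network takes the induced subgraph on the seed shell", {
  ppi <- ppi_df("A", "B", "B", "C")
  net1 <- build_disease_ppi_network("A", ppi, shell = 1)
  expect_setequal(net1$nodes$node_id, c("A", "B")) # C is two hops away
  expect_equal(n_edges(net1), 1L)

  net2 <- build_disease_ppi_network("A", ppi, shell = 2)
  expect_setequal(net2$nodes$node_id, c("A", "B", "C"))
  expect_equal(n_edges(net2), 2L)

  # seeds absent from the PPI are kept isolated, with a warning
  expect_warning(net3 <- build_disease_ppi_network(c("A", "ZZ"), ppi), "ZZ")
  expect_true("ZZ" %in% net3$nodes$node_id)
  expect_equal(unname(node_roles(net3)[["ZZ"]]), "disease_seed")

  expect_error(build_disease_ppi_network("ZZ", ppi),
               class = "netpharm_validation_error")
  expect_error(build_disease_ppi_network("A", ppi, shell = 3),
               class = "netpharm_usage_error")
})

test_that("shell enlargement never removes nodes or edges", {
  cfg <- small_cfg(seed = 5)
  gp <- gen_ppi(cfg)
  tmp <- tempfile()
  write_ppi(gp$edges, tmp)
  ppi <- load_ppi(tmp)
  n1 <- build_disease_ppi_network(gp$seeds, ppi, shell = 1)
  n2 <- build_disease_ppi_network(gp$seeds, ppi, shell = 2)
  expect_true(all(n1$nodes$node_id %in% n2$nodes$node_id))
  e1 <- paste(n1$edges$from, n1$edges$to)
  e2 <- paste(n2$edges$from, n2$edges$to)
  expect_true(all(e1 %in% e2))
})

test_that("intersect_targets is the set intersection over the disease network", {
  cn <- build_compound_target_network(ct_records("c1", "X", "c1", "Y", "c1", "Z"))
  dn <- build_disease_ppi_network("Y", ppi_df("Y", "Z", "Y", "W"))
  expect_equal(intersect_targets(cn, dn), c("Y", "Z"))

  dn2 <- build_disease_ppi_network("Q", ppi_df("Q", "R"))
  expect_warning(out <- intersect_targets(cn, dn2), "empty intersection")
  expect_length(out, 0L)
})

test_that("merged network joins qualifying compounds, intersection, and shell", {
  # minimal: one intersection target, no PPI neighbours, one linked compound
  rec <- ct_records("c1", "T1", "c2", "QQ")
  merged <- build_merged_network(rec, "T1", ppi_df("ZZ", "YY"))
  expect_equal(n_nodes(merged$network), 2L) # c2 has no intersection link
  expect_equal(n_edges(merged$network), 1L)
  expect_equal(merged$report$n_compounds, 1L)
  expect_equal(merged$report$n_intersection_targets, 1L)

  expect_error(build_merged_network(rec, character(0), ppi_df("A", "B")),
               class = "netpharm_validation_error")
  # all compound targets outside the intersection
  expect_error(build_merged_network(ct_records("c1", "T1"), "OTHER",
                                    ppi_df("OTHER", "B")),
               class = "netpharm_validation_error")
})

test_that("role partition and merge report are consistent on every build", {
  cfg <- small_cfg(seed = 9)
  fixture <- gen_merged_fixture(cfg)
  d <- tempfile()
  paths <- write_fixture_dir(fixture, d)
  rec <- load_compound_targets(paths[["compound_targets"]])
  ppi <- load_ppi(paths[["ppi"]])
  for (net in list(build_compound_target_network(rec),
                   build_disease_ppi_network(fixture$seeds, ppi),
                   build_merged_network(rec, fixture$intersection, ppi)$network)) {
    rep <- merge_report(net)
    role_sum <- rep$n_compounds + rep$n_compound_targets + rep$n_seed_genes +
      rep$n_intersection_targets + rep$n_other_proteins
    expect_equal(role_sum, n_nodes(net))
    expect_equal(anyDuplicated(net$nodes$node_id), 0L)
  }
})

test_that("merged network is the PPI-induced subgraph on its protein nodes", {
  cfg <- small_cfg(seed = 13)
  fixture <- gen_merged_fixture(cfg)
  d <- tempfile()
  paths <- write_fixture_dir(fixture, d)
  rec <- load_compound_targets(paths[["compound_targets"]])
  ppi <- load_ppi(paths[["ppi"]])
  merged <- build_merged_network(rec, fixture$intersection, ppi)$network
  prot <- merged$nodes$node_id[merged$nodes$role != "compound"]
  in_ppi <- paste(ppi$protein_a, ppi$protein_b)
  in_net <- paste(merged$edges$from, merged$edges$to)
  # every PPI edge between included proteins is present...
  covered <- ppi$protein_a %in% prot & ppi$protein_b %in% prot
  expect_true(all(in_ppi[covered] %in% in_net))
  # ...and every protein-protein edge of the network is a PPI edge
  pp_edges <- merged$edges$from %in% prot & merged$edges$to %in% prot
  expect_true(all(in_net[pp_edges] %in% in_ppi))
})

test_that("a seed that is also a compound target gets the intersection role", {
  cfg <- small_cfg(seed = 3)
  fixture <- gen_merged_fixture(cfg)
  d <- tempfile()
  paths <- write_fixture_dir(fixture, d)
  rec <- load_compound_targets(paths[["compound_targets"]])
  ppi <- load_ppi(paths[["ppi"]])
  merged <- build_merged_network(rec, fixture$intersection, ppi)$network
  roles <- node_roles(merged)
  hub_seeds <- fixture$planted_hubs # seed genes targeted by compounds
  expect_true(all(roles[hub_seeds] == "intersection_target"))
})
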