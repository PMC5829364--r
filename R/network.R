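NODE_ROLES <- c("compound", "compound_target", "disease_seed",
                "intersection_target", "other_protein")

#' Construct a pharmacology network
#'
#' A `pharm_network` is a simple undirected graph whose nodes carry
#' exactly one role out of `compound`, `compound_target`, `disease_seed`,
#' `intersection_target`, `other_protein`. Nodes and edges are stored in
#' a fixed lexicographic order so identical inputs always export
#' byte-identically.
#'
#' @param nodes Data frame with columns `node_id`, `role`.
#' @param edges Data frame with columns `from`, `to` (node ids), or NULL
#'   for an edgeless network.
#' @param name Network name.
#' @return An object of class `pharm_network` with sorted `nodes` and
#'   canonicalised `edges` (`from < to`).
#' @export
pharm_network <- function(nodes, edges = NULL, name = "") {
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id))
    np_validation_error("duplicate node_id (each node has exactly one role)")
  bad_role <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad_role) > 0L)
    np_validation_error(paste0("unknown node role(s): ", paste(bad_role, collapse = ", ")))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  } else {
    if (!all(c("from", "to") %in% names(edges)))
      np_usage_error("edges must have 'from' and 'to' columns")
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    if (any(from == to)) np_validation_error("self-loop edge in network")
    miss <- setdiff(union(from, to), nodes$node_id)
    if (length(miss) > 0L)
      np_validation_error(paste0("edge endpoint(s) not in node set: ",
                                 paste(utils::head(miss, 3), collapse = ", ")))
    edges <- data.frame(from = pmin(from, to), to = pmax(from, to),
                        stringsAsFactors = FALSE)
    edges <- unique(edges)
  }
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "pharm_network")
}

#' @export
print.pharm_network <- function(x, ...) {
  tally <- table(factor(x$nodes$role, levels = NODE_ROLES))
  tally <- tally[tally > 0]
  cat(sprintf("<pharm_network> '%s': %d nodes, %d edges\n",
              x$name, nrow(x$nodes), nrow(x$edges)))
  if (length(tally) > 0)
    cat("  roles:", paste(sprintf("%s=%d", names(tally), tally), collapse = ", "), "\n")
  invisible(x)
}

#' Number of nodes / edges of a pharm_network
#' @param net A [pharm_network()].
#' @return Integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Role of each node
#' @param net A [pharm_network()].
#' @return Named character vector of roles, keyed by node id.
#' @export
node_roles <- function(net) stats::setNames(net$nodes$role, net$nodes$node_id)

#' Convert between pharm_network and igraph
#'
#' The igraph form carries the role as a vertex attribute and is the
#' interchange used for GraphML export and shortest-path computations.
#'
#' @param net A [pharm_network()].
#' @return An undirected [igraph::igraph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "pharm_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' @rdname as_igraph
#' @param g An undirected igraph with vertex attributes `name` and `role`.
#' @param name Network name for the result.
#' @export
from_igraph <- function(g, name = "") {
  nodes <- data.frame(node_id = igraph::V(g)$name,
                      role = igraph::V(g)$role,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  pharm_network(nodes, edges, name = name)
}

# role precedence when a symbol qualifies for more than one protein role
ROLE_PRECEDENCE <- c(intersection_target = 1L, disease_seed = 2L,
                     compound_target = 3L, other_protein = 4L)

#' Build the compound-target bipartite network
#'
#' Connects each compound to its predicted targets: a bipartite simple
#' graph with node roles `compound` and `compound_target` and one edge
#' per distinct (compound, target) pair.
#'
#' @param records Data frame of compound-target records as returned by
#'   [load_compound_targets()].
#' @return A [pharm_network()].
#' @export
build_compound_target_network <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    np_validation_error("cannot build a compound-target network from zero records")
  compounds <- sort(unique(records$compound_id))
  targets <- sort(unique(records$target_symbol))
  overlap <- intersect(compounds, targets)
  if (length(overlap) > 0L)
    np_validation_error("compound ids collide with target symbols; use distinct namespaces")
  nodes <- data.frame(
    node_id = c(compounds, targets),
    role = c(rep("compound", length(compounds)),
             rep("compound_target", length(targets))),
    stringsAsFactors = FALSE)
  edges <- unique(data.frame(from = records$compound_id,
                             to = records$target_symbol,
                             stringsAsFactors = FALSE))
  pharm_network(nodes, edges, name = "compound_target")
}

ppi_graph <- function(ppi) {
  igraph::graph_from_data_frame(ppi[, c("protein_a", "protein_b")],
                                directed = FALSE)
}

neighborhood_nodes <- function(g, anchors, shell) {
  present <- intersect(anchors, igraph::V(g)$name)
  if (length(present) == 0L) return(character())
  nb <- igraph::ego(g, order = shell, nodes = present, mode = "all")
  sort(unique(unlist(lapply(nb, names), use.names = FALSE)))
}

induced_edges <- function(ppi, keep) {
  sel <- ppi$protein_a %in% keep & ppi$protein_b %in% keep
  ppi[sel, c("protein_a", "protein_b"), drop = FALSE]
}

#' Build the disease-seed PPI neighbourhood network
#'
#' Anchors the confidence-filtered PPI at the disease seed genes and
#' extracts the induced subgraph on the seeds plus everything within
#' `shell` hops of any seed. Keeping all induced edges (including edges
#' among non-seed neighbours) is how "indirect" interaction between
#' seeds via shared partners is represented. Seeds absent from the PPI
#' are retained as isolated `disease_seed` nodes with a warning.
#'
#' @param seeds Character vector of seed gene symbols.
#' @param ppi PPI edge data.frame as returned by [load_ppi()].
#' @param shell Neighbourhood radius, 1 (default) or 2.
#' @return A [pharm_network()] with roles `disease_seed` / `other_protein`.
#' @export
build_disease_ppi_network <- function(seeds, ppi, shell = 1L) {
  seeds <- unique(norm_symbol(seeds))
  seeds <- seeds[nzchar(seeds)]
  if (length(seeds) == 0L) np_usage_error("seeds must be non-empty")
  if (!shell %in% c(1L, 2L)) np_usage_error("shell must be 1 or 2")
  g <- ppi_graph(ppi)
  present <- intersect(seeds, igraph::V(g)$name)
  if (length(present) == 0L)
    np_validation_error("no seed gene appears in the filtered PPI; network would be vacuous")
  absent <- setdiff(seeds, present)
  if (length(absent) > 0L)
    warning(sprintf("%d seed gene(s) absent from the PPI kept as isolated nodes: %s",
                    length(absent), paste(absent, collapse = ", ")))
  keep <- union(neighborhood_nodes(g, present, shell), seeds)
  role <- ifelse(keep %in% seeds, "disease_seed", "other_protein")
  nodes <- data.frame(node_id = keep, role = role, stringsAsFactors = FALSE)
  pe <- induced_edges(ppi, keep)
  pharm_network(nodes,
                data.frame(from = pe$protein_a, to = pe$protein_b,
                           stringsAsFactors = FALSE),
                name = "disease_ppi")
}

#' Intersection of compound targets with the disease network
#'
#' Returns the gene symbols that are both compound targets (role
#' `compound_target` in the compound-target network) and members of the
#' disease PPI network (either role).
#'
#' @param compound_net Compound-target [pharm_network()].
#' @param disease_net Disease PPI [pharm_network()].
#' @return Sorted character vector (possibly empty, with a warning).
#' @export
intersect_targets <- function(compound_net, disease_net) {
  ct <- compound_net$nodes$node_id[compound_net$nodes$role == "compound_target"]
  dn <- disease_net$nodes$node_id
  out <- sort(intersect(ct, dn))
  if (length(out) == 0L)
    warning("empty intersection between compound targets and the disease network")
  out
}

#' Build the merged compound-intersection-target network
#'
#' Connects (i) compounds that target at least one intersection gene,
#' (ii) the intersection targets themselves, and (iii) the proteins
#' within `shell` hops of an intersection target in the filtered PPI,
#' with the PPI-induced subgraph on the protein nodes. Compounds with no
#' link to an intersection target are excluded. When a symbol qualifies
#' for more than one role, `intersection_target` takes precedence over
#' `other_protein`.
#'
#' @param records Compound-target records ([load_compound_targets()]).
#' @param intersection Character vector of intersection target symbols.
#' @param ppi PPI edge data.frame ([load_ppi()]).
#' @param shell Neighbourhood radius around intersection targets
#'   (default 1).
#' @return A list with elements `network` (a [pharm_network()]) and
#'   `report` (a one-row data.frame of role/edge counts).
#' @export
build_merged_network <- function(records, intersection, ppi, shell = 1L) {
  intersection <- unique(norm_symbol(intersection))
  if (length(intersection) == 0L)
    np_validation_error("empty intersection: nothing to merge")
  if (!shell %in% c(1L, 2L)) np_usage_error("shell must be 1 or 2")

  ct_edges <- unique(records[records$target_symbol %in% intersection,
                             c("compound_id", "target_symbol"), drop = FALSE])
  if (nrow(ct_edges) == 0L)
    np_validation_error("no compound targets any intersection gene; merged network would have no compounds")
  compounds <- sort(unique(ct_edges$compound_id))

  g <- ppi_graph(ppi)
  shell_nodes <- neighborhood_nodes(g, intersection, shell)
  others <- setdiff(shell_nodes, intersection)
  prot <- union(intersection, others)

  nodes <- data.frame(
    node_id = c(compounds, intersection, others),
    role = c(rep("compound", length(compounds)),
             rep("intersection_target", length(intersection)),
             rep("other_protein", length(others))),
    stringsAsFactors = FALSE)

  pe <- induced_edges(ppi, prot)
  edges <- rbind(
    data.frame(from = ct_edges$compound_id, to = ct_edges$target_symbol,
               stringsAsFactors = FALSE),
    data.frame(from = pe$protein_a, to = pe$protein_b, stringsAsFactors = FALSE))
  net <- pharm_network(nodes, edges, name = "merged")
  list(network = net, report = merge_report(net))
}

#' Per-role node counts of a network
#'
#' @param net A [pharm_network()].
#' @return One-row data.frame with columns `n_compounds`,
#'   `n_compound_targets`, `n_seed_genes`, `n_intersection_targets`,
#'   `n_other_proteins`, `n_nodes`, `n_edges`. Role counts always sum to
#'   `n_nodes`.
#' @export
merge_report <- function(net) {
  tab <- table(factor(net$nodes$role, levels = NODE_ROLES))
  data.frame(n_compounds = as.integer(tab[["compound"]]),
             n_compound_targets = as.integer(tab[["compound_target"]]),
             n_seed_genes = as.integer(tab[["disease_seed"]]),
             n_intersection_targets = as.integer(tab[["intersection_target"]]),
             n_other_proteins = as.integer(tab[["other_protein"]]),
             n_nodes = n_nodes(net),
             n_edges = n_edges(net))
}
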