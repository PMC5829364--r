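# Topological indices used for major-node (hub) selection: degree,
# shortest-path betweenness (Brandes' accumulation), and
# component-adjusted closeness. Shortest paths are unweighted.

adjacency_index <- function(net) {
  ids <- net$nodes$node_id
  idx <- seq_along(ids)
  names(idx) <- ids
  adj <- vector("list", length(ids))
  for (i in idx) adj[[i]] <- integer(0)
  if (nrow(net$edges) > 0L) {
    f <- idx[net$edges$from]
    t <- idx[net$edges$to]
    for (k in seq_along(f)) {
      adj[[f[k]]] <- c(adj[[f[k]]], t[k])
      adj[[t[k]]] <- c(adj[[t[k]]], f[k])
    }
  }
  list(ids = ids, adj = adj)
}

#' Degree centrality
#'
#' Number of edges incident to each node.
#'
#' @param net A [pharm_network()].
#' @return Named integer vector keyed by node id.
#' @export
degree_centrality <- function(net) {
  ids <- net$nodes$node_id
  deg <- stats::setNames(integer(length(ids)), ids)
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Betweenness centrality
#'
#' Fraction of pairwise shortest paths passing through each node:
#' `sum over pairs (s,t) of sigma_st(v) / sigma_st`, where `sigma_st`
#' counts shortest paths between s and t and `sigma_st(v)` those through
#' v. Computed by breadth-first search with dependency accumulation
#' (Brandes' algorithm). Pairs in different components contribute zero.
#' Normalisation divides by `(n-1)(n-2)/2`, the number of pairs excluding
#' the node itself; with fewer than 3 nodes the normalised value is 0 by
#' convention.
#'
#' @param net A [pharm_network()].
#' @param normalized Divide by `(n-1)(n-2)/2` (default TRUE).
#' @return Named numeric vector keyed by node id.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  ai <- adjacency_index(net)
  n <- length(ai$ids)
  bc <- numeric(n)
  if (n >= 3L || !normalized) {
    for (s in seq_len(n)) {
      # BFS from s, recording path counts and predecessors
      dist <- rep.int(-1L, n)
      sigma <- numeric(n)
      preds <- vector("list", n)
      dist[s] <- 0L
      sigma[s] <- 1
      queue <- integer(n)
      queue[1] <- s
      qh <- 1L; qt <- 1L
      while (qh <= qt) {
        v <- queue[qh]; qh <- qh + 1L
        for (w in ai$adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            qt <- qt + 1L
            queue[qt] <- w
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      # accumulate dependencies in reverse BFS order (the queue itself)
      delta <- numeric(n)
      for (w in rev(queue[seq_len(qt)])) {
        for (v in preds[[w]]) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
        if (w != s) bc[w] <- bc[w] + delta[w]
      }
    }
    bc <- bc / 2 # undirected: each pair counted from both endpoints
  }
  if (normalized) {
    bc <- if (n >= 3L) bc / ((n - 1) * (n - 2) / 2) else numeric(n)
  }
  stats::setNames(bc, ai$ids)
}

bfs_distances <- function(ai, s) {
  n <- length(ai$ids)
  dist <- rep.int(-1L, n)
  dist[s] <- 0L
  queue <- integer(n)
  queue[1] <- s
  qh <- 1L; qt <- 1L
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    for (w in ai$adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        qt <- qt + 1L
        queue[qt] <- w
      }
    }
  }
  dist
}

#' Closeness centrality
#'
#' Raw closeness of node i is the inverse of the summed shortest-path
#' distance from i to the nodes it can reach. The normalised
#' (component-adjusted) form is `(|R| / sum d) * (|R| / (n - 1))`, where
#' R is the reachable set excluding i: the within-component closeness
#' scaled by the component's relative size, the standard convention for
#' disconnected graphs. Isolated nodes score 0.
#'
#' @param net A [pharm_network()].
#' @param normalized Component-adjusted normalisation (default TRUE).
#' @return Named numeric vector keyed by node id.
#' @export
closeness_centrality <- function(net, normalized = TRUE) {
  ai <- adjacency_index(net)
  n <- length(ai$ids)
  out <- numeric(n)
  for (s in seq_len(n)) {
    d <- bfs_distances(ai, s)
    reach <- which(d > 0L)
    if (length(reach) == 0L) {
      out[s] <- 0
    } else {
      tot <- sum(d[reach])
      out[s] <- if (normalized) {
        (length(reach) / tot) * (length(reach) / (n - 1))
      } else {
        1 / tot
      }
    }
  }
  stats::setNames(out, ai$ids)
}

#' Per-node centrality table with network-mean thresholds
#'
#' Computes degree, normalised betweenness, and normalised closeness for
#' every node and attaches the three network means (over all nodes) as
#' the `means` attribute; `mean_degree` equals `2|E|/|V|` exactly.
#'
#' @param net A [pharm_network()].
#' @return Data frame with columns `node_id`, `role`, `degree`,
#'   `betweenness`, `closeness`, sorted by decreasing degree then
#'   node id, with attribute `means` = named vector `mean_degree`,
#'   `mean_betweenness`, `mean_closeness`.
#' @export
centrality_table <- function(net) {
  if (n_nodes(net) == 0L) np_validation_error("empty network")
  deg <- degree_centrality(net)
  btw <- betweenness_centrality(net, normalized = TRUE)
  clo <- closeness_centrality(net, normalized = TRUE)
  tab <- data.frame(node_id = net$nodes$node_id,
                    role = net$nodes$role,
                    degree = as.integer(deg[net$nodes$node_id]),
                    betweenness = as.numeric(btw[net$nodes$node_id]),
                    closeness = as.numeric(clo[net$nodes$node_id]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, tab$node_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "means") <- c(mean_degree = mean(tab$degree),
                          mean_betweenness = mean(tab$betweenness),
                          mean_closeness = mean(tab$closeness))
  tab
}

#' Select major nodes (hubs) by the mean-threshold rule
#'
#' A node is a major node when its degree, betweenness, and closeness are
#' all at or above the corresponding network means (inclusive `>=`).
#' Means are always taken over all nodes of the network; `scope`
#' restricts which roles are eligible for selection (e.g. protein roles
#' only), not the means.
#'
#' @param table A [centrality_table()].
#' @param scope Optional character vector of eligible roles; `NULL`
#'   (default) makes every role eligible.
#' @return A list with `nodes` (ids sorted by decreasing degree, ties by
#'   id), `thresholds` (the three means), and `table` (the selected
#'   rows with an `is_major` column over the full input).
#' @export
select_major_nodes <- function(table, scope = NULL) {
  if (nrow(table) == 0L) np_validation_error("empty centrality table")
  means <- attr(table, "means")
  if (is.null(means)) np_usage_error("table lacks the 'means' attribute; use centrality_table()")
  eligible <- if (is.null(scope)) rep(TRUE, nrow(table)) else table$role %in% scope
  hit <- eligible &
    table$degree >= means[["mean_degree"]] &
    table$betweenness >= means[["mean_betweenness"]] &
    table$closeness >= means[["mean_closeness"]]
  table$is_major <- hit
  sel <- table[hit, , drop = FALSE]
  sel <- sel[order(-sel$degree, sel$node_id), , drop = FALSE]
  list(nodes = sel$node_id, thresholds = means, table = table)
}

#' Write a centrality table as TSV
#'
#' Columns `node_id`, `role`, `degree`, `betweenness`, `closeness`,
#' `is_major`; the three mean thresholds are echoed as `# mean_...`
#' header comment lines.
#'
#' @param selection Result of [select_major_nodes()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_centrality_tsv <- function(selection, path) {
  means <- selection$thresholds
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s\t%.10g", names(means), means), con)
  tab <- selection$table
  tab$betweenness <- sprintf("%.10g", tab$betweenness)
  tab$closeness <- sprintf("%.10g", tab$closeness)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
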