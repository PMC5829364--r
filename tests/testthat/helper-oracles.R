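# Test fixtures and independent oracles.
#
# The betweenness oracle counts shortest paths by matrix powers
# ((A^d)[s,t] counts s-t walks of length d, and walks of minimal length
# are exactly the shortest paths), an entirely different route from the
# package's BFS + dependency accumulation.

toy_net <- function(pairs, extra_nodes = character(0), role = "other_protein") {
  # pairs: even-length character vector c(a1,b1, a2,b2, ...)
  m <- matrix(pairs, ncol = 2, byrow = TRUE)
  ids <- sort(unique(c(as.character(m), extra_nodes)))
  pharm_network(
    nodes = data.frame(node_id = ids, role = role, stringsAsFactors = FALSE),
    edges = data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE))
}

net_from_adjacency <- function(adj, ids = NULL) {
  n <- nrow(adj)
  if (is.null(ids)) ids <- sprintf("N%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- if (nrow(idx) == 0) NULL else
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]], stringsAsFactors = FALSE)
  pharm_network(
    nodes = data.frame(node_id = ids, role = "other_protein",
                       stringsAsFactors = FALSE),
    edges = edges)
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(stats::runif(length(up)) < p)
  adj + t(adj)
}

# all labelled simple graphs on n nodes (n small)
all_adjacencies <- function(n) {
  up <- which(upper.tri(matrix(0, n, n)))
  m <- length(up)
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    adj <- matrix(0L, n, n)
    adj[up] <- bits
    adj + t(adj)
  })
}

oracle_betweenness <- function(adj, normalized = TRUE) {
  n <- nrow(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  D <- igraph::distances(g)
  maxd <- suppressWarnings(max(D[is.finite(D) & D > 0], 0))
  pows <- vector("list", max(maxd, 1))
  cur <- diag(n)
  for (d in seq_len(max(maxd, 1))) {
    cur <- cur %*% adj
    pows[[d]] <- cur
  }
  sigma <- function(s, t) pows[[D[s, t]]][s, t]
  bc <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || D[s, t] == 0) next
      st <- sigma(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) && D[s, v] > 0 &&
            D[v, t] > 0 && D[s, v] + D[v, t] == D[s, t]) {
          bc[v] <- bc[v] + sigma(s, v) * sigma(v, t) / st
        }
      }
    }
  }
  if (normalized) bc <- if (n >= 3) bc / ((n - 1) * (n - 2) / 2) else numeric(n)
  bc
}

oracle_closeness <- function(adj, normalized = TRUE) {
  n <- nrow(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  D <- igraph::distances(g)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) return(0)
    if (normalized) (length(d) / sum(d)) * (length(d) / (n - 1)) else 1 / sum(d)
  }, numeric(1))
}

# combinatorial upper-tail oracle: explicit term summation via lchoose
oracle_hyper_tail <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(K, n)
  terms <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(terms[ks >= k])
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

small_cfg <- function(seed = 1, ...) {
  pharm_sim_config(rng_seed = seed, ...)
}
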