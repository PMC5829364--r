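#' Export a network in Cytoscape-readable formats
#'
#' Writes a [pharm_network()] as SIF (`source <tab> label <tab> target`),
#' GraphML (with the node role as a vertex attribute), or a node-attribute
#' TSV (`node_id`, `role`). Edge lines use the interaction label `ct` when
#' one endpoint is a compound and `pp` otherwise; for `ct` edges the
#' compound is written as the source. Node and edge ordering is
#' lexicographic, so exports of identical networks are byte-identical.
#' Isolated nodes appear in SIF as single-field lines, the usual
#' Cytoscape convention.
#'
#' @param net A [pharm_network()].
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "pharm_network"))
  if (length(format) != 1L || !format %in% c("sif", "graphml", "tsv"))
    np_usage_error("format must be one of 'sif', 'graphml', 'tsv'")
  switch(format,
    sif = write_sif(net, path),
    graphml = write_graphml(net, path),
    tsv = {
      utils::write.table(net$nodes, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      invisible(path)
    })
}

write_sif <- function(net, path) {
  roles <- node_roles(net)
  lines <- character(0)
  if (nrow(net$edges) > 0L) {
    from <- net$edges$from
    to <- net$edges$to
    label <- ifelse(roles[from] == "compound" | roles[to] == "compound", "ct", "pp")
    # compound as source on ct edges
    swap <- label == "ct" & roles[to] == "compound"
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    lines <- paste(from, label, to, sep = "\t")
    lines <- sort(lines)
  }
  touched <- unique(c(net$edges$from, net$edges$to))
  isolated <- sort(setdiff(net$nodes$node_id, touched))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a GraphML file written by [export_network()]
#'
#' Round-trips node ids, edges, and role attributes.
#'
#' @param path GraphML file path.
#' @param name Name for the resulting network.
#' @return A [pharm_network()].
#' @export
import_graphml <- function(path, name = "") {
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(igraph::vertex_attr(g, "role")))
    np_format_error("GraphML file lacks the 'role' node attribute")
  from_igraph(g, name = name)
}
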