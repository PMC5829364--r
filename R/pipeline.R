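# End-to-end orchestration: simulate (or load) inputs, build the three
# networks, rank nodes, select hubs, run enrichment, and write all
# artifacts plus a run manifest.

#' Write a run manifest
#'
#' Human-readable structured summary of a pipeline run: tool version,
#' configuration echo, input digests, per-stage counts, thresholds, and
#' a timestamp. Every count recorded here is taken from the produced
#' artifact itself.
#'
#' @param path Output file path.
#' @param sections Named list of named vectors/lists; one manifest block
#'   per element.
#' @return Invisibly, `path`.
#' @export
write_run_manifest <- function(path, sections) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("netpharm manifest v%s",
                     as.character(utils::packageVersion("netpharm"))), con)
  writeLines(sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), con)
  for (nm in names(sections)) {
    writeLines(paste0("[", nm, "]"), con)
    sec <- sections[[nm]]
    for (k in names(sec)) {
      v <- sec[[k]]
      writeLines(sprintf("%s: %s", k,
                         paste(format(v, trim = TRUE, scientific = FALSE),
                               collapse = ", ")), con)
    }
  }
  invisible(path)
}

read_manifest_digests <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- which(lines == "[digests]")
  if (length(start) == 0L) return(character(0))
  block <- lines[(start + 1L):length(lines)]
  stop_at <- which(grepl("^\\[", block))
  if (length(stop_at) > 0L) block <- block[seq_len(stop_at[1] - 1L)]
  block
}

#' Run the full network-pharmacology pipeline on a simulated study
#'
#' Generates the merged-network study fixture for `seed`, writes the
#' input tables, reloads them through the filtered loaders (top-`top_k`
#' targets, gene-disease score > `gda_min`, PPI combined score >
#' `ppi_min`), builds the compound-target, disease-PPI, and merged
#' networks, computes centralities and selects major nodes among the
#' protein roles of the merged network, runs overrepresentation analysis
#' of the major nodes against a generated annotation database, and
#' writes all artifacts plus a manifest under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving all randomness.
#' @param top_k,gda_min,ppi_min,shell,fdr_cutoff Pipeline parameters
#'   (defaults 30, 0.1, 0.7, 1, 0.01).
#' @param formats Network export formats (subset of `sif`, `graphml`,
#'   `tsv`).
#' @param config Optional [pharm_sim_config()]; its `rng_seed` is
#'   overridden by `seed`.
#' @param quiet Suppress progress logging.
#' @return Invisibly, a list with the networks, centrality selection,
#'   enrichment table, category tally, report, and artifact paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L, top_k = 30L, gda_min = 0.1,
                         ppi_min = 0.7, shell = 1L, fdr_cutoff = 0.01,
                         formats = c("sif", "tsv"), config = NULL,
                         quiet = FALSE) {
  old_quiet <- getOption("netpharm.quiet")
  options(netpharm.quiet = quiet)
  on.exit(options(netpharm.quiet = old_quiet))

  if (is.null(config)) config <- pharm_sim_config(rng_seed = seed)
  else config$rng_seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")

  np_log("simulating study fixture (seed ", seed, ")")
  fixture <- gen_merged_fixture(config)
  in_paths <- write_fixture_dir(fixture, in_dir)

  records <- load_compound_targets(in_paths[["compound_targets"]], top_k = top_k)
  disease <- load_disease_genes(in_paths[["disease_genes"]], min_score = gda_min)
  ppi <- load_ppi(in_paths[["ppi"]], min_combined_score = ppi_min)
  np_log(nrow(records), " compound-target records, ", nrow(disease),
         " disease genes, ", nrow(ppi), " PPI edges after filtering")

  ct_net <- build_compound_target_network(records)
  dis_net <- build_disease_ppi_network(disease$gene_symbol, ppi, shell = shell)
  intersection <- intersect_targets(ct_net, dis_net)
  merged <- build_merged_network(records, intersection, ppi, shell = shell)
  np_log("networks: compound-target ", n_nodes(ct_net), " nodes, disease ",
         n_nodes(dis_net), " nodes, merged ", n_nodes(merged$network),
         " nodes / ", n_edges(merged$network), " edges")

  tab <- centrality_table(merged$network)
  selection <- select_major_nodes(tab, scope = c("intersection_target",
                                                 "other_protein"))
  np_log(length(selection$nodes), " major nodes selected")

  ann <- gen_annotation_db(config, query = selection$nodes)
  write_annotation_gmt(ann$db, file.path(in_dir, "annotation.gmt"))
  enrichment <- run_enrichment(selection$nodes, ann$db, fdr_cutoff = fdr_cutoff)
  categories <- categorize_enrichment(enrichment)
  np_log(sum(enrichment$enriched), " enriched terms at FDR < ", fdr_cutoff)

  paths <- character(0)
  nets <- list(compound_target = ct_net, disease_ppi = dis_net,
               merged = merged$network)
  for (nm in names(nets)) {
    for (fmt in formats) {
      ext <- c(sif = "sif", graphml = "graphml", tsv = "nodes.tsv")[[fmt]]
      p <- file.path(out_dir, paste0(nm, ".", ext))
      export_network(nets[[nm]], p, format = fmt)
      paths <- c(paths, p)
    }
  }
  p <- file.path(out_dir, "centrality.tsv")
  write_centrality_tsv(selection, p); paths <- c(paths, p)
  p <- file.path(out_dir, "major_nodes.tsv")
  utils::write.table(
    data.frame(node_id = selection$nodes, stringsAsFactors = FALSE),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "enrichment.tsv")
  write_enrichment_tsv(enrichment, p); paths <- c(paths, p)
  p <- file.path(out_dir, "categories.tsv")
  utils::write.table(
    data.frame(category = names(categories), n_terms = as.integer(categories),
               stringsAsFactors = FALSE),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "merge_report.tsv")
  utils::write.table(merged$report, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)

  all_files <- c(in_paths, file.path(in_dir, "annotation.gmt"), paths)
  digests <- tools::md5sum(all_files)
  names(digests) <- basename(all_files)
  manifest_path <- file.path(out_dir, "manifest.txt")
  write_run_manifest(manifest_path, list(
    config = list(seed = seed, top_k = top_k, gda_min = gda_min,
                  ppi_min = ppi_min, shell = shell, fdr_cutoff = fdr_cutoff),
    counts = list(
      compound_target_records = nrow(records),
      disease_genes = nrow(disease),
      ppi_edges = nrow(ppi),
      compound_target_network_nodes = n_nodes(ct_net),
      compound_target_network_edges = n_edges(ct_net),
      disease_network_nodes = n_nodes(dis_net),
      disease_network_edges = n_edges(dis_net),
      intersection_targets = length(intersection),
      merged_network_nodes = n_nodes(merged$network),
      merged_network_edges = n_edges(merged$network),
      major_nodes = length(selection$nodes),
      enriched_terms = sum(enrichment$enriched)),
    thresholds = as.list(selection$thresholds),
    digests = as.list(digests)))

  invisible(list(networks = nets, intersection = intersection,
                 selection = selection, enrichment = enrichment,
                 categories = categories, report = merged$report,
                 fixture = fixture, paths = c(all_files, manifest_path),
                 manifest = manifest_path))
}
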