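# Seeded generators producing inputs with the structural shape a
# multi-compound network-pharmacology study assumes: a compound-target
# table with shared-target bias, a seed-anchored PPI with a known first
# shell, an annotation database with planted enriched terms, and a
# merged-network preset with planted hubs. All randomness flows from
# one config seed; the caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  code
}

sub_seed <- function(seed, offset) as.integer((as.numeric(seed) + offset) %% 2147483647)

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, max(2L, nchar(n)), seq_len(n))

#' Synthetic-study generator configuration
#'
#' Bundles the sizes and rates of the synthetic study. The defaults are
#' the composition a typical herbal network-pharmacology study reports:
#' 43 compounds each keeping their top 30 predicted targets from a pool
#' of 266 distinct targets, 14 disease seed genes whose high-confidence
#' PPI first shell holds 96 further proteins, and an annotation universe
#' with a handful of planted enriched terms whose category labels follow
#' the 19:10:6:4 proportions of the four top-level pathway categories.
#'
#' @param n_compounds Number of compounds (default 43).
#' @param top_k Targets retained per compound (default 30).
#' @param n_target_pool Distinct targets overall (default 266).
#' @param n_seeds Disease seed genes (default 14).
#' @param n_first_shell Non-seed proteins in the PPI first shell
#'   (default 96).
#' @param ppi_extra_density Probability of an extra high-confidence edge
#'   between any included protein pair beyond the guaranteed seed-anchored
#'   edges (default 0.055, giving an edge count of the order the study
#'   shape implies).
#' @param n_decoys Low-confidence decoy edges added to exercise the
#'   score filter (default 40).
#' @param n_terms Annotation terms (default 100).
#' @param planted_term_count Terms constructed to overlap the query
#'   (default 5).
#' @param planted_overlap_fraction Fraction of the query planted into
#'   each enriched term (default 0.8).
#' @param n_background Background genes beyond the query (default 1500).
#' @param category_weights Named weights for term category labels.
#' @param rng_seed Integer seed; all generator randomness derives from
#'   it (default 1).
#' @return A validated list of class `pharm_sim_config`.
#' @export
pharm_sim_config <- function(n_compounds = 43L, top_k = 30L,
                             n_target_pool = 266L, n_seeds = 14L,
                             n_first_shell = 96L, ppi_extra_density = 0.055,
                             n_decoys = 40L, n_terms = 100L,
                             planted_term_count = 5L,
                             planted_overlap_fraction = 0.8,
                             n_background = 1500L,
                             category_weights = c(
                               "human diseases" = 19,
                               "organismal systems" = 10,
                               "environmental information processing" = 6,
                               "cellular processes" = 4),
                             rng_seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds), top_k = as.integer(top_k),
              n_target_pool = as.integer(n_target_pool),
              n_seeds = as.integer(n_seeds),
              n_first_shell = as.integer(n_first_shell),
              ppi_extra_density = ppi_extra_density,
              n_decoys = as.integer(n_decoys), n_terms = as.integer(n_terms),
              planted_term_count = as.integer(planted_term_count),
              planted_overlap_fraction = planted_overlap_fraction,
              n_background = as.integer(n_background),
              category_weights = category_weights,
              rng_seed = as.integer(rng_seed))
  counts <- c(cfg$n_compounds, cfg$top_k, cfg$n_target_pool, cfg$n_seeds,
              cfg$n_terms, cfg$n_background)
  if (any(counts < 1L)) np_usage_error("all config counts must be positive")
  if (cfg$n_first_shell < 0L || cfg$n_decoys < 0L)
    np_usage_error("n_first_shell and n_decoys must be non-negative")
  if (cfg$top_k > cfg$n_target_pool)
    np_usage_error("top_k cannot exceed n_target_pool")
  if (cfg$n_target_pool > cfg$n_compounds * cfg$top_k)
    np_usage_error("target pool too large to be covered by n_compounds * top_k slots")
  if (cfg$planted_term_count > cfg$n_terms)
    np_usage_error("planted_term_count cannot exceed n_terms")
  if (cfg$planted_overlap_fraction <= 0 || cfg$planted_overlap_fraction > 1)
    np_usage_error("planted_overlap_fraction must be in (0, 1]")
  if (cfg$ppi_extra_density < 0)
    np_usage_error("ppi_extra_density must be >= 0")
  if (cfg$n_first_shell == 0L && cfg$ppi_extra_density > 0)
    np_usage_error("ppi_extra_density > 0 requires a non-empty first shell")
  structure(cfg, class = "pharm_sim_config")
}

# deal `pool` round-robin into per-compound target lists capped at top_k,
# then fill every compound to top_k by preferential (rich-get-richer)
# sampling so some targets are hit by many compounds
assign_targets <- function(compounds, pool, top_k) {
  hits <- stats::setNames(numeric(length(pool)), pool)
  assigned <- stats::setNames(vector("list", length(compounds)), compounds)
  shuffled <- sample(pool)
  ci <- 1L
  for (tg in shuffled) {
    tries <- 0L
    while (length(assigned[[ci]]) >= top_k && tries < length(compounds)) {
      ci <- if (ci == length(compounds)) 1L else ci + 1L
      tries <- tries + 1L
    }
    assigned[[ci]] <- c(assigned[[ci]], tg)
    hits[tg] <- hits[tg] + 1
    ci <- if (ci == length(compounds)) 1L else ci + 1L
  }
  for (cmp in compounds) {
    need <- top_k - length(assigned[[cmp]])
    if (need > 0L) {
      avail <- setdiff(pool, assigned[[cmp]])
      w <- 1 + hits[avail]
      extra <- sample(avail, min(need, length(avail)), prob = w)
      assigned[[cmp]] <- c(assigned[[cmp]], extra)
      hits[extra] <- hits[extra] + 1
    }
  }
  assigned
}

records_from_assignment <- function(assigned) {
  rows <- lapply(names(assigned), function(cmp) {
    tg <- sample(assigned[[cmp]]) # shuffle -> rank order
    k <- length(tg)
    data.frame(compound_id = cmp,
               compound_name = paste("compound", sub("^CMP0*", "", cmp)),
               target_symbol = tg,
               rank = seq_len(k),
               fit_score = round(9 - 0.15 * seq_len(k) + stats::runif(k), 3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic compound-target prediction table
#'
#' Produces `n_compounds` compounds, each with `top_k` ranked targets
#' drawn from a pool of `n_target_pool` symbols. Every pool target is
#' hit at least once (so the built bipartite network has
#' `n_compounds + n_target_pool` nodes) and the remaining slots are
#' filled with a rich-get-richer bias so that some targets are hit by
#' many compounds, as real pharmacophore predictions show.
#'
#' @param cfg A [pharm_sim_config()].
#' @return Data frame in the [load_compound_targets()] layout.
#' @export
gen_compound_target_table <- function(cfg) {
  stopifnot(inherits(cfg, "pharm_sim_config"))
  with_seed(sub_seed(cfg$rng_seed, 101), {
    compounds <- pad_ids("CMP", cfg$n_compounds)
    pool <- pad_ids("TGT", cfg$n_target_pool)
    records_from_assignment(assign_targets(compounds, pool, cfg$top_k))
  })
}

#' Generate a synthetic confidence-scored PPI
#'
#' Builds `n_seeds` seed genes joined by a high-confidence backbone path
#' (so seeds plus first shell form one connected network), wires each of
#' `n_first_shell` distinct non-seed proteins to at least one seed with
#' a combined score above 0.7, adds extra high-confidence edges between
#' included protein pairs with probability `ppi_extra_density`, and
#' finally adds `n_decoys` decoy edges with scores at or below 0.7
#' (some touching external proteins) that the confidence filter must
#' remove. After filtering at the default cutoff the seed-anchored
#' shell-1 network therefore has exactly `n_seeds + n_first_shell`
#' nodes.
#'
#' @param cfg A [pharm_sim_config()].
#' @return List with `edges` (raw edge data.frame in the [load_ppi()]
#'   layout, decoys included) and `seeds` (seed gene symbols).
#' @export
gen_ppi <- function(cfg) {
  stopifnot(inherits(cfg, "pharm_sim_config"))
  with_seed(sub_seed(cfg$rng_seed, 202), {
    seeds <- pad_ids("SEED", cfg$n_seeds)
    shell <- if (cfg$n_first_shell > 0L) pad_ids("PRT", cfg$n_first_shell) else character(0)
    nodes <- c(seeds, shell)

    from <- character(0); to <- character(0)
    if (length(seeds) > 1L) { # backbone path over seeds
      from <- seeds[-length(seeds)]
      to <- seeds[-1]
    }
    if (length(shell) > 0L) { # each shell protein anchored to a seed
      anchor <- sample(seeds, length(shell), replace = TRUE)
      from <- c(from, anchor)
      to <- c(to, shell)
    }
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    seen <- key(from, to)
    if (cfg$ppi_extra_density > 0 && length(nodes) > 1L) {
      pairs <- utils::combn(nodes, 2L)
      pk <- key(pairs[1, ], pairs[2, ])
      cand <- !(pk %in% seen)
      take <- cand & stats::runif(ncol(pairs)) < cfg$ppi_extra_density
      from <- c(from, pairs[1, take])
      to <- c(to, pairs[2, take])
    }
    score <- stats::runif(length(from), 0.701, 0.999)

    seen <- key(from, to)
    if (cfg$n_decoys > 0L) {
      ext <- pad_ids("EXT", max(4L, ceiling(cfg$n_decoys / 4)))
      da <- sample(c(nodes, ext), cfg$n_decoys, replace = TRUE)
      db_ <- sample(c(nodes, ext), cfg$n_decoys, replace = TRUE)
      ok <- da != db_ & !(key(da, db_) %in% seen)
      from <- c(from, da[ok]); to <- c(to, db_[ok])
      score <- c(score, stats::runif(sum(ok), 0.1, 0.699))
    }
    edges <- data.frame(protein_a = from, protein_b = to,
                        combined_score = round(score, 4),
                        stringsAsFactors = FALSE)
    list(edges = edges, seeds = seeds)
  })
}

proportional_counts <- function(weights, total) {
  exact <- weights / sum(weights) * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Generate a synthetic annotation database with planted enrichment
#'
#' Constructs `n_terms` gene-set terms over a background of the query
#' plus `n_background` filler genes. `planted_term_count` terms are true
#' positives containing `planted_overlap_fraction` of the query; the
#' rest are sampled from the background independently of the query.
#' Category labels are assigned in the `category_weights` proportions
#' (largest-remainder rounding), then shuffled across terms.
#'
#' @param cfg A [pharm_sim_config()].
#' @param query Character vector of query gene symbols (non-empty).
#' @return List with `db` (an [annotation_db()]) and `planted`
#'   (character vector of ground-truth enriched term ids).
#' @export
gen_annotation_db <- function(cfg, query) {
  stopifnot(inherits(cfg, "pharm_sim_config"))
  query <- unique(norm_symbol(query))
  query <- query[nzchar(query)]
  if (length(query) == 0L) np_usage_error("query must be non-empty")
  if (cfg$planted_term_count > 0L &&
      cfg$planted_overlap_fraction * length(query) < 1)
    np_usage_error("planted_overlap_fraction times query size is below one gene")
  n_hit <- ceiling(cfg$planted_overlap_fraction * length(query))
  with_seed(sub_seed(cfg$rng_seed, 303), {
    fillers <- pad_ids("GENE", cfg$n_background)
    background <- sort(unique(c(query, fillers)))
    ids <- pad_ids("TERM", cfg$n_terms)
    cats <- sample(rep(names(cfg$category_weights),
                       proportional_counts(cfg$category_weights, cfg$n_terms)))
    planted <- if (cfg$planted_term_count > 0L) ids[seq_len(cfg$planted_term_count)] else character(0)
    terms <- vector("list", cfg$n_terms)
    names(terms) <- ids
    for (i in seq_len(cfg$n_terms)) {
      if (ids[i] %in% planted) {
        hit <- sample(query, n_hit)
        fill <- sample(setdiff(fillers, hit), sample(20:50, 1))
        genes <- c(hit, fill)
      } else {
        genes <- sample(background, sample(15:100, 1))
      }
      terms[[i]] <- list(name = paste("synthetic term", i),
                         category = cats[i], genes = sort(unique(genes)))
    }
    list(db = annotation_db(terms, background), planted = planted)
  })
}

#' Generate the merged-network study fixture
#'
#' A convenience preset producing a fully consistent input set whose
#' pipeline run reproduces the classic composition of a compound /
#' intersection-target / first-shell merged network: by construction the
#' compound-target network has `n_compounds + n_target_pool` nodes, the
#' seed-anchored disease network has `n_seeds + n_first_shell` nodes,
#' the compound-target / disease-network intersection has
#' `n_intersection` members, and the merged network has exactly
#' `n_qualifying + n_intersection + n_merged_others` nodes and
#' `n_merged_edges` edges. `n_hubs` intersection targets receive a
#' disproportionate share of compound and PPI edges and are returned as
#' ground-truth planted hubs for recovery tests.
#'
#' @param cfg A [pharm_sim_config()].
#' @param n_intersection Intersection targets (default 17).
#' @param n_qualifying Compounds linked to the intersection (default 14).
#' @param n_merged_others First-shell proteins around the intersection
#'   (default 53).
#' @param n_merged_edges Total merged-network edges (default 306).
#' @param n_ct_edges Compound-to-intersection edges within the merged
#'   total (default 40).
#' @param n_hubs Planted high-degree intersection targets (default 5).
#' @return List with `compound_targets`, `disease_genes`, `ppi` (raw
#'   tables in the loader layouts), `seeds`, `intersection` (ground
#'   truth), `planted_hubs`, and `expected` (named list of the
#'   compositions the pipeline should recover).
#' @export
gen_merged_fixture <- function(cfg, n_intersection = 17L, n_qualifying = 14L,
                               n_merged_others = 53L, n_merged_edges = 306L,
                               n_ct_edges = 40L, n_hubs = 5L) {
  stopifnot(inherits(cfg, "pharm_sim_config"))
  n_seed_I <- min(n_hubs, cfg$n_seeds - 1L)
  n_prot_I <- n_intersection - n_seed_I
  n_A_seeds <- cfg$n_seeds - n_seed_I
  n_A_prots <- n_merged_others - n_A_seeds
  n_outer_prots <- cfg$n_first_shell - n_prot_I - n_A_prots
  if (n_prot_I < 0L || n_A_prots < 0L || n_outer_prots < 0L)
    np_usage_error("incompatible merged-fixture composition for this config")
  if (n_ct_edges < max(n_intersection, n_qualifying))
    np_usage_error("n_ct_edges must cover every intersection target and every qualifying compound")
  if (n_qualifying > cfg$n_compounds)
    np_usage_error("n_qualifying cannot exceed n_compounds")

  with_seed(sub_seed(cfg$rng_seed, 404), {
    seeds <- pad_ids("SEED", cfg$n_seeds)
    shell <- pad_ids("PRT", cfg$n_first_shell)
    hub_seeds <- seeds[seq_len(n_seed_I)]          # planted hubs
    I_prots <- shell[seq_len(n_prot_I)]
    I <- c(hub_seeds, I_prots)                     # intersection targets
    A_seeds <- seeds[-seq_len(n_seed_I)]
    A_prots <- shell[n_prot_I + seq_len(n_A_prots)]
    A <- c(A_seeds, A_prots)                       # merged "other proteins"
    outer <- shell[n_prot_I + n_A_prots + seq_len(n_outer_prots)]

    from <- character(0); to <- character(0)
    add <- function(a, b) { from <<- c(from, a); to <<- c(to, b) }
    if (length(hub_seeds) > 1L)                    # backbone among hub seeds
      add(hub_seeds[-length(hub_seeds)], hub_seeds[-1])
    add(sample(hub_seeds, length(I_prots), replace = TRUE), I_prots)
    add(sample(hub_seeds, length(A_prots), replace = TRUE), A_prots)
    add(sample(I, length(A_seeds), replace = TRUE), A_seeds)
    if (length(outer) > 0L)
      add(sample(A_seeds, length(outer), replace = TRUE), outer)

    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    seen <- key(from, to)
    n_base_IA <- sum(from %in% c(I, A) & to %in% c(I, A))
    n_extra_IA <- n_merged_edges - n_ct_edges - n_base_IA
    if (n_extra_IA < 0L)
      np_usage_error("n_merged_edges too small for the base wiring")

    # hub-biased extra induced edges among intersection + first-shell others
    IA <- c(I, A)
    w <- ifelse(IA %in% hub_seeds, 8, 1)
    added <- 0L
    while (added < n_extra_IA) {
      a <- sample(IA, 1L, prob = w)
      b <- sample(IA, 1L, prob = w)
      if (a == b) next
      k <- key(a, b)
      if (k %in% seen) next
      add(a, b); seen <- c(seen, k); added <- added + 1L
    }

    # realism edges outside the merged neighbourhood (never touch I)
    n_outer_edges <- min(120L, max(0L, n_outer_prots * 3L))
    pool_y <- c(outer, A)
    added <- 0L; guard <- 0L
    while (added < n_outer_edges && guard < 10000L && length(outer) > 0L) {
      guard <- guard + 1L
      a <- sample(outer, 1L)
      b <- sample(pool_y, 1L)
      if (a == b) next
      k <- key(a, b)
      if (k %in% seen) next
      add(a, b); seen <- c(seen, k); added <- added + 1L
    }
    score <- round(stats::runif(length(from), 0.701, 0.999), 4)

    # low-confidence decoys, partly on external proteins
    if (cfg$n_decoys > 0L) {
      ext <- pad_ids("EXT", 10L)
      da <- sample(c(seeds, shell, ext), cfg$n_decoys, replace = TRUE)
      db_ <- sample(c(seeds, shell, ext), cfg$n_decoys, replace = TRUE)
      ok <- da != db_ & !(key(da, db_) %in% seen)
      from <- c(from, da[ok]); to <- c(to, db_[ok])
      score <- c(score, round(stats::runif(sum(ok), 0.1, 0.699), 4))
    }
    ppi <- data.frame(protein_a = from, protein_b = to,
                      combined_score = score, stringsAsFactors = FALSE)

    disease_genes <- data.frame(
      gene_symbol = c(seeds, "BOUND01", pad_ids("LOWGDA", 5L)),
      gda_score = c(round(stats::runif(length(seeds), 0.15, 0.95), 3),
                    0.1, round(stats::runif(5L, 0.01, 0.09), 3)),
      stringsAsFactors = FALSE)

    # compound-target table: qualifying compounds carry the intersection
    compounds <- pad_ids("CMP", cfg$n_compounds)
    qual <- compounds[seq_len(n_qualifying)]
    planted_ct <- data.frame(
      compound_id = rep_len(qual, n_intersection),
      target_symbol = I, stringsAsFactors = FALSE)
    ctkey <- paste(planted_ct$compound_id, planted_ct$target_symbol)
    wI <- ifelse(I %in% hub_seeds, 8, 1)
    added <- 0L
    while (added < n_ct_edges - n_intersection) {
      a <- sample(qual, 1L)
      b <- sample(I, 1L, prob = wI)
      k <- paste(a, b)
      if (k %in% ctkey) next
      planted_ct <- rbind(planted_ct,
                          data.frame(compound_id = a, target_symbol = b,
                                     stringsAsFactors = FALSE))
      ctkey <- c(ctkey, k); added <- added + 1L
    }

    others_pool <- pad_ids("TGT", cfg$n_target_pool - n_intersection)
    assigned <- stats::setNames(vector("list", length(compounds)), compounds)
    for (i in seq_len(nrow(planted_ct)))
      assigned[[planted_ct$compound_id[i]]] <-
        c(assigned[[planted_ct$compound_id[i]]], planted_ct$target_symbol[i])
    # deal the remaining pool for coverage, then preferential fill
    hits <- stats::setNames(numeric(length(others_pool)), others_pool)
    ci <- 1L
    for (tg in sample(others_pool)) {
      tries <- 0L
      while (length(assigned[[ci]]) >= cfg$top_k && tries <= length(compounds)) {
        ci <- if (ci == length(compounds)) 1L else ci + 1L
        tries <- tries + 1L
      }
      assigned[[ci]] <- c(assigned[[ci]], tg)
      hits[tg] <- hits[tg] + 1
      ci <- if (ci == length(compounds)) 1L else ci + 1L
    }
    for (cmp in compounds) {
      need <- cfg$top_k - length(assigned[[cmp]])
      if (need > 0L) {
        avail <- setdiff(others_pool, assigned[[cmp]])
        extra <- sample(avail, min(need, length(avail)), prob = 1 + hits[avail])
        assigned[[cmp]] <- c(assigned[[cmp]], extra)
        hits[extra] <- hits[extra] + 1
      }
    }
    compound_targets <- records_from_assignment(assigned)
    # beyond-cutoff rows that the top-k loader filter must drop
    extra_rows <- do.call(rbind, lapply(compounds[1:5], function(cmp) {
      tg <- sample(setdiff(others_pool, assigned[[cmp]]), 3L)
      data.frame(compound_id = cmp,
                 compound_name = paste("compound", sub("^CMP0*", "", cmp)),
                 target_symbol = tg, rank = cfg$top_k + 1:3,
                 fit_score = round(stats::runif(3L, 0.5, 3), 3),
                 stringsAsFactors = FALSE)
    }))
    compound_targets <- rbind(compound_targets, extra_rows)
    compound_targets <- compound_targets[order(compound_targets$compound_id,
                                               compound_targets$rank), ]
    rownames(compound_targets) <- NULL

    list(compound_targets = compound_targets,
         disease_genes = disease_genes,
         ppi = ppi,
         seeds = seeds,
         intersection = sort(I),
         planted_hubs = sort(hub_seeds),
         expected = list(
           ct_nodes = cfg$n_compounds + cfg$n_target_pool,
           disease_nodes = cfg$n_seeds + cfg$n_first_shell,
           merged_nodes = n_qualifying + n_intersection + n_merged_others,
           merged_edges = n_merged_edges,
           n_qualifying = n_qualifying,
           n_intersection = n_intersection,
           n_merged_others = n_merged_others))
  })
}

#' Materialise a fixture directory of loader-ready input files
#'
#' Writes `compound_targets.tsv`, `disease_genes.tsv`, `ppi_edges.tsv`
#' (and `annotation.gmt` when an annotation database is supplied) in the
#' exact dialects the loaders read.
#'
#' @param fixture Result of [gen_merged_fixture()] (or a compatible
#'   list).
#' @param dir Output directory (created if needed).
#' @param db Optional [annotation_db()] to write alongside.
#' @return Named character vector of the written paths.
#' @export
write_fixture_dir <- function(fixture, dir, db = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    compound_targets = file.path(dir, "compound_targets.tsv"),
    disease_genes = file.path(dir, "disease_genes.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"))
  write_compound_targets(fixture$compound_targets, paths[["compound_targets"]])
  write_disease_genes(fixture$disease_genes, paths[["disease_genes"]])
  write_ppi(fixture$ppi, paths[["ppi"]])
  if (!is.null(db)) {
    paths <- c(paths, annotation = file.path(dir, "annotation.gmt"))
    write_annotation_gmt(db, paths[["annotation"]])
  }
  paths
}
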