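#' PPI confidence bands
#'
#' Named score boundaries of the conventional STRING-style confidence bands
#' for protein-protein interaction combined scores: low confidence below
#' 0.4, medium confidence from 0.4 to 0.7, and high confidence strictly
#' above 0.7. The default loader cutoff keeps high-confidence edges only.
#'
#' @return Named numeric vector with elements `low_max` (0.4) and
#'   `medium_max` (0.7).
#' @export
#' @examples
#' ppi_confidence_bands()
ppi_confidence_bands <- function() {
  c(low_max = 0.4, medium_max = 0.7)
}

read_tsv_table <- function(path, required, optional = character()) {
  if (!file.exists(path)) np_usage_error(sprintf("input file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    np_format_error(sprintf("%s: missing required column(s): %s",
                            basename(path), paste(missing, collapse = ", ")))
  }
  df[, c(required, intersect(optional, names(df))), drop = FALSE]
}

norm_symbol <- function(x) toupper(trimws(x))

#' Load compound-target prediction records
#'
#' Reads a tab-separated table of predicted compound-to-target links, as
#' produced by pharmacophore-mapping target prediction: one row per
#' (compound, target) pair with the per-compound prediction rank (1 = best).
#' Only the top `top_k` ranked targets of each compound are retained, the
#' standard pre-filter for such predictions. Target symbols are uppercased;
#' exact duplicate (compound, target) pairs collapse to the best (lowest)
#' rank.
#'
#' @param path Path to a TSV file with header columns `compound_id`,
#'   `compound_name`, `target_symbol`, `rank`, and optionally `fit_score`.
#' @param top_k Maximum per-compound rank to retain (default 30).
#' @return A data.frame with columns `compound_id`, `compound_name`,
#'   `target_symbol`, `rank` (integer), and `fit_score` (numeric or `NA`).
#' @export
load_compound_targets <- function(path, top_k = 30L) {
  if (!is.numeric(top_k) || length(top_k) != 1L || is.na(top_k) || top_k < 1)
    np_usage_error("top_k must be a single integer >= 1")
  top_k <- as.integer(top_k)
  df <- read_tsv_table(path, c("compound_id", "compound_name", "target_symbol", "rank"),
                       optional = "fit_score")
  if (nrow(df) == 0L) {
    return(data.frame(compound_id = character(), compound_name = character(),
                      target_symbol = character(), rank = integer(),
                      fit_score = numeric(), stringsAsFactors = FALSE))
  }
  rank_num <- suppressWarnings(as.numeric(df$rank))
  bad <- which(is.na(rank_num) | rank_num != floor(rank_num) | rank_num < 1)
  if (length(bad) > 0L) {
    # +1 for the header line so the reported number matches the file
    np_format_error(sprintf("non-integer or invalid rank at line %d: '%s'",
                            bad[1] + 1L, df$rank[bad[1]]))
  }
  df$rank <- as.integer(rank_num)
  df$target_symbol <- norm_symbol(df$target_symbol)
  if (any(df$target_symbol == ""))
    np_validation_error("empty target_symbol encountered")
  if ("fit_score" %in% names(df)) {
    fs <- suppressWarnings(as.numeric(df$fit_score))
    if (any(!is.na(fs) & fs < 0)) np_validation_error("fit_score must be >= 0")
    df$fit_score <- fs
  } else {
    df$fit_score <- NA_real_
  }

  dup_rank <- duplicated(df[, c("compound_id", "rank")])
  if (any(dup_rank)) {
    d <- df[dup_rank, ][1, ]
    np_validation_error(sprintf("duplicate rank %d within compound '%s'",
                                d$rank, d$compound_id))
  }

  # collapse duplicate (compound, target) pairs keeping the best rank
  df <- df[order(df$compound_id, df$target_symbol, df$rank), , drop = FALSE]
  dup_pair <- duplicated(df[, c("compound_id", "target_symbol")])
  if (any(dup_pair)) {
    np_log(sum(dup_pair), " duplicate (compound, target) pair(s) collapsed to best rank")
    df <- df[!dup_pair, , drop = FALSE]
  }

  df <- df[df$rank <= top_k, , drop = FALSE]
  df <- df[order(df$compound_id, df$rank), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load a disease gene list
#'
#' Reads a tab-separated table of disease-associated genes with a curated
#' gene-disease association (GDA) score in \[0, 1\] and keeps genes whose
#' score is strictly greater than `min_score`. The strict inequality
#' mirrors the usual "score > 0.1" seed-gene selection rule; boundary
#' values are excluded. Symbols are uppercased and deduplicated keeping
#' the maximum score.
#'
#' @param path Path to a TSV file with header columns `gene_symbol` and
#'   `gda_score`.
#' @param min_score Exclusive lower bound on the association score
#'   (default 0.1).
#' @return A data.frame with columns `gene_symbol` and `gda_score`.
#' @export
load_disease_genes <- function(path, min_score = 0.1) {
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      is.na(min_score) || min_score < 0 || min_score > 1)
    np_usage_error("min_score must be a single number in [0, 1]")
  df <- read_tsv_table(path, c("gene_symbol", "gda_score"))
  if (nrow(df) == 0L) {
    warning("disease gene table is empty")
    return(data.frame(gene_symbol = character(), gda_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  score <- suppressWarnings(as.numeric(df$gda_score))
  if (any(is.na(score)))
    np_format_error("non-numeric gda_score encountered")
  if (any(score < 0 | score > 1))
    np_validation_error("gda_score outside [0, 1]")
  df$gda_score <- score
  df$gene_symbol <- norm_symbol(df$gene_symbol)

  # dedup keeping max score
  df <- df[order(df$gene_symbol, -df$gda_score), , drop = FALSE]
  df <- df[!duplicated(df$gene_symbol), , drop = FALSE]

  df <- df[df$gda_score > min_score, , drop = FALSE]
  if (nrow(df) == 0L) warning("no disease genes pass the score filter")
  df <- df[order(df$gene_symbol), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load a confidence-scored PPI edge list
#'
#' Reads a tab-separated protein-protein interaction edge list carrying a
#' combined confidence score in \[0, 1\] and keeps edges whose score is
#' strictly greater than `min_combined_score` (default 0.7, the
#' high-confidence band boundary; see [ppi_confidence_bands()]).
#' Self-loops are dropped with a logged count; duplicate unordered pairs
#' collapse to the maximum score. Returned edges are canonicalised with
#' `protein_a < protein_b` and sorted.
#'
#' @param path Path to a TSV file with header columns `protein_a`,
#'   `protein_b`, `combined_score`.
#' @param min_combined_score Exclusive lower bound on the combined score
#'   (default 0.7).
#' @return A data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score`.
#' @export
load_ppi <- function(path, min_combined_score = 0.7) {
  if (!is.numeric(min_combined_score) || length(min_combined_score) != 1L ||
      is.na(min_combined_score) || min_combined_score < 0 || min_combined_score > 1)
    np_usage_error("min_combined_score must be a single number in [0, 1]")
  df <- read_tsv_table(path, c("protein_a", "protein_b", "combined_score"))
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (nrow(df) > 0L && any(is.na(score)))
    np_format_error("non-numeric combined_score encountered")
  if (any(score < 0 | score > 1))
    np_validation_error("combined_score outside [0, 1]")
  df$combined_score <- score
  df$protein_a <- norm_symbol(df$protein_a)
  df$protein_b <- norm_symbol(df$protein_b)

  loops <- df$protein_a == df$protein_b
  if (any(loops)) {
    np_log(sum(loops), " self-loop edge(s) dropped")
    df <- df[!loops, , drop = FALSE]
  }

  # canonical unordered pair, keep max score over duplicates
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  df$protein_a <- a
  df$protein_b <- b
  df <- df[order(df$protein_a, df$protein_b, -df$combined_score), , drop = FALSE]
  df <- df[!duplicated(df[, c("protein_a", "protein_b")]), , drop = FALSE]

  df <- df[df$combined_score > min_combined_score, , drop = FALSE]
  if (nrow(df) == 0L) warning("no PPI edges pass the confidence filter")
  rownames(df) <- NULL
  df[, c("protein_a", "protein_b", "combined_score")]
}

#' Construct an annotation database object
#'
#' An `annotation_db` bundles a set of annotation terms (gene sets with a
#' human-readable name and a category label) together with the background
#' gene universe against which overrepresentation is tested.
#'
#' @param terms Named list; each element is `list(name=, category=,
#'   genes=)` with `genes` a character vector of uppercase symbols.
#' @param background Character vector of background gene symbols. If
#'   `NULL`, the union of all term member sets is used.
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(terms, background = NULL) {
  if (length(terms) == 0L) np_validation_error("annotation_db needs at least one term")
  if (is.null(names(terms)) || any(names(terms) == ""))
    np_validation_error("terms must be a named list keyed by term_id")
  terms <- lapply(terms, function(t) {
    t$genes <- sort(unique(norm_symbol(t$genes)))
    if (length(t$genes) == 0L) np_validation_error("term with zero genes")
    t
  })
  members <- sort(unique(unlist(lapply(terms, `[[`, "genes"), use.names = FALSE)))
  if (is.null(background)) {
    background <- members
  } else {
    background <- sort(unique(norm_symbol(background)))
    outside <- setdiff(members, background)
    if (length(outside) > 0L) {
      np_validation_error(sprintf(
        "%d term member gene(s) absent from the explicit background (e.g. %s)",
        length(outside), outside[1]))
    }
  }
  structure(list(terms = terms, background = background), class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("<annotation_db> %d terms, background of %d genes\n",
              length(x$terms), length(x$background)))
  invisible(x)
}

#' Load a GMT-style annotation database
#'
#' Parses a gene-matrix-transposed (GMT) style file in which each line is
#' `term_id <tab> term_name|category <tab> gene1 <tab> gene2 ...`. The
#' category label rides in the description field after a `|` separator.
#' Unless `background_path` is given, the background universe is the union
#' of all term member sets.
#'
#' @param path Path to the GMT file.
#' @param background_path Optional path to a one-symbol-per-line
#'   background file; must be a superset of all term members.
#' @return An [annotation_db()] object.
#' @export
load_annotation_db <- function(path, background_path = NULL) {
  if (!file.exists(path)) np_usage_error(sprintf("input file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) np_format_error("empty annotation file")
  terms <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      np_validation_error(sprintf("line %d: term '%s' has zero genes",
                                  i, fields[1]))
    desc <- strsplit(fields[2], "|", fixed = TRUE)[[1]]
    if (length(desc) != 2L)
      np_format_error(sprintf("line %d: description must be 'term_name|category', got '%s'",
                              i, fields[2]))
    genes <- norm_symbol(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      np_validation_error(sprintf("line %d: term '%s' has zero genes", i, fields[1]))
    terms[[fields[1]]] <- list(name = desc[1], category = desc[2],
                               genes = sort(unique(genes)))
  }
  background <- NULL
  if (!is.null(background_path)) {
    background <- norm_symbol(readLines(background_path, warn = FALSE))
    background <- background[nzchar(background)]
  }
  annotation_db(terms, background)
}

# ---- writers (used by the generators and the pipeline; the dialects ----
# ---- written here are exactly the dialects the loaders read)        ----

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.10g", v)
  }, character(1))
  out
}

#' Write loader-compatible input tables
#'
#' Writers for the three TSV input dialects and the GMT annotation
#' dialect; `load_*` on the written file reproduces the record set
#' (loader idempotence).
#'
#' @param df Data frame in the corresponding loader's output layout.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_compound_targets <- function(df, path) {
  out <- df
  out$fit_score <- fmt_num(out$fit_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compound_targets
#' @export
write_disease_genes <- function(df, path) {
  out <- df
  out$gda_score <- fmt_num(out$gda_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compound_targets
#' @export
write_ppi <- function(df, path) {
  out <- df
  out$combined_score <- fmt_num(out$combined_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotation database as a GMT-style file
#'
#' @param db An [annotation_db()] object.
#' @param path Output file path.
#' @param background_path Optional path for the explicit background list.
#' @return Invisibly, `path`.
#' @export
write_annotation_gmt <- function(db, path, background_path = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  ids <- sort(names(db$terms))
  lines <- vapply(ids, function(id) {
    t <- db$terms[[id]]
    paste(c(id, paste0(t$name, "|", t$category), t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(background_path)) writeLines(db$background, background_path)
  invisible(path)
}
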