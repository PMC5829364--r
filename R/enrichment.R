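# Overrepresentation analysis (ORA): one-sided upper-tail hypergeometric
# test of a query gene set against annotated terms, Benjamini-Hochberg
# FDR over all tested terms, rich factor k/K as the effect size.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` query genes inside a term of size `K` when `n`
#' query genes are drawn from a background of `N`. Evaluated through the
#' distribution function in a numerically stable way; `P(X >= 0)` is
#' exactly 1. With `ease = TRUE` the more conservative EASE variant is
#' used, which scores the tail at `k - 1` (one overlapping gene removed).
#'
#' @param k Overlap count (query genes inside the term).
#' @param K Term size.
#' @param n Query size.
#' @param N Background size.
#' @param ease Use the EASE-score variant (default FALSE).
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N, ease = FALSE) {
  if (any(is.na(c(k, K, n, N))) || any(c(k, K, n, N) < 0))
    np_usage_error("k, K, n, N must be non-negative")
  if (k > min(K, n) || K > N || n > N)
    np_usage_error("hypergeometric bounds violated: need k <= min(K, n) and K, n <= N")
  kk <- if (ease) pmax(k - 1, 0) else k
  # P(X >= kk) = 1 - P(X <= kk - 1), via the stable upper-tail form
  stats::phyper(kk - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with the p-values sorted ascending, the i-th
#' is multiplied by `m/i` and a running minimum from the largest rank
#' down enforces monotonicity; values are capped at 1 and returned in
#' the input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    np_usage_error("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run overrepresentation analysis
#'
#' Tests the query gene set against every term of the annotation
#' database. Query genes outside the background are dropped with a
#' warning and the effective query size `n` reflects the retained set.
#' p-values come from [hypergeometric_tail()]; the FDR column is the
#' Benjamini-Hochberg adjustment over all tested terms (not only the
#' reported ones). One row is reported per term with overlap `k >= 1`,
#' sorted by FDR, then p, then term id. `rich_factor = k / K`.
#'
#' @param query Character vector of query gene symbols.
#' @param db An [annotation_db()].
#' @param fdr_cutoff Rows with `fdr < fdr_cutoff` are flagged `enriched`
#'   (default 0.01).
#' @param ease Use the EASE tail variant (default FALSE).
#' @return Data frame with columns `term_id`, `term_name`, `category`,
#'   `k`, `K`, `n`, `N`, `rich_factor`, `p_value`, `fdr`, `enriched`.
#' @export
run_enrichment <- function(query, db, fdr_cutoff = 0.01, ease = FALSE) {
  stopifnot(inherits(db, "annotation_db"))
  query <- unique(norm_symbol(query))
  query <- query[nzchar(query)]
  outside <- setdiff(query, db$background)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the background dropped: %s",
                    length(outside),
                    paste(utils::head(outside, 5), collapse = ", ")))
    query <- intersect(query, db$background)
  }
  if (length(query) == 0L)
    np_validation_error("no query gene is in the annotation background")

  N <- length(db$background)
  n <- length(query)
  ids <- names(db$terms)
  k <- vapply(db$terms, function(t) length(intersect(t$genes, query)), integer(1))
  K <- vapply(db$terms, function(t) length(t$genes), integer(1))
  p <- mapply(hypergeometric_tail, k = k, K = K,
              MoreArgs = list(n = n, N = N, ease = ease))
  fdr <- bh_fdr(p)

  rows <- data.frame(term_id = ids,
                     term_name = vapply(db$terms, `[[`, character(1), "name"),
                     category = vapply(db$terms, `[[`, character(1), "category"),
                     k = k, K = K, n = n, N = N,
                     rich_factor = k / K,
                     p_value = p, fdr = fdr,
                     stringsAsFactors = FALSE, row.names = NULL)
  rows <- rows[rows$k >= 1L, , drop = FALSE]
  rows$enriched <- rows$fdr < fdr_cutoff
  rows <- rows[order(rows$fdr, rows$p_value, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Tally enriched terms by category
#'
#' Counts enriched rows (those flagged `enriched`) per category label;
#' the counts sum to the number of enriched rows.
#'
#' @param rows Result of [run_enrichment()].
#' @return Named integer vector, sorted by decreasing count then name;
#'   empty when nothing is enriched.
#' @export
categorize_enrichment <- function(rows) {
  enr <- rows[rows$enriched, , drop = FALSE]
  if (nrow(enr) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(enr$category)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(-out, names(out))]
}

#' Write an enrichment table as TSV
#'
#' Plot-ready columns mirroring the usual enrichment bubble chart:
#' term, category, overlap and term sizes, rich factor, p, FDR.
#'
#' @param rows Result of [run_enrichment()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(rows, path) {
  out <- rows
  for (col in c("rich_factor", "p_value", "fdr"))
    out[[col]] <- sprintf("%.10g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
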