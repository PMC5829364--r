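test_that("hypergeometric tail matches closed-form and summation oracles", {
  expect_equal(hypergeometric_tail(0, 5, 5, 10), 1)
  # all five draws inside the five-member term: C(5,5)C(5,0)/C(10,5) = 1/252
  expect_equal(hypergeometric_tail(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:50) {
    N <- sample(5:40, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, n - (N - K)):min(K, n), 1)
    expect_equal(hypergeometric_tail(k, K, n, N), oracle_hyper_tail(k, K, n, N),
                 tolerance = 1e-12)
  }

  # the full support sums to one
  for (par in list(c(8, 4, 3), c(20, 10, 7), c(30, 5, 25))) {
    ks <- 0:min(par[2], par[3])
    probs <- exp(lchoose(par[2], ks) + lchoose(par[1] - par[2], par[3] - ks) -
                   lchoose(par[1], par[3]))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    expect_equal(hypergeometric_tail(min(par[2], par[3]), par[2], par[3], par[1]),
                 probs[length(probs)], tolerance = 1e-12)
  }

  expect_error(hypergeometric_tail(6, 5, 5, 10), class = "netpharm_usage_error")
  expect_error(hypergeometric_tail(1, 11, 5, 10), class = "netpharm_usage_error")

  # EASE variant scores the tail one overlap gene short (more conservative)
  expect_equal(hypergeometric_tail(3, 5, 5, 20, ease = TRUE),
               hypergeometric_tail(2, 5, 5, 20))
  expect_true(hypergeometric_tail(3, 5, 5, 20, ease = TRUE) >
                hypergeometric_tail(3, 5, 5, 20))
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  # 0.01*3/1, 0.02*3/2, 0.03*3/3 -> 0.03, 0.03, 0.03
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.05, 6)), rep(0.05, 6))
  # order invariance
  p <- c(0.04, 0.001, 0.3, 0.02, 1)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  expect_error(bh_fdr(c(0.1, 0)), class = "netpharm_usage_error")
  expect_error(bh_fdr(c(0.1, 1.1)), class = "netpharm_usage_error")
})

make_db <- function(terms, background = NULL) annotation_db(terms, background)

test_that("a term identical to the query ranks first", {
  set.seed(1)
  bg <- sprintf("G%03d", 1:300)
  target <- bg[1:12]
  terms <- list(HIT = list(name = "hit", category = "c1", genes = target))
  for (i in 1:20) {
    terms[[sprintf("NULL%02d", i)]] <-
      list(name = "null", category = "c2", genes = bg[sample(300, 40)])
  }
  db <- make_db(terms, bg)
  rows <- run_enrichment(target, db)
  expect_equal(rows$term_id[1], "HIT")
  expect_equal(rows$p_value[1], min(rows$p_value))
  expect_true(rows$enriched[1])
  expect_equal(rows$rich_factor[rows$term_id == "HIT"], 1)
  # FDR column is monotone along the p-sorted rows
  srt <- rows[order(rows$p_value), ]
  expect_true(all(diff(srt$fdr) >= -1e-12))
})

test_that("rich factor is overlap over term size and bounds hold", {
  bg <- sprintf("G%03d", 1:200)
  db <- make_db(list(T1 = list(name = "t", category = "c", genes = bg[1:50])), bg)
  rows <- run_enrichment(bg[c(1:10, 151:160)], db)
  expect_equal(rows$k, 10L)
  expect_equal(rows$K, 50L)
  expect_equal(rows$rich_factor, 0.2)
  expect_equal(rows$n, 20L)
  expect_equal(rows$N, 200L)
  expect_true(rows$k <= min(rows$K, rows$n) && rows$K <= rows$N)
})

test_that("query genes outside the background are dropped with a warning", {
  bg <- sprintf("G%03d", 1:100)
  db <- make_db(list(T1 = list(name = "t", category = "c", genes = bg[1:20])), bg)
  expect_warning(rows <- run_enrichment(c(bg[1:5], "ALIEN1"), db), "ALIEN1")
  expect_equal(rows$n, 5L)
  expect_error(suppressWarnings(run_enrichment("ALIEN1", db)),
               class = "netpharm_validation_error")
})

test_that("growing the background never decreases a p-value", {
  bg <- sprintf("G%03d", 1:100)
  terms <- list(T1 = list(name = "t", category = "c", genes = bg[1:15]),
                T2 = list(name = "t", category = "c", genes = bg[10:40]))
  q <- bg[c(1:8, 90:95)]
  p_small <- run_enrichment(q, make_db(terms, bg))$p_value
  bigger <- c(bg, sprintf("X%03d", 1:200))
  p_big <- run_enrichment(q, make_db(terms, bigger))$p_value
  expect_true(all(p_big <= p_small + 1e-15))
})

test_that("category tallies count enriched rows only", {
  cfg <- pharm_sim_config(n_terms = 39L, planted_term_count = 39L,
                          planted_overlap_fraction = 0.8, rng_seed = 2)
  query <- sprintf("Q%02d", 1:10)
  ann <- gen_annotation_db(cfg, query)
  rows <- run_enrichment(query, ann$db)
  expect_true(all(rows$enriched[rows$term_id %in% ann$planted]))
  tally <- categorize_enrichment(rows)
  expect_equal(sum(tally), sum(rows$enriched))
  expect_equal(unname(tally[c("human diseases", "organismal systems",
                              "environmental information processing",
                              "cellular processes")]),
               c(19L, 10L, 6L, 4L))

  # no enriched rows -> empty tally
  rows$enriched <- FALSE
  expect_length(categorize_enrichment(rows), 0L)

  # single category
  rows2 <- rows[1:3, ]
  rows2$category <- "only"
  rows2$enriched <- TRUE
  expect_equal(categorize_enrichment(rows2), c(only = 3L))
})

test_that("fdr cutoff 1 reports every tested term with overlap", {
  bg <- sprintf("G%03d", 1:100)
  terms <- list(T1 = list(name = "t", category = "c", genes = bg[1:15]),
                T2 = list(name = "t", category = "c", genes = bg[50:60]))
  rows <- run_enrichment(bg[1:5], make_db(terms, bg), fdr_cutoff = 1)
  expect_true(all(rows$enriched))
  expect_equal(rows$term_id, "T1") # T2 has zero overlap, not reported
})
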