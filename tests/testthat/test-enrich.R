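test_that("hypergeometric upper tail matches hand-enumerated cases", {
  expect_identical(hypergeom_upper(0, 5, 4, 10), 1)
  expect_equal(hypergeom_upper(4, 5, 4, 10), 6 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_upper(3, 3, 3, 6), 1 / 20, tolerance = 1e-12)
  # monotone non-increasing in k
  p <- hypergeom_upper(0:4, 5, 4, 10)
  expect_true(all(diff(p) < 0))
  expect_error(hypergeom_upper(5, 5, 4, 10), "min")
  expect_error(hypergeom_upper(1, 11, 4, 10), "exceed")
  expect_error(hypergeom_upper(-1, 5, 4, 10), "negative")
})

test_that("hypergeometric upper tail equals exhaustive subset enumeration", {
  for (N in c(5, 8)) {
    for (K in 0:N) {
      for (n in 1:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_upper(k, n, K, N), enum_hypergeom(k, n, K, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.005, 0.1, 0.1)), c(0.015, 0.1, 0.1))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  for (rep in 1:50) {
    p <- runif(sample(1:8, 1))
    q <- bh_fdr(p)
    expect_equal(q, stepup_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(1.2), "\\(0, 1\\]")
})

test_that("per-cluster entity enrichment flags planted associations only", {
  # 40 docs, 4 clusters of 10; entity X in 8 of cluster 0's docs plus 2
  # stragglers, entity UBIQ in every document
  docs <- sprintf("D%03d", 1:40)
  labels <- stats::setNames(rep(0:3, each = 10), docs)
  m <- dplyr::bind_rows(
    tibble::tibble(doc_id = c(docs[1:8], docs[15], docs[25]), preflabel = "X",
                   type = "protein"),
    tibble::tibble(doc_id = docs, preflabel = "UBIQ", type = "protein")
  )
  res <- cluster_entity_enrichment(m, labels, alpha = 0.1, min_count = 2)
  expect_equal(res$preflabel[res$cluster == 0], "X")
  expect_equal(res$k[res$cluster == 0], 8L)
  expect_equal(res$K_bg[res$cluster == 0], 10L)
  expect_equal(res$N_bg[res$cluster == 0], 40L)
  expect_equal(res$p_value[res$cluster == 0],
               hypergeom_upper(8, 10, 10, 40), tolerance = 1e-12)
  # the ubiquitous entity can never be enriched (p = 1 in every cluster)
  expect_false("UBIQ" %in% res$preflabel)
  # X is not reported in other clusters (k < 2 or p above the cut-off)
  expect_false(any(res$preflabel == "X" & res$cluster != 0))
  expect_true(all(res$fdr >= res$p_value - 1e-15))
})

test_that("category enrichment counts mapped proteins against a mapped background", {
  cm <- category_map(
    preflabel = c("P1", "P2", "P3", "P4", "P5", "P6",
                  "P1", "P2", "P3", "P4", "P5", "P6"),
    category_id = c(rep("DOID:ALL", 6), "DOID:MET", "DOID:MET", "DOID:MET",
                    "DOID:OTH", "DOID:OTH", "DOID:OTH"),
    category_description = c(rep("disease", 6), rep("metabolic", 3),
                             rep("other", 3))
  )
  bg <- c("P1", "P2", "P3", "P4", "P5", "P6", "UNMAPPED")
  res <- category_enrichment(list(`0` = c("P1", "P2", "P3")), cm, bg)
  # a category covering the whole background can never be enriched
  expect_equal(res$p_value[res$category_id == "DOID:ALL"], 1)
  row <- res[res$category_id == "DOID:MET", ]
  expect_equal(row$k, 3L)
  expect_equal(row$n, 3L)       # the unmapped protein is counted out
  expect_equal(row$K_bg, 3L)
  expect_equal(row$N_bg, 6L)
  expect_equal(row$p_value, hypergeom_upper(3, 3, 3, 6), tolerance = 1e-12)
  expect_equal(row$description, "metabolic")
  # FDR within the cluster family
  expect_equal(res$fdr, bh_fdr(res$p_value), tolerance = 1e-12)
  expect_error(category_enrichment(list(`0` = "P1"), cm, character(0)),
               "background")
})

test_that("null enrichment p-values are calibrated on association-free corpora", {
  lex <- plain_protein_lexicon(40)
  nsig <- 0
  ntest <- 0
  for (s in 1:3) {
    gen <- generate_corpus(generator_config(
      n_docs = 560, doc_length_mean = 20, entity_lexicon = lex,
      mention_rate = 14, synonym_prob = 0, seed = 700 + s
    ))
    res <- cluster_entity_enrichment(gen$truth$mentions, gen$truth$topics,
                                     alpha = 1.1, min_count = 0)
    ntest <- ntest + 7 * 40
    nsig <- nsig + sum(res$p_value < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / ntest)
  expect_lt(abs(nsig / ntest - 0.05), 3 * se)
})
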