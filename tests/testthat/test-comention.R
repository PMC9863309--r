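# Small sentencized corpus + hand-placed mentions used by several blocks.
mention_row <- function(doc, sent, preflabel, type, start = 0L) {
  tibble::tibble(doc_id = doc, sentence_index = sent, start = start,
                 end = start + nchar(preflabel), text_found = preflabel,
                 preflabel = preflabel, type = type)
}

test_that("a sentence comentioning two entities yields one canonical record", {
  lex <- entity_lexicon(c("LEP", "obesity"), c("protein", "disease"),
                        list(c("LEP", "Leptin"), "obesity"))
  corp <- sentencize(make_corpus("Leptin is linked to obesity.", year = 2019L))
  m <- tag_entities(corp, lex)
  rec <- extract_comentions(m, corp)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$v1_preflabel, "LEP")
  expect_equal(rec$v2_preflabel, "obesity")
  expect_equal(rec$v1_text_found, "Leptin")
  expect_equal(rec$pub_year, 2019L)
  expect_equal(rec$sentence_text, "Leptin is linked to obesity.")
})

test_that("type_pair filtering keeps only cross-type pairs", {
  corp <- sentencize(make_corpus("Alpha beta gamma delta epsilon zeta."))
  m <- dplyr::bind_rows(
    mention_row("D001", 0L, "A", "protein", 0L),
    mention_row("D001", 0L, "B", "protein", 10L),
    mention_row("D001", 0L, "d", "disease", 20L)
  )
  rec <- extract_comentions(m, corp, type_pair = c("protein", "disease"))
  expect_equal(nrow(rec), 2)
  expect_setequal(paste(rec$v1_preflabel, rec$v2_preflabel), c("A d", "B d"))
  # unfiltered extraction also reports the protein-protein pair
  expect_equal(nrow(extract_comentions(m, corp)), 3)
})

test_that("repeated preflabels in one sentence are deduplicated and order-invariant", {
  corp <- sentencize(make_corpus("Alpha beta gamma delta epsilon zeta."))
  m <- dplyr::bind_rows(
    mention_row("D001", 0L, "LEP", "protein", 0L),
    mention_row("D001", 0L, "LEP", "protein", 12L),
    mention_row("D001", 0L, "obesity", "disease", 24L)
  )
  rec <- extract_comentions(m, corp)
  expect_equal(nrow(rec), 1)
  # mention order must not matter
  rec2 <- extract_comentions(m[c(3, 1, 2), ], corp)
  expect_identical(rec, rec2)
})

test_that("edge support is counted over distinct documents", {
  corp <- sentencize(make_corpus(rep("Alpha beta gamma delta epsilon zeta.", 6)))
  # the same pair in six different documents
  m6 <- dplyr::bind_rows(lapply(sprintf("D%03d", 1:6), function(d) {
    dplyr::bind_rows(mention_row(d, 0L, "LEP", "protein", 0L),
                     mention_row(d, 0L, "obesity", "disease", 10L))
  }))
  rec6 <- extract_comentions(m6, corp)
  net <- build_network(rec6, min_support = 5)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 6L)
  expect_equal(sort(net$nodes$preflabel, method = "radix"), c("LEP", "obesity"))
  expect_true(all(net$edges$weight <= min(net$nodes$weight)))

  # the same pair in three sentences of ONE document has support 1
  corp1 <- sentencize(make_corpus("One two three. Four five six. Seven eight nine."))
  m1 <- dplyr::bind_rows(lapply(0:2, function(s) {
    dplyr::bind_rows(mention_row("D001", s, "LEP", "protein", 0L),
                     mention_row("D001", s, "obesity", "disease", 5L))
  }))
  rec1 <- extract_comentions(m1, corp1)
  expect_equal(nrow(rec1), 3)
  net1 <- build_network(rec1, min_support = 2)
  expect_equal(nrow(net1$edges), 0)
  expect_equal(nrow(net1$nodes), 0)
})

test_that("record counts and edge weights match a brute-force double loop", {
  set.seed(41)
  n_docs <- 30
  corp <- sentencize(make_corpus(rep("One two three. Four five six.", n_docs),
                                 year = 2010L))
  ents <- c(A = "protein", B = "protein", C = "protein",
            d = "disease", e = "disease")
  rows <- list()
  for (i in 1:200) {
    rows[[i]] <- mention_row(sprintf("D%03d", sample(n_docs, 1)),
                             sample(0:1, 1),
                             sample(names(ents), 1), "x",
                             start = sample(0:8, 1))
  }
  m <- dplyr::bind_rows(rows)
  m$type <- unname(ents[m$preflabel])
  rec <- extract_comentions(m, corp)

  # brute force over sentences
  bf_pairs <- list()
  for (key in unique(paste(m$doc_id, m$sentence_index))) {
    sel <- m[paste(m$doc_id, m$sentence_index) == key, ]
    labs <- sort(unique(sel$preflabel), method = "radix")
    if (length(labs) < 2) next
    cmb <- utils::combn(labs, 2)
    bf_pairs[[key]] <- paste(key, cmb[1, ], cmb[2, ])
  }
  bf <- sort(unlist(bf_pairs), method = "radix")
  got <- sort(paste(rec$doc_id, rec$sentence_index, rec$v1_preflabel,
                    rec$v2_preflabel), method = "radix")
  expect_equal(got, unname(bf))

  net <- build_network(rec, min_support = 1)
  for (i in seq_len(nrow(net$edges))) {
    docs_bf <- unique(rec$doc_id[rec$v1_preflabel == net$edges$v1[i] &
                                   rec$v2_preflabel == net$edges$v2[i]])
    expect_equal(net$edges$weight[i], length(docs_bf))
  }
  # support threshold is monotone
  for (ms in 1:5) {
    expect_true(all(build_network(rec, min_support = ms)$edges$weight >= ms))
  }
})

test_that("the tabular comention report mirrors the record list", {
  lex <- entity_lexicon(c("LEP", "INS", "obesity"),
                        c("protein", "protein", "disease"),
                        list(c("LEP", "leptin"), c("INS", "insulin"), "obesity"))
  corp <- sentencize(make_corpus("Both leptin and insulin relate to obesity.",
                                 year = 2021L))
  m <- tag_entities(corp, lex)
  rec <- extract_comentions(m, corp, type_pair = c("protein", "disease"))
  tab <- comention_table(rec)
  expect_equal(nrow(tab), 2)
  expect_equal(names(tab), c("pmid", "sentence", "date", "gene_protein", "disease"))
  expect_equal(unique(tab$pmid), "D001")
  expect_equal(unique(tab$disease), "obesity")
  expect_setequal(tab$gene_protein, c("LEP", "INS"))

  expect_equal(nrow(comention_table(rec[0, ])), 0)
  # protein-protein pairs are a contract error
  pp <- extract_comentions(m, corp, type_pair = c("protein", "protein"))
  expect_error(comention_table(pp), "protein-disease")
})

test_that("network export writes parseable GraphML and an edge list", {
  corp <- sentencize(make_corpus(rep("Alpha beta gamma.", 6)))
  m <- dplyr::bind_rows(lapply(sprintf("D%03d", 1:6), function(d) {
    dplyr::bind_rows(mention_row(d, 0L, "LEP", "protein", 0L),
                     mention_row(d, 0L, "obesity", "disease", 8L))
  }))
  net <- build_network(extract_comentions(m, corp), min_support = 5)
  g_path <- withr::local_tempfile(fileext = ".graphml")
  e_path <- withr::local_tempfile(fileext = ".tsv")
  write_comention_network(net, g_path, e_path)
  g <- igraph::read_graph(g_path, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 6)
  expect_equal(nrow(utils::read.delim(e_path)), 1)
})
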