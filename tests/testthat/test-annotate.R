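test_that("dictionary tagging normalizes synonyms to preferred labels", {
  lex <- entity_lexicon(c("ADIPOQ", "LEP"), "protein",
                        list(c("ADIPOQ", "adiponectin"), c("LEP", "leptin")))
  corp <- sentencize(make_corpus("Plasma adiponectin levels rose. Leptin did not."))
  m <- tag_entities(corp, lex)
  expect_equal(nrow(m), 2)
  expect_equal(m$preflabel, c("ADIPOQ", "LEP"))
  expect_equal(m$text_found[1], "adiponectin")
  # case-insensitive matching for synonyms >= 4 chars ("Leptin" ~ "leptin")
  expect_equal(m$text_found[2], "Leptin")
  expect_identical(substring(corp$sentences$text[m$sentence_index + 1 +
                                                   c(0, 0)][1], m$start[1] + 1, m$end[1]),
                   "adiponectin")
})

test_that("leftmost-longest matching wins over shorter overlapping synonyms", {
  lex <- entity_lexicon(c("MILK", "MFGM"), "protein",
                        list("milk", "milk fat globule membrane"))
  corp <- sentencize(make_corpus("The milk fat globule membrane proteins were measured."))
  m <- tag_entities(corp, lex)
  expect_equal(nrow(m), 1)
  expect_equal(m$preflabel, "MFGM")
  expect_equal(m$text_found, "milk fat globule membrane")

  # earlier start beats longer span
  corp2 <- sentencize(make_corpus("Pure milk then milk fat globule membrane again."))
  m2 <- tag_entities(corp2, lex)
  expect_equal(m2$preflabel, c("MILK", "MFGM"))
})

test_that("short synonyms are case-sensitive, and matches stay on token boundaries", {
  lex <- entity_lexicon(c("INS", "LEP"), "protein",
                        list(c("INS", "insulin"), "LEP"))
  corp <- sentencize(make_corpus(c(
    "The ins and outs were noted.",       # lowercase 'ins' must not match INS
    "INS rose with insulin infusion.",    # both surfaces of INS
    "Insulins were not single tokens.",   # no partial-token match
    "Plasma LEPR differs from LEP here."  # LEPR must not match LEP
  )))
  m <- tag_entities(corp, lex)
  expect_equal(m$doc_id, c("D002", "D002", "D004"))
  expect_equal(m$text_found, c("INS", "insulin", "LEP"))
  expect_equal(m$preflabel, c("INS", "INS", "LEP"))
})

test_that("tagging the preferred label itself is idempotent for the whole lexicon", {
  lex <- synthetic_lexicon()
  corp <- sentencize(make_corpus(sprintf("Here %s was measured.", lex$preflabel)))
  m <- tag_entities(corp, lex)
  expect_equal(nrow(m), nrow(lex))
  expect_equal(m$preflabel[order(m$doc_id)], lex$preflabel)
  expect_identical(m$text_found[order(m$doc_id)], lex$preflabel)
})

test_that("mentions never overlap within a sentence", {
  gen <- generate_corpus(generator_config(n_docs = 80, seed = 13,
                                          mention_rate = 4, synonym_prob = 0.5))
  corp <- sentencize(gen$corpus)
  m <- tag_entities(corp, synthetic_lexicon())
  by_sent <- split(m, paste(m$doc_id, m$sentence_index))
  for (s in by_sent) {
    if (nrow(s) < 2) next
    s <- s[order(s$start), ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("tagger recovers planted mentions exactly on synonym-varied corpora", {
  gen <- generate_corpus(generator_config(n_docs = 100, seed = 17,
                                          mention_rate = 2, synonym_prob = 0.5))
  corp <- sentencize(gen$corpus)
  m <- tag_entities(corp, synthetic_lexicon())
  tagged <- doc_span_keys(m, corp)
  truth <- truth_span_keys(gen$truth)
  expect_equal(mean(tagged %in% truth), 1)  # precision
  expect_equal(mean(truth %in% tagged), 1)  # recall
  # and document-level counts equal the generator oracle
  expect_equal(entity_document_counts(m)[, c("preflabel", "n_documents")],
               truth_entity_doc_counts(gen$truth)[, c("preflabel", "n_documents")])
})

test_that("document-level counts deduplicate and filter correctly", {
  m <- tibble::tibble(
    doc_id = c("a", "a", "a", "b", "b"),
    sentence_index = c(0L, 0L, 1L, 0L, 0L),
    start = 0L, end = 3L,
    text_found = "LEP",
    preflabel = c("LEP", "LEP", "LEP", "LEP", "CRP"),
    type = "protein"
  )
  counts <- entity_document_counts(m)
  expect_equal(counts$preflabel, c("LEP", "CRP"))
  expect_equal(counts$n_documents, c(2L, 1L))
  expect_equal(nrow(entity_document_counts(m, min_count = 2)), 1)
  expect_equal(nrow(entity_document_counts(m[0, ])), 0)
})

test_that("tagging an unsentencized corpus is a state error", {
  corp <- make_corpus("Some text.")
  expect_error(tag_entities(corp, synthetic_lexicon()), "sentencize")
})
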