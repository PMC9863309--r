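test_that("corpus JSON round-trips, preserves order, and validates", {
  f <- withr::local_tempfile(fileext = ".json")
  docs <- tibble::tibble(
    doc_id = c("111", "222"),
    title = c("First", ""),
    abstract = c("Alpha text here.", "Beta text there."),
    full_text = c("", "Longer full text."),
    year = c(2015L, NA),
    journal = c("Nutrients", ""),
    sjr = c(1.189, NA),
    query_tags = list(c("protnutr_mh", "protnutr_ab"), character(0))
  )
  corp <- corpus(docs)
  write_corpus(corp, f)
  back <- read_corpus(f)
  expect_equal(back$documents, corp$documents)
  expect_equal(back$documents$doc_id, c("111", "222"))

  # round trip on a larger generated corpus, plus byte-identical double write
  gen <- generate_corpus(generator_config(n_docs = 20, seed = 42))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_corpus(gen$corpus, f2)
  expect_equal(read_corpus(f2)$documents, gen$corpus$documents)
  f3 <- withr::local_tempfile(fileext = ".json")
  write_corpus(gen$corpus, f3)
  expect_identical(readBin(f2, "raw", file.size(f2)),
                   readBin(f3, "raw", file.size(f3)))
})

test_that("corpus reading rejects malformed and invalid input with named errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"doc_id": "111", "abstract": "A."},
               {"doc_id": "111", "abstract": "B."}]', f)
  expect_error(read_corpus(f), "111")

  writeLines('[{"doc_id": "5", "title": "no text at all"}]', f)
  expect_error(read_corpus(f), "abstract")

  writeLines('[{"doc_id": "5", "abstract": "A."', f)
  expect_error(read_corpus(f), "malformed")

  expect_error(corpus(tibble::tibble(doc_id = "x", abstract = "A.", year = 1500L)),
               "year")
  expect_error(read_corpus(tempfile()), "not found")
})

test_that("sentencizer splits on terminal punctuation but protects abbreviations and decimals", {
  sents <- function(txt) sentencize(make_corpus(txt))$sentences$text
  expect_equal(sents("Proteins were measured. Diet was recorded."),
               c("Proteins were measured.", "Diet was recorded."))
  # decimals never split
  expect_equal(sents("after 48 h at 4.9 and 6.0 °C in milk."),
               "after 48 h at 4.9 and 6.0 °C in milk.")
  # protected abbreviations and single initials
  expect_length(sents("This is shown in Fig. 3 and discussed. Next point here."), 2)
  expect_length(sents("Samples from J. Smith were used. Results follow."), 2)
  expect_length(sents("Kaput et al. 2020 showed growth. It works."), 2)
  expect_length(sents("Values rose, e.g. in mice. Controls did not."), 2)
  # degenerate text is one sentence
  expect_length(sents("no punctuation at all"), 1)
  expect_length(sents("lowercase after period. not split here"), 1)
})

test_that("sentence spans partition the source text", {
  gen <- generate_corpus(generator_config(n_docs = 200, seed = 7, mention_rate = 2))
  corp <- sentencize(gen$corpus)
  for (i in seq_len(nrow(corp$documents))) {
    txt <- corp$documents$abstract[i]
    ss <- corp$sentences[corp$sentences$doc_id == corp$documents$doc_id[i], ]
    expect_equal(ss$index, seq_len(nrow(ss)) - 1L)
    expect_identical(ss$text, substring(txt, ss$start + 1L, ss$end))
    expect_true(all(ss$start < ss$end))
    if (nrow(ss) > 1) {
      gaps <- substring(txt, ss$end[-nrow(ss)] + 1L, ss$start[-1])
      expect_true(all(grepl("^[[:space:]]*$", gaps)))
      expect_true(all(ss$start[-1] >= ss$end[-nrow(ss)]))
    }
    # separators are whitespace only, so joining reconstructs the source
    lead <- substr(txt, 1, ss$start[1])
    trail <- substring(txt, ss$end[nrow(ss)] + 1L)
    expect_true(grepl("^[[:space:]]*$", lead) && grepl("^[[:space:]]*$", trail))
  }
})

test_that("query overlap regions match brute-force membership tallies", {
  ov <- query_overlap(list(a = c("1", "2", "3"), b = c("2", "3", "4")))
  expect_equal(ov[["a"]], 1L)
  expect_equal(ov[["b"]], 1L)
  expect_equal(ov[["a&b"]], 2L)

  single <- query_overlap(list(only = as.character(1:17)))
  expect_equal(unname(single), 17L)

  set.seed(99)
  sets <- list(mh = as.character(sample(100, 60)),
               majr = as.character(sample(100, 30)),
               ab = as.character(sample(100, 45)))
  ov <- query_overlap(sets)
  expect_equal(sum(ov), length(unique(unlist(sets))))
  # brute force: signature per id
  ids <- unique(unlist(sets))
  sig <- vapply(ids, function(id) {
    paste(names(sets)[vapply(sets, function(s) id %in% s, logical(1))],
          collapse = "&")
  }, "")
  expect_equal(ov, table(sig)[names(ov)] |> as.integer() |>
                 stats::setNames(names(ov)))
  expect_error(query_overlap(list()), "named")
})
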