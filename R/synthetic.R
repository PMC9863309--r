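#' Topic specification for the synthetic-corpus generator
#'
#' A topic is a set of at least 10 distinct keywords plus the probability
#' that a generated token is drawn from them (versus the shared background
#' vocabulary). Keyword sets of distinct topics must be disjoint, which
#' makes the expected between-topic document similarity on keyword terms
#' zero and justifies exact clustering-recovery tests.
#'
#' @param topic_id 0-based integer topic index.
#' @param keywords Character vector of at least 10 distinct terms.
#' @param keyword_weight Probability in (0, 1) that a token is a keyword.
#' @return Object of class `topic_spec`.
#' @export
topic_spec <- function(topic_id, keywords, keyword_weight = 0.6) {
  keywords <- as.character(keywords)
  if (anyDuplicated(keywords) || length(keywords) < 10L) {
    stop("topic ", topic_id, ": keywords must be >= 10 distinct terms")
  }
  if (keyword_weight <= 0 || keyword_weight >= 1) {
    stop("keyword_weight must lie strictly in (0, 1)")
  }
  structure(list(topic_id = as.integer(topic_id), keywords = keywords,
                 keyword_weight = keyword_weight), class = "topic_spec")
}

#' Built-in disjoint topic keyword sets
#'
#' Seven nutrition-proteomics flavored topics of 15 keywords each (liver and
#' metabolic disease; milk and infant nutrition; plant and allergen; gut
#' microbiome; nutrigenomics; cancer and meat quality; saliva and
#' biomarkers). The sets are pairwise disjoint and disjoint from
#' [default_background_vocab()] and from every synonym in
#' [synthetic_lexicon()].
#'
#' @param k Number of topics (1 to 7).
#' @param n_keywords Keywords per topic (10 to 15).
#' @param keyword_weight Passed to [topic_spec()].
#' @return List of [topic_spec()] objects.
#' @export
default_topics <- function(k = 7L, n_keywords = 15L, keyword_weight = 0.6) {
  sets <- list(
    c("liver", "diet", "mouse", "fatty", "rat", "plasma", "muscle", "hepatic",
      "lipid", "metabolic", "cholesterol", "dietary", "rodent", "steatosis",
      "triglyceride"),
    c("milk", "infant", "peptide", "colostrum", "lactation", "bovine",
      "membrane", "globule", "dairy", "whey", "formula", "breastfeeding",
      "mammary", "lactose", "suckling"),
    c("plant", "seed", "allergen", "gluten", "wheat", "soybean", "crop",
      "fruit", "grain", "cereal", "legume", "germination", "cultivar",
      "harvest", "botanical"),
    c("gut", "probiotic", "microbiota", "intestinal", "microbiome",
      "bacterial", "host", "mucosa", "commensal", "barrier", "colon",
      "microbial", "dysbiosis", "lumen", "villus"),
    c("nutrition", "nutritional", "research", "nutrigenomics", "health",
      "metabolomics", "genomics", "science", "personalized", "policy",
      "education", "lifestyle", "population", "guideline", "literacy"),
    c("cancer", "meat", "quality", "fish", "tumor", "carcinoma", "beef",
      "pork", "tenderness", "postmortem", "oncology", "malignant", "biopsy",
      "seafood", "carcinogenesis"),
    c("egg", "salivary", "saliva", "child", "biomarker", "proteome",
      "serum", "urine", "pediatric", "cohort", "panel", "secretome",
      "specimen", "adolescent", "saliva-based")
  )
  stopifnot(k >= 1L, k <= length(sets), n_keywords >= 10L, n_keywords <= 15L)
  lapply(seq_len(k), function(i) {
    topic_spec(i - 1L, sets[[i]][seq_len(n_keywords)], keyword_weight)
  })
}

#' Shared background vocabulary for the generator
#'
#' Generic scientific terms drawn with probability `1 - keyword_weight`.
#' Disjoint from the [default_topics()] keyword sets and from every synonym
#' in [synthetic_lexicon()].
#'
#' @return Character vector of background terms.
#' @export
default_background_vocab <- function() {
  c("protein", "proteomic", "proteomics", "analysis", "study", "human",
    "cell", "disease", "sample", "level", "expression", "result", "method",
    "data", "group", "control", "effect", "change", "increase", "decrease",
    "association", "measured", "identified", "quantified", "abundance",
    "pathway", "process", "function", "functional", "response", "treatment",
    "subject", "participant", "patient", "clinical", "trial", "baseline",
    "significant", "observed", "compared", "difference", "profile",
    "profiling", "approach", "technology", "spectrometry", "chromatography",
    "enzyme", "receptor", "transporter", "regulation", "signaling",
    "mechanism", "tissue", "blood", "concentration", "intake", "exposure",
    "supplementation", "intervention", "outcome", "model", "experiment",
    "replicate", "statistical", "correlation", "variance", "cluster",
    "network", "database", "annotation", "extraction", "digestion",
    "fractionation", "separation", "detection", "quantification",
    "validation", "reproducibility", "workflow", "instrument", "platform",
    "marker", "candidate", "target", "modification", "phosphorylation",
    "glycosylation", "oxidation", "degradation", "synthesis", "turnover",
    "homeostasis", "inflammation", "immunity", "metabolism", "energy",
    "growth", "development", "aging", "storage")
}

#' Synthetic protein/disease lexicon
#'
#' A small curated lexicon of real protein symbols and disease names with
#' synonym variation (external IDs are NCBI gene or MeSH identifiers). It
#' is a synthetic stand-in for the dictionary stage of large normalization
#' tools: every synonym is chosen so that no surface form (or token-prefix
#' of one) collides with [default_topics()] keywords or
#' [default_background_vocab()], which gives the dictionary tagger exact
#' precision and recall on generated corpora.
#'
#' @return An [entity_lexicon()] with 12 proteins and 8 diseases.
#' @export
synthetic_lexicon <- function() {
  entity_lexicon(
    preflabel = c("LEP", "ADIPOQ", "INS", "ALB", "CRP", "TNF", "IL6",
                  "APOE", "LTF", "MFGE8", "LALBA", "TF",
                  "obesity", "type 2 diabetes", "celiac disease",
                  "colorectal cancer", "hypertension",
                  "inflammatory bowel disease", "metabolic syndrome",
                  "atopic dermatitis"),
    type = c(rep("protein", 12L), rep("disease", 8L)),
    synonyms = list(
      c("LEP", "leptin"),
      c("ADIPOQ", "adiponectin"),
      c("INS", "insulin"),
      c("ALB", "albumin"),
      c("CRP", "c-reactive protein"),
      c("TNF", "tnf-alpha", "tumor necrosis factor"),
      c("IL6", "interleukin-6"),
      c("APOE", "apolipoprotein-e"),
      c("LTF", "lactoferrin", "lactotransferrin"),
      c("MFGE8", "lactadherin"),
      c("LALBA", "alpha-lactalbumin"),
      c("TF", "transferrin"),
      c("obesity", "obese", "adiposity"),
      c("type 2 diabetes", "t2dm"),
      c("celiac disease", "coeliac disease"),
      c("colorectal cancer", "crc"),
      c("hypertension", "hypertensive"),
      c("inflammatory bowel disease", "ibd"),
      c("metabolic syndrome", "mets"),
      c("atopic dermatitis", "eczema")
    ),
    external_id = c("3952", "9370", "3630", "213", "1401", "7124", "3569",
                    "348", "4057", "4240", "3906", "7018",
                    "D009765", "D003924", "D002446", "D015179", "D006973",
                    "D015212", "D024821", "D003876")
  )
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic-corpus generator. The defaults are
#' the study conditions used throughout the package's validation: 7 disjoint
#' 15-keyword topics at `keyword_weight` 0.6, 120-token documents, one
#' planted entity mention per document on average with 30% synonym
#' variation, and publication years uniform over 2000-2022.
#'
#' @param n_docs Number of documents (at least the number of topics).
#' @param topics List of [topic_spec()] objects with disjoint keyword sets.
#' @param background_vocab Background terms disjoint from all keywords.
#' @param doc_length_mean Mean document length in tokens (>= 20).
#' @param entity_lexicon An [entity_lexicon()] of plantable entities.
#' @param mention_rate Expected planted mentions per document (Poisson).
#' @param synonym_prob Probability a planted mention uses a non-preferred
#'   synonym.
#' @param year_range Integer `c(min_year, max_year)`.
#' @param seed Integer seed; the generator is fully determined by it.
#' @param topic_weights Optional sampling weights over topics (default
#'   uniform).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_docs,
                             topics = default_topics(),
                             background_vocab = default_background_vocab(),
                             doc_length_mean = 120L,
                             entity_lexicon = synthetic_lexicon(),
                             mention_rate = 1,
                             synonym_prob = 0.3,
                             year_range = c(2000L, 2022L),
                             seed = 0L,
                             topic_weights = NULL) {
  n_docs <- as.integer(n_docs)
  if (n_docs < length(topics)) stop("n_docs must be >= the number of topics")
  if (doc_length_mean < 20) stop("doc_length_mean must be >= 20")
  if (mention_rate < 0) stop("mention_rate must be non-negative")
  if (synonym_prob < 0 || synonym_prob > 1) stop("synonym_prob must lie in [0, 1]")
  year_range <- as.integer(year_range)
  if (length(year_range) != 2L || year_range[1] > year_range[2]) {
    stop("year_range must be c(min_year, max_year) with min <= max")
  }
  kw <- lapply(topics, `[[`, "keywords")
  all_kw <- unlist(kw, use.names = FALSE)
  if (anyDuplicated(all_kw)) {
    stop("topic keyword sets must be pairwise disjoint")
  }
  if (length(intersect(all_kw, background_vocab))) {
    stop("background vocabulary must be disjoint from topic keywords")
  }
  if (!is.null(topic_weights) && length(topic_weights) != length(topics)) {
    stop("topic_weights must match the number of topics")
  }
  structure(list(
    n_docs = n_docs, topics = topics, background_vocab = background_vocab,
    doc_length_mean = doc_length_mean, entity_lexicon = entity_lexicon,
    mention_rate = mention_rate, synonym_prob = synonym_prob,
    year_range = year_range, seed = as.integer(seed),
    topic_weights = topic_weights
  ), class = "generator_config")
}

.journal_pool <- c("J Proteome Res", "Nutrients", "Mol Cell Proteomics",
                   "Food Chem", "Am J Clin Nutr")

#' Generate a synthetic corpus with ground truth
#'
#' Each document samples a topic (uniformly, or by `topic_weights`), a
#' Poisson token count (truncated at 20), and i.i.d. tokens: with the
#' topic's `keyword_weight` probability a uniform topic keyword, otherwise a
#' uniform background term. Tokens are chunked into sentences of 8-15
#' tokens (uniform) terminated by ". ", the first token of each sentence is
#' capitalized, and a Poisson(`mention_rate`) number of entity surface forms
#' (preferred label, or a non-preferred synonym with probability
#' `synonym_prob`) are spliced in as whole tokens, never at sentence start
#' and never across a sentence boundary, with exact character spans
#' recorded. Fully determined by `config$seed`; per-document substreams are
#' derived from `(seed, document index)`, so a generated prefix is stable
#' when only `n_docs` changes.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (a [corpus()], not sentencized) and `truth`:
#'   list with `topics` (named integer vector doc_id -> topic_id) and
#'   `mentions` (tibble `doc_id`, `preflabel`, `type`, `start`, `end`,
#'   `surface` with 0-based half-open document-level spans).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_docs
  topics <- config$topics
  n_topics <- length(topics)
  lex <- config$entity_lexicon
  tw <- config$topic_weights
  set.seed(config$seed)
  doc_seeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)

  doc_rows <- vector("list", n)
  truth_topic <- integer(n)
  mention_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(doc_seeds[i])
    doc_id <- sprintf("SYN%05d", i)
    t_idx <- if (is.null(tw)) sample.int(n_topics, 1L) else
      sample.int(n_topics, 1L, prob = tw)
    spec <- topics[[t_idx]]
    len <- max(20L, stats::rpois(1L, config$doc_length_mean))
    is_kw <- stats::runif(len) < spec$keyword_weight
    tok <- character(len)
    if (any(is_kw)) tok[is_kw] <- sample(spec$keywords, sum(is_kw), replace = TRUE)
    if (any(!is_kw)) tok[!is_kw] <- sample(config$background_vocab, sum(!is_kw),
                                           replace = TRUE)

    # chunk into sentences of 8-15 tokens
    sizes <- integer(0)
    used <- 0L
    while (used < len) {
      s <- sample(8:15, 1L)
      s <- min(s, len - used)
      sizes <- c(sizes, s)
      used <- used + s
    }
    # each sentence: list of parts; a part is a token vector plus an
    # optional mention id (planted surfaces stay whole)
    sentences <- lapply(split(tok, rep(seq_along(sizes), sizes)), function(tt) {
      lapply(tt, function(w) list(tokens = w, mention = NA_integer_))
    })

    n_m <- stats::rpois(1L, config$mention_rate)
    planted <- vector("list", n_m)
    if (n_m > 0L && nrow(lex)) {
      for (mi in seq_len(n_m)) {
        e <- sample.int(nrow(lex), 1L)
        syns <- setdiff(lex$synonyms[[e]], lex$preflabel[e])
        use_syn <- length(syns) > 0L && stats::runif(1L) < config$synonym_prob
        surface <- if (use_syn) {
          if (length(syns) == 1L) syns else sample(syns, 1L)
        } else lex$preflabel[e]
        si <- sample.int(length(sentences), 1L)
        slot <- sample.int(length(sentences[[si]]), 1L)  # insert after >= 1st part
        part <- list(tokens = strsplit(surface, " ", fixed = TRUE)[[1]],
                     mention = mi)
        sentences[[si]] <- append(sentences[[si]], list(part), after = slot)
        planted[[mi]] <- list(preflabel = lex$preflabel[e], type = lex$type[e],
                              surface = surface)
      }
    }

    # render, tracking character offsets (0-based half-open)
    off <- 0L
    spans <- vector("list", n_m)
    sent_texts <- character(length(sentences))
    for (si in seq_along(sentences)) {
      words <- character(0)
      first <- TRUE
      for (part in sentences[[si]]) {
        w <- part$tokens
        if (first) {
          substr(w[1], 1L, 1L) <- toupper(substr(w[1], 1L, 1L))
          first <- FALSE
        }
        start <- off + sum(nchar(words)) + length(words)  # +1 space per word
        if (!is.na(part$mention)) {
          width <- sum(nchar(w)) + length(w) - 1L
          spans[[part$mention]] <- c(start, start + width)
        }
        words <- c(words, w)
      }
      sent_texts[si] <- paste0(paste(words, collapse = " "), ".")
      off <- off + nchar(sent_texts[si]) + 1L  # "+1": joining space
    }
    abstract <- paste(sent_texts, collapse = " ")

    year <- sample(seq(config$year_range[1], config$year_range[2]), 1L)
    sjr <- round(stats::runif(1L, 0.2, 3.5), 3L)
    journal <- sample(.journal_pool, 1L)
    tags <- character(0)
    if (stats::runif(1L) < 0.7) {
      tags <- "protnutr_mh"
      if (stats::runif(1L) < 0.4) tags <- c(tags, "protnutr_majr")
    }
    if (stats::runif(1L) < 0.6) tags <- c(tags, "protnutr_ab")
    if (!length(tags)) tags <- "protnutr_ab"

    doc_rows[[i]] <- tibble::tibble(
      doc_id = doc_id, title = sprintf("Synthetic abstract %05d", i),
      abstract = abstract, full_text = "", year = year,
      journal = journal, sjr = sjr, query_tags = list(tags)
    )
    truth_topic[i] <- spec$topic_id
    if (n_m > 0L && nrow(lex)) {
      mention_rows[[i]] <- tibble::tibble(
        doc_id = doc_id,
        preflabel = vapply(planted, `[[`, "", "preflabel"),
        type = vapply(planted, `[[`, "", "type"),
        start = vapply(spans, `[`, 0, 1L),
        end = vapply(spans, `[`, 0, 2L),
        surface = vapply(planted, `[[`, "", "surface")
      )
    }
  }

  docs <- dplyr::bind_rows(doc_rows)
  corp <- corpus(docs)
  truth_mentions <- dplyr::bind_rows(mention_rows)
  if (!nrow(truth_mentions)) {
    truth_mentions <- tibble::tibble(doc_id = character(0), preflabel = character(0),
                                     type = character(0), start = numeric(0),
                                     end = numeric(0), surface = character(0))
  }
  truth_mentions$start <- as.integer(truth_mentions$start)
  truth_mentions$end <- as.integer(truth_mentions$end)
  truth <- list(topics = stats::setNames(truth_topic, docs$doc_id),
                mentions = truth_mentions)
  list(corpus = corp, truth = truth)
}

#' Document counts of planted entities
#'
#' Ground-truth oracle for the annotator: the number of distinct documents
#' in which each preferred label was planted (document-level, so repeated
#' mentions in one document count once).
#'
#' @param truth The `truth` element of [generate_corpus()].
#' @return Tibble `(preflabel, type, n_documents)` sorted by descending
#'   count, ties alphabetical.
#' @export
truth_entity_doc_counts <- function(truth) {
  entity_document_counts(truth$mentions)
}

#' Write / read generator ground truth as JSON
#'
#' @param truth The `truth` element of [generate_corpus()].
#' @param path Output path.
#' @return Invisibly, `path` (writer); the truth list (reader).
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(
    topics = as.list(truth$topics),
    mentions = truth$mentions
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  topics <- unlist(payload$topics)
  mentions <- tibble::as_tibble(payload$mentions)
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  list(topics = stats::setNames(as.integer(topics), names(topics)),
       mentions = mentions)
}
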