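#' Pipeline configuration
#'
#' Exactly one of `corpus_path` or `generator` must be supplied: the
#' pipeline either reads an existing corpus JSON file or simulates one with
#' [generate_corpus()]. All stage parameters live here so that a single
#' config plus a seed fully determines every output file.
#'
#' @param corpus_path Path to a corpus JSON file, or `NULL`.
#' @param generator List of [generator_config()] arguments (e.g. `n_docs`,
#'   `mention_rate`), or `NULL`. The pipeline seed is injected.
#' @param lexicon_path Path to a lexicon TSV; defaults to
#'   [synthetic_lexicon()] when simulating.
#' @param category_map_path Optional path to a category map TSV.
#' @param stopwords_path Optional path to a one-term-per-line stop-word
#'   file; defaults to [default_stopwords()].
#' @param type_pair Entity types for the comention stage.
#' @param ngram_max,min_df Tokenization parameters (see
#'   [tokenize_corpus()]).
#' @param k Number of clusters (>= 2).
#' @param k_range K values for the WSS diagnostic curve.
#' @param n_restarts K-means restarts.
#' @param min_support Distinct-document support threshold for network
#'   edges.
#' @param alpha Enrichment reporting cut-off (`p < alpha`).
#' @param perplexity t-SNE perplexity (capped below the document count at
#'   run time).
#' @param embed_iter t-SNE gradient iterations.
#' @param seed Integer seed fanned out to every stage.
#' @param out_dir Output directory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus_path = NULL, generator = NULL,
                            lexicon_path = NULL, category_map_path = NULL,
                            stopwords_path = NULL,
                            type_pair = c("protein", "disease"),
                            ngram_max = 4L, min_df = 2L,
                            k = 7L, k_range = 2:10, n_restarts = 10L,
                            min_support = 5L, alpha = 0.1,
                            perplexity = 30, embed_iter = 500L,
                            seed = 0L, out_dir = "litminer_out") {
  if (is.null(corpus_path) == is.null(generator)) {
    stop("exactly one of corpus_path or generator must be set")
  }
  if (k < 2L) stop("k must be >= 2")
  structure(list(
    corpus_path = corpus_path, generator = generator,
    lexicon_path = lexicon_path, category_map_path = category_map_path,
    stopwords_path = stopwords_path, type_pair = type_pair,
    ngram_max = as.integer(ngram_max), min_df = as.integer(min_df),
    k = as.integer(k), k_range = as.integer(k_range),
    n_restarts = as.integer(n_restarts), min_support = as.integer(min_support),
    alpha = alpha, perplexity = perplexity, embed_iter = as.integer(embed_iter),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds named [pipeline_config()] arguments; `.json` files are
#' parsed as JSON, anything else as YAML.
#'
#' @param path Config file path.
#' @param seed Optional seed overriding the file's value.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(seed)) vals$seed <- as.integer(seed)
  if (!is.null(vals$k_range) && length(vals$k_range) == 2L) {
    vals$k_range <- seq(vals$k_range[1], vals$k_range[2])
  }
  do.call(pipeline_config, vals)
}

run_stage <- function(stage, out_files, fun) {
  tryCatch(fun(), error = function(e) {
    existing <- out_files[file.exists(out_files)]
    if (length(existing)) unlink(existing)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the machine-reading pipeline end to end
#'
#' Executes simulate/load, sentencize, tag, comention, vectorize, cluster,
#' themes, embed, trends and enrichment, writing every report artifact to
#' `config$out_dir` and a JSON manifest recording the inputs, the seed,
#' per-stage row counts and the MD5 hash of every output file. Two runs
#' with the same config and seed produce byte-identical outputs. A failing
#' stage removes its partial outputs and raises an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out, ...)
  counts <- list()

  # -- load or simulate ----------------------------------------------------
  truth <- NULL
  stage_files <- fp(c("corpus.json", "ground_truth.json", "lexicon.tsv"))
  env <- run_stage("load", stage_files, function() {
    if (!is.null(config$generator)) {
      gen_args <- config$generator
      gen_args$seed <- config$seed
      gen <- generate_corpus(do.call(generator_config, gen_args))
      write_corpus(gen$corpus, fp("corpus.json"))
      write_ground_truth(gen$truth, fp("ground_truth.json"))
      lexicon <- if (is.null(config$lexicon_path)) synthetic_lexicon() else
        read_lexicon(config$lexicon_path)
      write_lexicon(lexicon, fp("lexicon.tsv"))
      list(corp = gen$corpus, lexicon = lexicon, truth = gen$truth)
    } else {
      list(corp = read_corpus(config$corpus_path), lexicon = NULL,
           truth = NULL)
    }
  })
  corp <- env$corp
  lexicon <- env$lexicon
  truth <- env$truth
  counts$documents <- nrow(corp$documents)

  corp <- run_stage("sentencize", character(0), function() sentencize(corp))
  counts$sentences <- nrow(corp$sentences)

  mentions <- run_stage("tag", fp(c("mentions.tsv", "entity_counts.tsv")), function() {
    if (is.null(lexicon)) {
      if (is.null(config$lexicon_path)) {
        stop("lexicon_path is required when reading an existing corpus")
      }
      lexicon <- read_lexicon(config$lexicon_path)
    }
    m <- tag_entities(corp, lexicon)
    write_tsv_file(m, fp("mentions.tsv"))
    write_tsv_file(entity_document_counts(m), fp("entity_counts.tsv"))
    list(mentions = m, lexicon = lexicon)
  })
  lexicon <- mentions$lexicon
  mentions <- mentions$mentions
  counts$mentions <- nrow(mentions)

  records <- run_stage("comention", fp(c("comention_records.tsv", "comention_table.tsv",
                                         "comention_edges.tsv", "comention_network.graphml")),
                       function() {
    rec <- extract_comentions(mentions, corp, type_pair = config$type_pair)
    write_tsv_file(rec, fp("comention_records.tsv"))
    if (identical(sort(config$type_pair), c("disease", "protein"))) {
      write_tsv_file(comention_table(rec), fp("comention_table.tsv"))
    }
    net <- build_network(rec, min_support = config$min_support, mentions = mentions)
    write_comention_network(net, fp("comention_network.graphml"),
                            fp("comention_edges.tsv"))
    rec
  })
  counts$comention_records <- nrow(records)

  stopwords <- if (is.null(config$stopwords_path)) default_stopwords() else
    readLines(config$stopwords_path, encoding = "UTF-8", warn = FALSE)
  mat <- run_stage("vectorize", character(0), function() {
    tfidf(tokenize_corpus(corp, ngram_max = config$ngram_max,
                          stopwords = stopwords, min_df = config$min_df))
  })
  counts$vocabulary <- length(mat$vocabulary)

  clust <- run_stage("cluster", fp(c("assignments.tsv", "wss_curve.tsv")), function() {
    cl <- kmeans_docs(mat, config$k, seed = config$seed,
                      n_restarts = config$n_restarts)
    write_tsv_file(tibble::tibble(doc_id = names(cl$labels),
                                  cluster = unname(cl$labels)),
                   fp("assignments.tsv"))
    wc <- wss_curve(mat, config$k_range, seed = config$seed,
                    n_restarts = config$n_restarts)
    curve <- wc$curve
    curve$elbow <- as.integer(curve$k == wc$elbow & !is.na(wc$elbow))
    write_tsv_file(curve, fp("wss_curve.tsv"))
    cl
  })
  counts$clusters <- clust$k

  themes <- run_stage("themes", fp(c("themes.tsv", "theme_terms.tsv")), function() {
    th <- cluster_themes(mat, clust, corp)
    write_tsv_file(th$summary, fp("themes.tsv"))
    write_tsv_file(th$terms, fp("theme_terms.tsv"))
    th
  })
  counts$themes <- nrow(themes$summary)

  run_stage("embed", fp("embedding.tsv"), function() {
    perp <- min(config$perplexity, (nrow(corp$documents) - 1) / 3)
    emb <- embed_2d(mat, seed = config$seed, perplexity = perp,
                    max_iter = config$embed_iter)
    emb$cluster <- unname(clust$labels[emb$doc_id])
    emb$sjr <- corp$documents$sjr[match(emb$doc_id, corp$documents$doc_id)]
    write_tsv_file(emb, fp("embedding.tsv"))
    emb
  })
  counts$embedded <- nrow(corp$documents)

  trend <- run_stage("trends", fp("year_trend.tsv"), function() {
    tr <- cluster_year_trend(clust, corp)
    write_tsv_file(tr, fp("year_trend.tsv"))
    tr
  })
  counts$trend_rows <- nrow(trend)

  enr <- run_stage("enrichment", fp(c("entity_enrichment.tsv", "category_enrichment.tsv")),
                   function() {
    ee <- cluster_entity_enrichment(mentions, clust, type_filter = "protein",
                                    alpha = config$alpha)
    write_tsv_file(ee, fp("entity_enrichment.tsv"))
    if (!is.null(config$category_map_path)) {
      catmap <- read_category_map(config$category_map_path)
      pm <- unique(mentions[mentions$type == "protein", c("doc_id", "preflabel")])
      pm$cluster <- clust$labels[pm$doc_id]
      ce_sets <- split(pm$preflabel, pm$cluster)
      bg <- lexicon$preflabel[lexicon$type == "protein"]
      ce <- category_enrichment(ce_sets, catmap, bg, alpha = config$alpha)
      write_tsv_file(ce, fp("category_enrichment.tsv"))
    }
    ee
  })
  counts$enriched <- nrow(enr)

  files <- sort(setdiff(list.files(out), "manifest.json"), method = "radix")
  hashes <- as.character(tools::md5sum(fp(files)))
  manifest <- list(
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    stage_counts = counts,
    files = stats::setNames(as.list(hashes), files)
  )
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(fp("manifest.json"), open = "wb")
  writeLines(json, con, useBytes = TRUE)
  close(con)
  invisible(manifest)
}
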