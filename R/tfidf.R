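#' Minimal English stop-word list
#'
#' Function words only. Thematic cluster keywords in the literature keep
#' generic domain words ("study", "human"), so the default list deliberately
#' removes nothing but grammatical glue; pass your own vector to
#' [tokenize_corpus()] for a stricter policy.
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "nor", "of", "in", "on", "at",
    "to", "for", "with", "by", "from", "as", "is", "are", "was", "were",
    "be", "been", "being", "am", "do", "does", "did", "have", "has", "had",
    "that", "this", "these", "those", "it", "its", "we", "our", "ours",
    "they", "their", "them", "he", "she", "his", "her", "you", "your",
    "not", "no", "than", "then", "so", "if", "because", "while", "during",
    "between", "into", "through", "about", "against", "after", "before",
    "above", "below", "over", "under", "again", "further", "once", "here",
    "there", "when", "where", "why", "how", "all", "any", "both", "each",
    "few", "more", "most", "other", "some", "such", "only", "own", "same",
    "too", "very", "can", "will", "just", "also", "which", "who", "whom",
    "what", "would", "could", "should", "may", "might", "must", "upon")
}

# Lowercase, keep maximal runs of letters/digits/hyphen of length >= 2,
# drop stop words.
tokenize_text <- function(text, stopwords = character(0)) {
  x <- tolower(text)
  tok <- regmatches(x, gregexpr("[[:alnum:]-]+", x))[[1]]
  tok <- tok[nchar(tok) >= 2L]
  if (length(stopwords)) tok <- tok[!tok %in% stopwords]
  tok
}

add_ngrams <- function(tok, ngram_max) {
  out <- tok
  if (ngram_max >= 2L && length(tok) >= 2L) {
    for (n in 2:min(ngram_max, length(tok))) {
      idx <- seq_len(length(tok) - n + 1L)
      gram <- tok[idx]
      for (s in 1:(n - 1L)) gram <- paste(gram, tok[idx + s])
      out <- c(out, gram)
    }
  }
  out
}

#' Tokenize a corpus into term sequences and a vocabulary
#'
#' Lowercases each document's analysis field, extracts tokens (maximal runs
#' of letters, digits and hyphens, length at least 2), removes stop words,
#' and adds n-grams of adjacent surviving tokens up to `ngram_max` (so
#' multi-word themes such as "milk fat globule membrane" can become single
#' vocabulary terms). Terms seen in fewer than `min_df` documents are dropped
#' from the vocabulary; the vocabulary is sorted lexicographically (C
#' collation) for determinism.
#'
#' @param corp A [corpus()] object.
#' @param ngram_max Maximum n-gram length, 1 to 4.
#' @param stopwords Character vector of stop words
#'   (e.g. [default_stopwords()]).
#' @param min_df Minimum document frequency for a vocabulary term.
#' @return Object of class `corpus_tokens`: list with `doc_ids`, `terms`
#'   (list of per-document term sequences, n-grams included) and
#'   `vocabulary`.
#' @export
tokenize_corpus <- function(corp, ngram_max = 4L, stopwords = default_stopwords(),
                            min_df = 2L) {
  validate_corpus(corp)
  stopifnot(ngram_max >= 1L, ngram_max <= 4L, min_df >= 0L)
  docs <- corp$documents
  if (!nrow(docs)) stop("corpus is empty")
  texts <- doc_text(docs$abstract, docs$full_text)
  terms <- lapply(texts, function(t) add_ngrams(tokenize_text(t, stopwords), ngram_max))
  df <- table(unlist(lapply(terms, unique), use.names = FALSE))
  vocab <- names(df)[as.integer(df) >= min_df]
  vocab <- sort(vocab, method = "radix")
  structure(list(doc_ids = docs$doc_id, terms = terms, vocabulary = vocab),
            class = "corpus_tokens")
}

#' tf-idf document-term matrix
#'
#' Computes the term-frequency--inverse-document-frequency weighting with
#' the smoothed idf variant `idf(t) = ln((1 + N) / (1 + df(t))) + 1` (N =
#' number of documents, df = document frequency), raw term counts as tf, and
#' each document row scaled to unit Euclidean norm. A term's weight is
#' highest when it is common in a document and rare in the rest of the
#' corpus.
#'
#' @param tokens A [tokenize_corpus()] result.
#' @return Object of class `tfidf_matrix`: list with `weights` (sparse
#'   documents x terms `dgCMatrix` with unit-norm rows), `idf` (named
#'   vector), `vocabulary` and `doc_ids`.
#' @export
tfidf <- function(tokens) {
  stopifnot(inherits(tokens, "corpus_tokens"))
  vocab <- tokens$vocabulary
  if (!length(vocab)) stop("vocabulary is empty")
  n_docs <- length(tokens$doc_ids)

  trip <- lapply(seq_len(n_docs), function(d) {
    idx <- match(tokens$terms[[d]], vocab)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(NULL)
    r <- rle(sort(idx))
    list(i = rep.int(d, length(r$values)), j = r$values, x = r$lengths)
  })
  ii <- unlist(lapply(trip, `[[`, "i"), use.names = FALSE)
  jj <- unlist(lapply(trip, `[[`, "j"), use.names = FALSE)
  xx <- unlist(lapply(trip, `[[`, "x"), use.names = FALSE)
  if (is.null(ii)) { ii <- integer(0); jj <- integer(0); xx <- integer(0) }
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(n_docs, length(vocab)),
                                 dimnames = list(tokens$doc_ids, vocab))
  row_nnz <- Matrix::rowSums(counts > 0)
  if (any(row_nnz == 0)) {
    stop("document(s) with no vocabulary terms: ",
         paste(tokens$doc_ids[row_nnz == 0], collapse = ", "))
  }
  df <- Matrix::colSums(counts > 0)
  idf <- log((1 + n_docs) / (1 + df)) + 1
  w <- counts %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(w^2))
  w <- Matrix::Diagonal(x = 1 / norms) %*% w
  w <- methods::as(w, "CsparseMatrix")
  dimnames(w) <- list(tokens$doc_ids, vocab)
  structure(list(weights = w, idf = stats::setNames(as.numeric(idf), vocab),
                 vocabulary = vocab, doc_ids = tokens$doc_ids),
            class = "tfidf_matrix")
}

#' @export
print.tfidf_matrix <- function(x, ...) {
  cat(sprintf("<tfidf_matrix> %d documents x %d terms (%.2f%% nonzero)\n",
              nrow(x$weights), ncol(x$weights),
              100 * Matrix::nnzero(x$weights) / prod(dim(x$weights))))
  invisible(x)
}
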