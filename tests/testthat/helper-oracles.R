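# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (dense loops, exhaustive enumeration) so that a
# shared bug cannot hide.

# Brute-force tf-idf of the stated formula: raw counts, smoothed idf
# ln((1+N)/(1+df)) + 1, L2 row normalization.
bf_tfidf <- function(term_lists, vocab) {
  n <- length(term_lists)
  counts <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (d in seq_len(n)) {
    for (t in term_lists[[d]]) {
      if (t %in% vocab) counts[d, t] <- counts[d, t] + 1
    }
  }
  df <- colSums(counts > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  w <- counts
  for (d in seq_len(n)) {
    for (j in seq_along(vocab)) w[d, j] <- counts[d, j] * idf[j]
    nrm <- sqrt(sum(w[d, ]^2))
    if (nrm > 0) w[d, ] <- w[d, ] / nrm
  }
  w
}

# Exhaustive hypergeometric upper tail: enumerate every size-n subset of a
# background with K marked items, count subsets with >= k marked.
enum_hypergeom <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  hits <- colSums(matrix(subsets %in% marked, nrow = n))
  mean(hits >= k)
}

# Literal step-up rule: q_(i) = min_{j >= i} m p_(j) / j, mapped back.
stepup_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, m * p[ord[j]] / j)
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Small corpus from bare abstracts.
make_corpus <- function(abstracts, year = NA_integer_, sjr = NA_real_) {
  corpus(tibble::tibble(
    doc_id = sprintf("D%03d", seq_along(abstracts)),
    abstract = abstracts, year = year, sjr = sjr
  ))
}

# Tagger mentions with document-level span keys, for comparison with the
# generator's ground truth.
doc_span_keys <- function(mentions, corp) {
  ss <- corp$sentences
  off <- stats::setNames(ss$start, paste(ss$doc_id, ss$index))
  d0 <- mentions$start + unname(off[paste(mentions$doc_id, mentions$sentence_index)])
  paste(mentions$doc_id, d0, d0 + (mentions$end - mentions$start),
        mentions$preflabel)
}

truth_span_keys <- function(truth) {
  paste(truth$mentions$doc_id, truth$mentions$start, truth$mentions$end,
        truth$mentions$preflabel)
}

# Featureless protein lexicon (preflabel-only synonyms) for calibration runs.
plain_protein_lexicon <- function(n) {
  labs <- sprintf("GENE%02d", seq_len(n))
  entity_lexicon(labs, "protein", as.list(labs))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Majority-vote mapping cluster -> planted topic.
match_clusters_to_topics <- function(labels, topics) {
  topics <- topics[names(labels)]
  vapply(split(topics, labels), function(tt) {
    as.integer(names(sort(table(tt), decreasing = TRUE))[1])
  }, integer(1))
}
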