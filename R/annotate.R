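#' Tag and normalize entity mentions in a sentencized corpus
#'
#' Deterministic dictionary tagger: every synonym occurrence aligned to token
#' boundaries (a token boundary is the transition between word characters --
#' letters, digits, hyphen -- and anything else) is a candidate match.
#' Matching is case-insensitive for synonyms of at least 4 characters and
#' exact for shorter ones, which guards short gene symbols ("INS") against
#' ordinary words ("ins"). Overlapping candidates are resolved
#' leftmost-longest: earliest start wins, then the longest span, then lexicon
#' order. Each match is normalized to its `(preflabel, type)`.
#'
#' @param corp A sentencized [corpus()] (see [sentencize()]).
#' @param lexicon An [entity_lexicon()].
#' @return Tibble of mentions: `doc_id`, `sentence_index`, `start`, `end`
#'   (0-based half-open, sentence-local), `text_found`, `preflabel`, `type`.
#' @export
tag_entities <- function(corp, lexicon) {
  if (is.null(corp$sentences)) {
    stop("corpus is not sentencized; call sentencize() first")
  }
  sent <- corp$sentences
  empty <- tibble::tibble(doc_id = character(0), sentence_index = integer(0),
                          start = integer(0), end = integer(0),
                          text_found = character(0), preflabel = character(0),
                          type = character(0))
  if (!nrow(sent) || !nrow(lexicon)) return(empty)

  syn_tab <- data.frame(
    syn = unlist(lexicon$synonyms, use.names = FALSE),
    preflabel = rep(lexicon$preflabel, lengths(lexicon$synonyms)),
    type = rep(lexicon$type, lengths(lexicon$synonyms)),
    lex_index = rep(seq_len(nrow(lexicon)), lengths(lexicon$synonyms)),
    stringsAsFactors = FALSE
  )
  syn_tab$ci <- nchar(syn_tab$syn) >= 4L

  hits <- vector("list", nrow(syn_tab))
  for (j in seq_len(nrow(syn_tab))) {
    pat <- paste0("(?<![[:alnum:]-])", regex_escape(syn_tab$syn[j]),
                  "(?![[:alnum:]-])")
    m <- gregexpr(pat, sent$text, perl = TRUE, ignore.case = syn_tab$ci[j])
    found <- which(vapply(m, function(x) x[1L] != -1L, logical(1)))
    if (!length(found)) next
    hits[[j]] <- do.call(rbind, lapply(found, function(r) {
      st <- as.integer(m[[r]])
      data.frame(row = r, start1 = st,
                 len = attr(m[[r]], "match.length"), lex = j)
    }))
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) return(empty)

  # leftmost-longest resolution per sentence
  hits <- hits[order(hits$row, hits$start1, -hits$len,
                     syn_tab$lex_index[hits$lex]), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_row <- -1L
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$row[i] != last_row) {
      last_row <- hits$row[i]
      last_end <- 0L
    }
    if (hits$start1[i] > last_end) {
      keep[i] <- TRUE
      last_end <- hits$start1[i] + hits$len[i] - 1L
    }
  }
  hits <- hits[keep, , drop = FALSE]

  tibble::tibble(
    doc_id = sent$doc_id[hits$row],
    sentence_index = sent$index[hits$row],
    start = hits$start1 - 1L,
    end = hits$start1 - 1L + hits$len,
    text_found = substring(sent$text[hits$row], hits$start1,
                           hits$start1 + hits$len - 1L),
    preflabel = syn_tab$preflabel[hits$lex],
    type = syn_tab$type[hits$lex]
  )
}

#' Document-level entity frequency table
#'
#' Counts, for every preferred label, the number of distinct documents with
#' at least one mention, emulating corpus overview bar charts such as
#' "diseases with 50 or more articles".
#'
#' @param mentions Mention tibble from [tag_entities()].
#' @param min_count Drop rows mentioned in fewer documents than this.
#' @param type_filter Optional entity type (`"protein"` or `"disease"`).
#' @return Tibble `(preflabel, type, n_documents)` sorted by descending
#'   count, ties alphabetical.
#' @export
entity_document_counts <- function(mentions, min_count = 0L, type_filter = NULL) {
  m <- mentions
  if (!is.null(type_filter)) m <- m[m$type %in% type_filter, , drop = FALSE]
  m <- unique(m[, c("doc_id", "preflabel", "type")])
  if (!nrow(m)) {
    return(tibble::tibble(preflabel = character(0), type = character(0),
                          n_documents = integer(0)))
  }
  key <- paste(m$preflabel, m$type, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  counts <- tibble::tibble(
    preflabel = vapply(parts, `[`, "", 1L),
    type = vapply(parts, `[`, "", 2L),
    n_documents = as.integer(tab)
  )
  counts <- counts[counts$n_documents >= min_count, , drop = FALSE]
  counts[order(-counts$n_documents, counts$preflabel, method = "radix"), ]
}
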