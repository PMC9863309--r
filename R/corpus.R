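#' Construct a corpus object
#'
#' A corpus holds an ordered collection of documents (one publication each)
#' and, after [sentencize()] has been called, the sentence table derived from
#' the chosen text field of each document. The abstract is the analysis field
#' whenever it is non-empty; otherwise the full text is used.
#'
#' @param documents A data frame with columns `doc_id` (unique, non-empty),
#'   `title`, `abstract`, `full_text`, `year` (integer or `NA`), `journal`,
#'   `sjr` (non-negative or `NA`) and `query_tags` (list column of character
#'   vectors). Missing optional columns are filled with empty defaults.
#' @param sentences Optional sentence table as produced by [sentencize()].
#'
#' @return An object of class `corpus`: a list with elements `documents`
#'   (tibble) and `sentences` (tibble or `NULL`).
#' @export
corpus <- function(documents, sentences = NULL) {
  documents <- tibble::as_tibble(documents)
  defaults <- list(title = "", abstract = "", full_text = "",
                   year = NA_integer_, journal = "", sjr = NA_real_)
  for (nm in names(defaults)) {
    if (!nm %in% names(documents)) documents[[nm]] <- defaults[[nm]]
  }
  if (!"query_tags" %in% names(documents)) {
    documents$query_tags <- replicate(nrow(documents), character(0), simplify = FALSE)
  }
  documents$doc_id <- as.character(documents$doc_id)
  documents$year <- as.integer(documents$year)
  documents$sjr <- as.numeric(documents$sjr)
  obj <- structure(list(documents = documents, sentences = sentences),
                   class = "corpus")
  validate_corpus(obj)
  obj
}

validate_corpus <- function(x) {
  docs <- x$documents
  if (anyNA(docs$doc_id) || any(!nzchar(docs$doc_id))) {
    stop("corpus validation: empty doc_id")
  }
  dup <- docs$doc_id[duplicated(docs$doc_id)]
  if (length(dup)) {
    stop("corpus validation: duplicate doc_id ", paste(unique(dup), collapse = ", "))
  }
  no_text <- !nzchar(docs$abstract) & !nzchar(docs$full_text)
  if (any(no_text)) {
    stop("corpus validation: document ", paste(docs$doc_id[no_text], collapse = ", "),
         " has neither abstract nor full_text")
  }
  bad_year <- !is.na(docs$year) & (docs$year < 1800L | docs$year > 2100L)
  if (any(bad_year)) {
    stop("corpus validation: year out of range [1800, 2100] for document ",
         paste(docs$doc_id[bad_year], collapse = ", "))
  }
  if (!is.na(m <- match(FALSE, is.na(docs$sjr) | docs$sjr >= 0))) {
    stop("corpus validation: negative sjr for document ", docs$doc_id[m])
  }
  invisible(x)
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d documents", nrow(x$documents)))
  if (!is.null(x$sentences)) {
    cat(sprintf(", %d sentences", nrow(x$sentences)))
  } else {
    cat(" (not sentencized)")
  }
  cat("\n")
  invisible(x)
}

# Analysis text of one document: abstract preferred over full text.
doc_text <- function(abstract, full_text) {
  ifelse(nzchar(abstract), abstract, full_text)
}

#' Read a corpus from its JSON dialect
#'
#' The corpus file is a UTF-8 JSON array of objects with keys `doc_id`
#' (required), `title`, `abstract`, `full_text`, `year`, `journal`, `sjr` and
#' `query_tags` (array of strings). Absent optional keys are read as empty
#' strings / missing values. Sentences are not populated; call [sentencize()].
#'
#' @param path Path to a corpus JSON file.
#' @return A [corpus()] object with documents in file order.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  recs <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed corpus JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(recs)) stop("corpus JSON must be a top-level array of objects")
  get_chr <- function(r, key) {
    v <- r[[key]]
    if (is.null(v)) "" else as.character(v)
  }
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r[["doc_id"]]) || !nzchar(as.character(r[["doc_id"]]))) {
      stop("corpus record ", i, ": missing required field 'doc_id'")
    }
    tibble::tibble(
      doc_id = as.character(r[["doc_id"]]),
      title = get_chr(r, "title"),
      abstract = get_chr(r, "abstract"),
      full_text = get_chr(r, "full_text"),
      year = if (is.null(r[["year"]])) NA_integer_ else as.integer(r[["year"]]),
      journal = get_chr(r, "journal"),
      sjr = if (is.null(r[["sjr"]])) NA_real_ else as.numeric(r[["sjr"]]),
      query_tags = list(as.character(unlist(r[["query_tags"]], use.names = FALSE)))
    )
  })
  docs <- dplyr::bind_rows(rows)
  if (nrow(docs)) {
    no_text <- !nzchar(docs$abstract) & !nzchar(docs$full_text)
    if (any(no_text)) {
      stop("corpus record '", docs$doc_id[which(no_text)[1]],
           "': missing required field 'abstract' (or 'full_text')")
    }
  }
  corpus(docs)
}

#' Write a corpus to its JSON dialect
#'
#' Writing is deterministic (two writes of the same corpus are byte-identical)
#' and round-trips through [read_corpus()]. Missing optional values are
#' omitted from the record.
#'
#' @param corp A [corpus()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corp, path) {
  validate_corpus(corp)
  docs <- corp$documents
  recs <- lapply(seq_len(nrow(docs)), function(i) {
    r <- list(doc_id = docs$doc_id[i])
    if (nzchar(docs$title[i])) r$title <- docs$title[i]
    if (nzchar(docs$abstract[i])) r$abstract <- docs$abstract[i]
    if (nzchar(docs$full_text[i])) r$full_text <- docs$full_text[i]
    if (!is.na(docs$year[i])) r$year <- docs$year[i]
    if (nzchar(docs$journal[i])) r$journal <- docs$journal[i]
    if (!is.na(docs$sjr[i])) r$sjr <- docs$sjr[i]
    tags <- docs$query_tags[[i]]
    if (length(tags)) r$query_tags <- I(tags)
    r
  })
  json <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, useBytes = TRUE)
  invisible(path)
}

# Protected abbreviations: a period ending one of these never splits.
.protected_abbrev_re <- "(?i)(^|[^a-z])(e\\.g|i\\.e|et[[:space:]]+al|vs|fig|ca)\\.$"

# Positions (1-based) of sentence-terminal punctuation in `text`.
sentence_breaks <- function(text) {
  cand <- gregexpr("[.!?](?=[[:space:]]+[[:upper:]0-9])", text, perl = TRUE)[[1]]
  if (cand[1] == -1L) return(integer(0))
  cand <- as.integer(cand)
  keep <- vapply(cand, function(p) {
    if (substr(text, p, p) != ".") return(TRUE)
    prev <- if (p > 1L) substr(text, p - 1L, p - 1L) else ""
    nxt <- sub("^[[:space:]]+", "", substr(text, p + 1L, min(nchar(text), p + 20L)))
    # a period between digits is a decimal-style number, never a boundary
    if (grepl("^[0-9]$", prev) && grepl("^[0-9]", nxt)) return(FALSE)
    head <- substr(text, max(1L, p - 9L), p)
    if (grepl(.protected_abbrev_re, head, perl = TRUE)) return(FALSE)
    # single capital initial, e.g. "J. Smith"
    if (grepl("(^|[^[:alpha:]])[[:upper:]]\\.$", head)) return(FALSE)
    TRUE
  }, logical(1))
  cand[keep]
}

# Partition `text` into sentence spans (0-based half-open offsets).
sentence_spans <- function(text) {
  n <- nchar(text)
  first_ns <- regexpr("[^[:space:]]", text)
  if (first_ns == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  last_ns <- as.integer(regexpr("[[:space:]]*$", text)) - 1L
  breaks <- sentence_breaks(text)
  breaks <- breaks[breaks < last_ns]
  starts <- integer(length(breaks) + 1L)
  ends <- integer(length(breaks) + 1L)
  starts[1] <- as.integer(first_ns) - 1L
  for (i in seq_along(breaks)) {
    ends[i] <- breaks[i]
    rel <- regexpr("[^[:space:]]", substr(text, breaks[i] + 1L, n))
    starts[i + 1L] <- breaks[i] + as.integer(rel) - 1L
  }
  ends[length(ends)] <- as.integer(last_ns)
  data.frame(start = starts, end = ends)
}

#' Split the documents of a corpus into sentences
#'
#' Rule-based sentencization of each document's analysis field (abstract,
#' else full text): a sentence ends at `.`, `!` or `?` followed by whitespace
#' and an uppercase letter or digit, except when the period closes a
#' protected abbreviation (`e.g.`, `i.e.`, `et al.`, `vs.`, `Fig.`, `ca.`, a
#' single capital initial) or sits between digits (decimal numbers such as
#' `4.9`). Offsets are 0-based half-open into the source field; degenerate
#' text yields a single sentence.
#'
#' @param corp A [corpus()] object.
#' @return The corpus with its `sentences` tibble populated
#'   (`doc_id`, `index`, `start`, `end`, `text`).
#' @export
sentencize <- function(corp) {
  validate_corpus(corp)
  docs <- corp$documents
  out <- vector("list", nrow(docs))
  for (i in seq_len(nrow(docs))) {
    txt <- doc_text(docs$abstract[i], docs$full_text[i])
    sp <- sentence_spans(txt)
    out[[i]] <- tibble::tibble(
      doc_id = docs$doc_id[i],
      index = seq_len(nrow(sp)) - 1L,
      start = sp$start,
      end = sp$end,
      text = substring(txt, sp$start + 1L, sp$end)
    )
  }
  corp$sentences <- dplyr::bind_rows(out)
  corp
}

#' Exclusive region counts for named sets of document IDs
#'
#' Computes the counts of every non-empty exclusive region of a Venn-style
#' overlap between named query result sets. The region signature is the
#' `&`-joined sorted list of set names containing the ID; the counts always
#' sum to the size of the union.
#'
#' @param id_sets Named list of character vectors of document IDs.
#' @return Named integer vector, one element per non-empty region.
#' @export
query_overlap <- function(id_sets) {
  if (!length(id_sets) || is.null(names(id_sets)) || any(!nzchar(names(id_sets)))) {
    stop("id_sets must be a non-empty named list")
  }
  ids <- unique(unlist(id_sets, use.names = FALSE))
  if (!length(ids)) return(stats::setNames(integer(0), character(0)))
  mem <- vapply(id_sets, function(s) ids %in% s, logical(length(ids)))
  if (!is.matrix(mem)) mem <- matrix(mem, nrow = length(ids),
                                     dimnames = list(NULL, names(id_sets)))
  sig <- apply(mem, 1L, function(r) paste(names(id_sets)[r], collapse = "&"))
  tab <- table(sig)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(names(out), method = "radix")]
}
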