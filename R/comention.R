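#' Extract sentence-level comention records
#'
#' For each sentence, every unordered pair of distinct preferred labels
#' mentioned in it yields one record, deduplicated per sentence (an entity
#' repeated in the same sentence is a single participant). Records are
#' canonical -- the two vertices are ordered lexicographically by preflabel
#' -- because comentions carry no direction. When `type_pair` is given (e.g.
#' `c("protein", "disease")`), only pairs whose unordered type combination
#' matches are kept.
#'
#' @param mentions Mention tibble from [tag_entities()].
#' @param corp The sentencized [corpus()] the mentions were tagged on.
#' @param type_pair Optional length-2 character vector of entity types.
#' @return Tibble of comention records: `doc_id`, `sentence_index`,
#'   `sentence_text`, `v1_preflabel`, `v1_type`, `v1_text_found`,
#'   `v2_preflabel`, `v2_type`, `v2_text_found`, `pub_year`.
#' @export
extract_comentions <- function(mentions, corp, type_pair = NULL) {
  if (is.null(corp$sentences)) stop("corpus is not sentencized")
  empty <- tibble::tibble(
    doc_id = character(0), sentence_index = integer(0),
    sentence_text = character(0),
    v1_preflabel = character(0), v1_type = character(0), v1_text_found = character(0),
    v2_preflabel = character(0), v2_type = character(0), v2_text_found = character(0),
    pub_year = integer(0)
  )
  if (!nrow(mentions)) return(empty)
  if (!is.null(type_pair) && length(type_pair) != 2L) {
    stop("type_pair must have exactly two elements")
  }

  m <- mentions[order(mentions$doc_id, mentions$sentence_index, mentions$start,
                      method = "radix"), ]
  # dedup: first occurrence of each preflabel within a sentence
  dk <- paste(m$doc_id, m$sentence_index, m$preflabel, m$type, sep = "\r")
  m <- m[!duplicated(dk), , drop = FALSE]

  sent_text <- stats::setNames(corp$sentences$text,
                               paste(corp$sentences$doc_id, corp$sentences$index, sep = "\r"))
  year <- stats::setNames(corp$documents$year, corp$documents$doc_id)

  groups <- split(seq_len(nrow(m)), paste(m$doc_id, m$sentence_index, sep = "\r"))
  want <- if (is.null(type_pair)) NULL else sort(type_pair)
  rows <- vector("list", length(groups))
  ri <- 0L
  for (g in groups) {
    if (length(g) < 2L) next
    pairs <- utils::combn(g, 2L)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      if (!is.null(want) && !identical(sort(c(m$type[i], m$type[j])), want)) next
      # canonical vertex order in C collation, independent of locale
      if (order(c(m$preflabel[i], m$preflabel[j]), method = "radix")[1L] == 2L) {
        tmp <- i; i <- j; j <- tmp
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        doc_id = m$doc_id[i], sentence_index = m$sentence_index[i],
        v1_preflabel = m$preflabel[i], v1_type = m$type[i], v1_text_found = m$text_found[i],
        v2_preflabel = m$preflabel[j], v2_type = m$type[j], v2_text_found = m$text_found[j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!ri) return(empty)
  rec <- dplyr::bind_rows(rows[seq_len(ri)])
  rec$sentence_text <- unname(sent_text[paste(rec$doc_id, rec$sentence_index, sep = "\r")])
  rec$pub_year <- unname(year[rec$doc_id])
  rec <- rec[order(rec$doc_id, rec$sentence_index, rec$v1_preflabel, rec$v2_preflabel,
                   method = "radix"), ]
  tibble::as_tibble(rec[, c("doc_id", "sentence_index", "sentence_text",
                            "v1_preflabel", "v1_type", "v1_text_found",
                            "v2_preflabel", "v2_type", "v2_text_found", "pub_year")])
}

#' Build the comention network
#'
#' Edge support is counted at the distinct-document level: the weight of an
#' edge is the number of unique publications comentioning the two entities,
#' and edges below `min_support` are removed (a network figure restricted to
#' pairs with five or more supporting references uses `min_support = 5`).
#' Node weight is the number of distinct documents mentioning the entity --
#' computed from `mentions` when supplied, else from the full record set.
#' Isolated nodes are dropped.
#'
#' @param records Comention records from [extract_comentions()].
#' @param min_support Minimum distinct-document support for an edge.
#' @param mentions Optional mention tibble for corpus-wide node weights.
#' @return Object of class `comention_network`: list with `nodes`
#'   (`preflabel`, `type`, `weight`), `edges` (`v1`, `v2`, `weight`),
#'   `graph` (igraph), and the supporting `records` of retained edges.
#' @export
build_network <- function(records, min_support = 0L, mentions = NULL) {
  pair_key <- paste(records$v1_preflabel, records$v2_preflabel, sep = "\r")
  pd <- unique(data.frame(key = pair_key, doc = records$doc_id,
                          v1 = records$v1_preflabel, v2 = records$v2_preflabel,
                          stringsAsFactors = FALSE))
  wt <- table(pd$key)
  keep_keys <- names(wt)[as.integer(wt) >= min_support]
  edges <- unique(pd[pd$key %in% keep_keys, c("key", "v1", "v2")])
  edges$weight <- as.integer(wt[edges$key])
  edges <- edges[order(edges$v1, edges$v2, method = "radix"), c("v1", "v2", "weight")]
  rownames(edges) <- NULL

  kept <- records[pair_key %in% keep_keys, , drop = FALSE]
  node_ids <- unique(c(edges$v1, edges$v2))
  types <- stats::setNames(
    c(records$v1_type, records$v2_type),
    c(records$v1_preflabel, records$v2_preflabel)
  )
  if (is.null(mentions)) {
    long <- rbind(
      data.frame(preflabel = records$v1_preflabel, doc = records$doc_id),
      data.frame(preflabel = records$v2_preflabel, doc = records$doc_id)
    )
  } else {
    long <- data.frame(preflabel = mentions$preflabel, doc = mentions$doc_id)
  }
  long <- unique(long)
  nw <- table(long$preflabel)
  nodes <- tibble::tibble(
    preflabel = sort(node_ids, method = "radix"),
    type = unname(types[sort(node_ids, method = "radix")]),
    weight = as.integer(nw[sort(node_ids, method = "radix")])
  )
  g <- igraph::graph_from_data_frame(
    d = edges, directed = FALSE,
    vertices = data.frame(name = nodes$preflabel, type = nodes$type,
                          weight = nodes$weight, stringsAsFactors = FALSE)
  )
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges),
                 graph = g, records = kept),
            class = "comention_network")
}

#' @export
print.comention_network <- function(x, ...) {
  cat(sprintf("<comention_network> %d nodes, %d edges (%d supporting records)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$records)))
  invisible(x)
}

#' Tabular protein-disease comention report
#'
#' One row per comention record with the publication ID, the extracted
#' sentence, the publication date and the two entities, in the layout of an
#' interactive comention appendix table. Requires records from a
#' protein-disease extraction.
#'
#' @param records Comention records from
#'   `extract_comentions(..., type_pair = c("protein", "disease"))`.
#' @return Tibble `(pmid, sentence, date, gene_protein, disease)`.
#' @export
comention_table <- function(records) {
  cols <- c("pmid", "sentence", "date", "gene_protein", "disease")
  if (!nrow(records)) {
    out <- tibble::tibble(pmid = character(0), sentence = character(0),
                          date = integer(0), gene_protein = character(0),
                          disease = character(0))
    return(out)
  }
  ok <- (records$v1_type == "protein" & records$v2_type == "disease") |
    (records$v1_type == "disease" & records$v2_type == "protein")
  if (!all(ok)) {
    stop("comention_table requires protein-disease records; found pair types ",
         paste(unique(paste(records$v1_type, records$v2_type)[!ok]), collapse = "; "))
  }
  prot <- ifelse(records$v1_type == "protein", records$v1_preflabel, records$v2_preflabel)
  dis <- ifelse(records$v1_type == "disease", records$v1_preflabel, records$v2_preflabel)
  tibble::tibble(pmid = records$doc_id, sentence = records$sentence_text,
                 date = records$pub_year, gene_protein = prot, disease = dis)
}

#' Export a comention network
#'
#' Writes the network as GraphML (node attributes `type`, `weight`; edge
#' attribute `weight`) and, optionally, an edge-list TSV.
#'
#' @param network A [build_network()] result.
#' @param graphml_path Output GraphML path.
#' @param edges_path Optional edge-list TSV path.
#' @return Invisibly, `graphml_path`.
#' @export
write_comention_network <- function(network, graphml_path, edges_path = NULL) {
  igraph::write_graph(network$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path)) write_tsv_file(network$edges, edges_path)
  invisible(graphml_path)
}
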