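#' Construct an entity lexicon
#'
#' A lexicon maps surface strings (synonyms) to a preferred label and an
#' entity type, the normalization target under which all synonyms of one
#' entity are collapsed. The preferred label is always included among its own
#' synonyms (it is added if absent). `external_id` carries the identifier of
#' the normalization vocabulary (NCBI gene ID for proteins, MeSH/DOID for
#' diseases); it is passthrough metadata.
#'
#' @param preflabel Character vector of preferred labels.
#' @param type Character vector, each `"protein"` or `"disease"`. Genes and
#'   proteins are not distinguished.
#' @param synonyms List of character vectors of surface forms (one element
#'   per entry).
#' @param external_id Character vector of external identifiers (optional).
#' @return A tibble of class `entity_lexicon` with columns `preflabel`,
#'   `type`, `external_id`, `synonyms` (list column).
#' @export
entity_lexicon <- function(preflabel, type, synonyms, external_id = "") {
  preflabel <- as.character(preflabel)
  type <- as.character(type)
  if (length(type) == 1L) type <- rep(type, length(preflabel))
  if (length(external_id) == 1L) external_id <- rep(external_id, length(preflabel))
  if (!is.list(synonyms)) synonyms <- list(synonyms)
  stopifnot(length(type) == length(preflabel), length(synonyms) == length(preflabel))
  bad_type <- setdiff(unique(type), c("protein", "disease"))
  if (length(bad_type)) stop("unknown entity type: ", paste(bad_type, collapse = ", "))
  synonyms <- lapply(seq_along(preflabel), function(i) {
    s <- unique(as.character(synonyms[[i]]))
    if (any(!nzchar(s))) stop("empty synonym for entry '", preflabel[i], "'")
    if (!preflabel[i] %in% s) s <- c(preflabel[i], s)
    s
  })
  key <- paste(type, preflabel, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate preflabel within type: ",
         paste(preflabel[duplicated(key)], collapse = ", "))
  }
  structure(
    tibble::tibble(preflabel = preflabel, type = type,
                   external_id = as.character(external_id), synonyms = synonyms),
    class = c("entity_lexicon", class(tibble::tibble()))
  )
}

#' Read an entity lexicon from TSV
#'
#' Expected columns: `preflabel`, `type`, `external_id`, `synonyms`
#' (pipe-separated surface forms). Lines starting with `#` are comments;
#' the file is UTF-8.
#'
#' @param path Path to the lexicon TSV file.
#' @return An [entity_lexicon()].
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("preflabel", "type", "external_id", "synonyms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("lexicon TSV missing column(s): ", paste(miss, collapse = ", "))
  entity_lexicon(df$preflabel, df$type,
                 strsplit(df$synonyms, "|", fixed = TRUE), df$external_id)
}

#' Write an entity lexicon to TSV
#'
#' @param lexicon An [entity_lexicon()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- data.frame(
    preflabel = lexicon$preflabel,
    type = lexicon$type,
    external_id = lexicon$external_id,
    synonyms = vapply(lexicon$synonyms, paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
  write_tsv_file(df, path)
  invisible(path)
}
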