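# Deterministic TSV writer shared by all export paths.
write_tsv_file <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.list(df[[j]])) {
    df[[j]] <- vapply(df[[j]], paste, "", collapse = "|")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Escape a literal string for use inside a perl regex.
regex_escape <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

# Coerce clustering input to a named 0-based integer label vector.
cluster_labels <- function(x) {
  if (inherits(x, "doc_clustering")) return(x$labels)
  if (is.null(names(x))) stop("cluster labels must be named by doc_id")
  stats::setNames(as.integer(x), names(x))
}
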