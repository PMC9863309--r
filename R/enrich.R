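#' Upper-tail hypergeometric probability
#'
#' One-sided overrepresentation p-value: the probability of observing at
#' least `k` marked items in a draw of `n` from a background of `N_bg` items
#' of which `K_bg` are marked,
#' `p = sum_{i=k}^{min(n, K_bg)} C(K_bg, i) C(N_bg - K_bg, n - i) / C(N_bg, n)`.
#' Equivalent to the one-sided Fisher exact test; evaluated through the
#' log-space-stable distribution function. `k = 0` returns exactly 1.
#' Vectorized over its arguments.
#'
#' @param k Observed marked count(s), `0 <= k <= min(n, K_bg)`.
#' @param n Draw (e.g. cluster) size, `n <= N_bg`.
#' @param K_bg Background marked count, `K_bg <= N_bg`.
#' @param N_bg Background size.
#' @return Numeric vector of p-values in (0, 1].
#' @export
hypergeom_upper <- function(k, n, K_bg, N_bg) {
  args <- cbind(k = k, n = n, K_bg = K_bg, N_bg = N_bg)
  k <- args[, "k"]; n <- args[, "n"]; K_bg <- args[, "K_bg"]; N_bg <- args[, "N_bg"]
  if (any(k < 0 | n < 0 | K_bg < 0 | N_bg < 0)) {
    stop("hypergeom_upper: negative argument")
  }
  if (any(n > N_bg | K_bg > N_bg)) {
    stop("hypergeom_upper: n and K_bg must not exceed N_bg")
  }
  if (any(k > pmin(n, K_bg))) {
    stop("hypergeom_upper: k must not exceed min(n, K_bg)")
  }
  p <- stats::phyper(k - 1, K_bg, N_bg - K_bg, n, lower.tail = FALSE)
  p[k == 0] <- 1
  unname(pmin(p, 1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR: `q_(i) = min_{j >= i} (m p_(j) / j)`, clipped at 1 and
#' mapped back to the input order. Adjusted values are never below the raw
#' p-values.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values in the same order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Shared engine: one enrichment row per (cluster, item).
enrich_rows <- function(obs, cluster_sizes, K_bg, N_bg, min_count, alpha) {
  obs <- obs[obs$k >= min_count, , drop = FALSE]
  if (!nrow(obs)) return(obs)
  obs$n <- cluster_sizes[as.character(obs$cluster)]
  obs$K_bg <- K_bg[obs$item]
  obs$N_bg <- N_bg
  obs$p_value <- hypergeom_upper(obs$k, obs$n, obs$K_bg, obs$N_bg)
  obs$fdr <- NA_real_
  for (cl in unique(obs$cluster)) {
    sel <- obs$cluster == cl
    obs$fdr[sel] <- bh_fdr(obs$p_value[sel])
  }
  obs <- obs[obs$p_value < alpha, , drop = FALSE]
  obs[order(obs$cluster, obs$p_value, obs$item, method = "radix"), , drop = FALSE]
}

#' Per-cluster entity overrepresentation
#'
#' For each cluster and entity: `k` = documents in the cluster containing
#' the entity, `n` = cluster size, `K_bg` = documents in the whole corpus
#' containing the entity, `N_bg` = corpus size; the p-value is the
#' upper-tail hypergeometric probability. Entities observed in fewer than
#' `min_count` cluster documents are dropped (protein enrichment tables
#' conventionally bottom out at 2), as are rows at or above the `alpha`
#' cut-off. Raw p and the BH-FDR within each cluster's test family are
#' reported side by side.
#'
#' @param mentions Mention tibble from [tag_entities()] (or any table with
#'   `doc_id`, `preflabel`, `type`).
#' @param result A [kmeans_docs()] result or named label vector covering
#'   the corpus.
#' @param type_filter Optional entity type to test.
#' @param alpha Report rows with `p < alpha` (default 0.1).
#' @param min_count Minimum per-cluster document count.
#' @return Tibble `(cluster, preflabel, type, k, n, K_bg, N_bg, p_value,
#'   fdr)` sorted by cluster then p-value.
#' @export
cluster_entity_enrichment <- function(mentions, result, type_filter = NULL,
                                      alpha = 0.1, min_count = 2L) {
  labels <- cluster_labels(result)
  m <- mentions
  if (!is.null(type_filter)) m <- m[m$type %in% type_filter, , drop = FALSE]
  m <- unique(m[, c("doc_id", "preflabel", "type")])
  m <- m[m$doc_id %in% names(labels), , drop = FALSE]
  empty <- tibble::tibble(cluster = integer(0), preflabel = character(0),
                          type = character(0), k = integer(0), n = integer(0),
                          K_bg = integer(0), N_bg = integer(0),
                          p_value = numeric(0), fdr = numeric(0))
  if (!nrow(m)) return(empty)

  m$cluster <- labels[m$doc_id]
  type_of <- stats::setNames(m$type, m$preflabel)
  kk <- table(paste(m$cluster, m$preflabel, sep = "\r"))
  parts <- strsplit(names(kk), "\r", fixed = TRUE)
  obs <- data.frame(
    cluster = as.integer(vapply(parts, `[`, "", 1L)),
    item = vapply(parts, `[`, "", 2L),
    k = as.integer(kk),
    stringsAsFactors = FALSE
  )
  cl_sizes <- table(labels)
  cluster_sizes <- stats::setNames(as.integer(cl_sizes), names(cl_sizes))
  Kb <- table(m$preflabel)
  K_bg <- stats::setNames(as.integer(Kb), names(Kb))
  out <- enrich_rows(obs, cluster_sizes, K_bg, length(labels), min_count, alpha)
  if (!nrow(out)) return(empty)
  tibble::tibble(cluster = out$cluster, preflabel = out$item,
                 type = unname(type_of[out$item]), k = out$k, n = out$n,
                 K_bg = out$K_bg, N_bg = out$N_bg,
                 p_value = out$p_value, fdr = out$fdr)
}

#' Read an entity-to-category annotation map from TSV
#'
#' Columns `preflabel`, `category_id`, `category_description`; `#` comment
#' lines allowed. Categories play the role of disease-ontology terms in
#' functional annotation of cluster protein sets.
#'
#' @param path Path to the TSV file.
#' @return Object of class `category_map`: list with `map` (named list
#'   preflabel -> character vector of category IDs) and `description`
#'   (named character vector).
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) stop("category map file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("preflabel", "category_id", "category_description")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("category map TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  category_map(df$preflabel, df$category_id, df$category_description)
}

#' Construct an entity-to-category map
#'
#' @param preflabel Character vector of entity labels.
#' @param category_id Parallel vector of category IDs.
#' @param category_description Parallel vector of human-readable
#'   descriptions.
#' @return A `category_map` object; see [read_category_map()].
#' @export
category_map <- function(preflabel, category_id, category_description = category_id) {
  stopifnot(length(preflabel) == length(category_id))
  map <- lapply(split(as.character(category_id), as.character(preflabel)), unique)
  map <- map[lengths(map) > 0]
  desc <- tapply(as.character(category_description), as.character(category_id),
                 function(v) v[[1L]])
  structure(list(map = map, description = stats::setNames(as.character(desc), names(desc))),
            class = "category_map")
}

#' Per-cluster category overrepresentation with BH-FDR
#'
#' Functional-annotation style test on cluster entity sets: for each cluster
#' and category, `k` = cluster proteins mapping to the category, `n` =
#' mapped cluster proteins, `K_bg` = background proteins in the category,
#' `N_bg` = mapped background size. Proteins without any category mapping
#' are counted out. The BH-FDR is computed within each cluster's category
#' family.
#'
#' @param cluster_entities Named list: cluster index -> character vector of
#'   preflabels observed in that cluster.
#' @param catmap A [category_map()].
#' @param background Character vector of background preflabels.
#' @param alpha Report rows with `p < alpha`; the default (`Inf`) keeps
#'   every tested category.
#' @return Tibble `(cluster, category_id, description, k, n, K_bg, N_bg,
#'   p_value, fdr)` sorted by cluster then p-value.
#' @export
category_enrichment <- function(cluster_entities, catmap, background, alpha = Inf) {
  if (!length(background)) stop("category_enrichment: empty background")
  background <- unique(as.character(background))
  mapped_bg <- background[background %in% names(catmap$map)]
  if (!length(mapped_bg)) stop("category_enrichment: no background entity maps to any category")
  N_bg <- length(mapped_bg)
  bg_cat <- table(unlist(lapply(catmap$map[mapped_bg], unique), use.names = FALSE))
  K_bg <- stats::setNames(as.integer(bg_cat), names(bg_cat))

  rows <- list()
  cluster_sizes <- integer(0)
  for (cl in names(cluster_entities)) {
    prots <- intersect(unique(cluster_entities[[cl]]), mapped_bg)
    cluster_sizes[[cl]] <- length(prots)
    if (!length(prots)) next
    cc <- table(unlist(lapply(catmap$map[prots], unique), use.names = FALSE))
    rows[[cl]] <- data.frame(cluster = cl, item = names(cc), k = as.integer(cc),
                             stringsAsFactors = FALSE)
  }
  empty <- tibble::tibble(cluster = character(0), category_id = character(0),
                          description = character(0), k = integer(0), n = integer(0),
                          K_bg = integer(0), N_bg = integer(0),
                          p_value = numeric(0), fdr = numeric(0))
  if (!length(rows)) return(empty)
  obs <- dplyr::bind_rows(rows)
  names(cluster_sizes) <- names(cluster_sizes)
  out <- enrich_rows(obs, cluster_sizes, K_bg, N_bg, min_count = 1L, alpha = alpha)
  if (!nrow(out)) return(empty)
  tibble::tibble(cluster = out$cluster, category_id = out$item,
                 description = unname(catmap$description[out$item]),
                 k = out$k, n = out$n, K_bg = out$K_bg, N_bg = out$N_bg,
                 p_value = out$p_value, fdr = out$fdr)
}
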