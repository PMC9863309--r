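# Squared Euclidean distances between rows of X and rows of C.
dist2_matrix <- function(X, C) {
  D <- matrix(rowSums(X^2), nrow(X), nrow(C)) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE) -
    2 * X %*% t(C)
  D[D < 0] <- 0
  D
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    tot <- sum(d2)
    pick <- if (tot <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

# Lloyd iterations with empty-cluster repair (reseed to the point farthest
# from its assigned centroid).
lloyd <- function(X, centers, max_iter, tol) {
  n <- nrow(X)
  k <- nrow(centers)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- dist2_matrix(X, centers)
    lab <- max.col(-D, ties.method = "first")
    repeat {
      sizes <- tabulate(lab, nbins = k)
      empt <- which(sizes == 0L)
      if (!length(empt)) break
      own <- D[cbind(seq_len(n), lab)]
      far <- which.max(own)
      centers[empt[1L], ] <- X[far, ]
      lab[far] <- empt[1L]
      D[, empt[1L]] <- dist2_matrix(X, centers[empt[1L], , drop = FALSE])
    }
    newc <- rowsum(X, lab) / tabulate(lab, nbins = k)
    shift <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    if (shift < tol || iter >= max_iter) break
  }
  D <- dist2_matrix(X, centers)
  lab <- max.col(-D, ties.method = "first")
  wss <- sum(D[cbind(seq_len(n), lab)])
  list(labels = lab, centers = centers, wss = wss, iterations = iter)
}

#' K-means clustering of tf-idf document vectors
#'
#' Lloyd's algorithm with k-means++ initialization, multiple restarts (the
#' restart with the lowest within-cluster sum of squares wins), convergence
#' when the largest centroid shift falls below `tol`, and empty-cluster
#' repair by reseeding to the point farthest from its assigned centroid.
#' Deterministic given `seed`.
#'
#' @param x A [tfidf()] result or a numeric matrix with document rownames.
#' @param k Number of clusters (at most the number of documents).
#' @param seed Integer seed.
#' @param n_restarts Number of k-means++ restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Convergence threshold on centroid movement.
#' @return Object of class `doc_clustering`: list with `k`, `labels` (named
#'   integer vector, cluster indices `0..k-1` keyed by doc_id), `centroids`
#'   (k x terms), `wss`, `seed`, `n_restarts`, `iterations`.
#' @export
kmeans_docs <- function(x, k, seed = 0L, n_restarts = 10L, max_iter = 300L,
                        tol = 1e-6) {
  X <- if (inherits(x, "tfidf_matrix")) as.matrix(x$weights) else as.matrix(x)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  if (k > nrow(X)) stop("k (", k, ") exceeds the number of documents (", nrow(X), ")")
  stopifnot(k >= 1L, n_restarts >= 1L)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd(X, kmeanspp_init(X, k), max_iter, tol)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  centroids <- best$centers
  rownames(centroids) <- as.character(seq_len(k) - 1L)
  colnames(centroids) <- colnames(X)
  structure(list(
    k = k,
    labels = stats::setNames(as.integer(best$labels) - 1L, rownames(X)),
    centroids = centroids,
    wss = best$wss,
    seed = seed,
    n_restarts = n_restarts,
    iterations = best$iterations
  ), class = "doc_clustering")
}

#' @export
print.doc_clustering <- function(x, ...) {
  cat(sprintf("<doc_clustering> k = %d, n = %d, WSS = %.4f (seed %d, %d restarts)\n",
              x$k, length(x$labels), x$wss, x$seed, x$n_restarts))
  invisible(x)
}

#' Within-cluster sum-of-squares curve over a range of K
#'
#' Runs [kmeans_docs()] for each K and reports the WSS, the diagnostic used
#' to choose a suitable number of clusters. The advisory elbow suggestion is
#' the K maximizing the second forward difference of the WSS curve (the
#' sharpest flattening); it requires at least three consecutive K values.
#'
#' @inheritParams kmeans_docs
#' @param k_range Increasing integer vector of K values within `[1, n]`.
#' @return Object of class `wss_curve`: list with `curve` (tibble `k`,
#'   `wss`) and `elbow` (integer or `NA`).
#' @export
wss_curve <- function(x, k_range, seed = 0L, n_restarts = 10L, max_iter = 300L,
                      tol = 1e-6) {
  k_range <- as.integer(k_range)
  stopifnot(length(k_range) >= 1L, !is.unsorted(k_range))
  wss <- vapply(k_range, function(k) {
    kmeans_docs(x, k, seed = seed, n_restarts = n_restarts,
                max_iter = max_iter, tol = tol)$wss
  }, numeric(1))
  elbow <- NA_integer_
  if (length(k_range) >= 3L) {
    d2 <- wss[-c(1L, 2L)] - 2 * wss[-c(1L, length(wss))] + wss[-c(length(wss) - 1L, length(wss))]
    elbow <- k_range[which.max(d2) + 1L]
  }
  structure(list(curve = tibble::tibble(k = k_range, wss = wss), elbow = elbow),
            class = "wss_curve")
}

#' @export
print.wss_curve <- function(x, ...) {
  cat(sprintf("<wss_curve> K in [%d, %d], elbow suggestion: %s\n",
              min(x$curve$k), max(x$curve$k),
              ifelse(is.na(x$elbow), "none", x$elbow)))
  invisible(x)
}

#' Per-cluster theme keywords and summary statistics
#'
#' The theme of a cluster is its `top_n` terms by mean tf-idf weight over
#' the cluster's documents (ties alphabetical), the human-readable label of
#' the thematic group. The summary also reports cluster size (document
#' count), median SJR, and the median/earliest/latest publication year.
#'
#' @param x The [tfidf()] matrix used for clustering.
#' @param result A [kmeans_docs()] result (or named label vector).
#' @param corp The [corpus()] providing year/SJR metadata.
#' @param top_n Number of theme terms per cluster.
#' @return Object of class `cluster_themes`: list with `summary` (tibble
#'   `cluster`, `letter`, `theme`, `size`, `median_sjr`, `median_year`,
#'   `earliest`, `latest`) and `terms` (tibble `cluster`, `letter`, `rank`,
#'   `term`, `mean_tfidf`).
#' @export
cluster_themes <- function(x, result, corp, top_n = 10L) {
  labels <- cluster_labels(result)
  W <- x$weights
  if (!all(rownames(W) %in% names(labels))) {
    stop("clustering labels do not cover all documents in the tf-idf matrix")
  }
  labels <- labels[rownames(W)]
  docs <- corp$documents
  meta_idx <- match(rownames(W), docs$doc_id)
  clusters <- sort(unique(labels))
  term_rows <- vector("list", length(clusters))
  sum_rows <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    rows <- which(labels == cl)
    mw <- Matrix::colMeans(W[rows, , drop = FALSE])
    ord <- order(-mw, names(mw), method = "radix")[seq_len(min(top_n, length(mw)))]
    letter <- if (cl < 26L) LETTERS[cl + 1L] else as.character(cl)
    term_rows[[ci]] <- tibble::tibble(
      cluster = cl, letter = letter, rank = seq_along(ord),
      term = names(mw)[ord], mean_tfidf = as.numeric(mw[ord])
    )
    yrs <- docs$year[meta_idx[rows]]
    yrs <- yrs[!is.na(yrs)]
    sjr <- docs$sjr[meta_idx[rows]]
    sum_rows[[ci]] <- tibble::tibble(
      cluster = cl, letter = letter,
      theme = paste(names(mw)[ord], collapse = ", "),
      size = length(rows),
      median_sjr = if (all(is.na(sjr))) NA_real_ else stats::median(sjr, na.rm = TRUE),
      median_year = if (length(yrs)) as.integer(stats::median(yrs)) else NA_integer_,
      earliest = if (length(yrs)) min(yrs) else NA_integer_,
      latest = if (length(yrs)) max(yrs) else NA_integer_
    )
  }
  structure(list(summary = dplyr::bind_rows(sum_rows),
                 terms = dplyr::bind_rows(term_rows)),
            class = "cluster_themes")
}

#' @export
print.cluster_themes <- function(x, ...) {
  cat(sprintf("<cluster_themes> %d clusters\n", nrow(x$summary)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s (n=%d): %s\n", x$summary$letter[i], x$summary$size[i],
                x$summary$theme[i]))
  }
  invisible(x)
}

#' Cluster-by-year publication trend table
#'
#' Counts documents per (year, cluster). Years inside the observed range
#' with no documents are reported as zero for every cluster; documents with
#' unknown year are excluded, so the table sums to the number of documents
#' with a known year.
#'
#' @param result A [kmeans_docs()] result (or named label vector).
#' @param corp The [corpus()] providing publication years.
#' @return Tibble `(year, cluster, n_docs)` ordered by year then cluster.
#' @export
cluster_year_trend <- function(result, corp) {
  labels <- cluster_labels(result)
  docs <- corp$documents
  idx <- match(names(labels), docs$doc_id)
  year <- docs$year[idx]
  ok <- !is.na(year)
  if (!any(ok)) {
    return(tibble::tibble(year = integer(0), cluster = integer(0), n_docs = integer(0)))
  }
  year <- year[ok]
  lab <- labels[ok]
  clusters <- sort(unique(labels))
  grid <- expand.grid(year = seq(min(year), max(year)), cluster = clusters,
                      KEEP.OUT.ATTRS = FALSE)
  key <- paste(year, lab, sep = "\r")
  tab <- table(key)
  gkey <- paste(grid$year, grid$cluster, sep = "\r")
  n <- as.integer(tab[gkey])
  n[is.na(n)] <- 0L
  out <- tibble::tibble(year = as.integer(grid$year),
                        cluster = as.integer(grid$cluster), n_docs = n)
  out[order(out$year, out$cluster), ]
}
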