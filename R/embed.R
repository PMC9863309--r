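# Conditional-probability matrix P for t-SNE: per-point precision is
# calibrated by binary search so that the entropy of each row matches
# log(perplexity).
tsne_affinities <- function(X, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(X)
  D2 <- dist2_matrix(X, X)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    betamin <- -Inf
    betamax <- Inf
    for (tries in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) {
        H <- 0
        p[] <- 0
      } else {
        H <- log(sump) + beta * sum(di * p) / sump
        p <- p / sump
      }
      hdiff <- H - logU
      if (abs(hdiff) < tol) break
      if (hdiff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

#' 2-D t-SNE embedding of the tf-idf matrix
#'
#' Exact (quadratic-cost) t-SNE: neighborhood affinities with per-point
#' perplexity calibration, Student-t low-dimensional kernel, gradient
#' descent with momentum, adaptive gains and early exaggeration. The
#' embedding is initialized from the first two principal components (sign-
#' fixed), so the result is deterministic given `seed`; documents with
#' similar word content land in close proximity, and identical rows stay
#' coincident. Suited to desk-scale corpora (hundreds to a few thousand
#' documents).
#'
#' @param x A [tfidf()] result or numeric matrix with document rownames.
#' @param seed Integer seed (used for the degenerate fallback
#'   initialization).
#' @param perplexity Effective neighborhood size; must be below the number
#'   of documents.
#' @param max_iter Number of gradient iterations.
#' @return Tibble `(doc_id, x, y)`, one coordinate pair per document.
#' @export
embed_2d <- function(x, seed = 0L, perplexity = 30, max_iter = 500L) {
  X_all <- if (inherits(x, "tfidf_matrix")) as.matrix(x$weights) else as.matrix(x)
  n_all <- nrow(X_all)
  if (n_all < 4L) stop("embedding requires at least 4 documents")
  if (perplexity >= n_all) stop("perplexity (", perplexity,
                                ") must be smaller than the number of documents (",
                                n_all, ")")
  # identical rows get identical coordinates: embed unique rows only, then
  # copy the representative's position to each duplicate
  row_key <- apply(X_all, 1L, paste, collapse = "\r")
  rep_of <- match(row_key, row_key)
  uniq <- which(rep_of == seq_len(n_all))
  X <- X_all[uniq, , drop = FALSE]
  n <- nrow(X)
  perplexity <- min(perplexity, max(2, (n - 1) / 3))
  set.seed(seed)
  P <- tsne_affinities(X, perplexity)

  # PCA initialization, scaled small; sign fixed for determinism
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 2L, nv = 0L)
  Y <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2L)
  for (j in 1:2) {
    if (all(Y[, j] == 0)) {
      Y[, j] <- stats::rnorm(n, sd = 1)
    } else if (Y[which.max(abs(Y[, j])), j] < 0) {
      Y[, j] <- -Y[, j]
    }
  }
  Y <- Y / max(stats::sd(Y[, 1L]), .Machine$double.eps) * 1e-4

  momentum <- 0.5
  eta <- 200
  gains <- matrix(1, n, 2L)
  inc <- matrix(0, n, 2L)
  exaggeration <- 12
  P_run <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    if (iter == 101L) P_run <- P
    if (iter == 251L) momentum <- 0.8
    D2y <- dist2_matrix(Y, Y)
    W <- 1 / (1 + D2y)
    diag(W) <- 0
    Q <- pmax(W / sum(W), .Machine$double.eps)
    L <- (P_run - Q) * W
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y_all <- Y[match(rep_of, uniq), , drop = FALSE]
  tibble::tibble(doc_id = rownames(X_all) %||% as.character(seq_len(n_all)),
                 x = Y_all[, 1L], y = Y_all[, 2L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
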