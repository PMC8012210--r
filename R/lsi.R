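as_counts <- function(x) {
  if (inherits(x, "feature_matrix")) x$counts else methods::as(x, "CsparseMatrix")
}

#' TF-IDF normalization (log variant)
#'
#' `tf` is each cell's count fraction over the selected features, `idf`
#' is `n_cells / feature occurrence count`, and the normalized value is
#' `log(1 + tf * idf * scale_factor)`.
#'
#' @param matrix `feature_matrix` or sparse cells x features matrix.
#' @param features optional column subset (indices or names).
#' @param idf optional precomputed idf vector (used when projecting new
#'   cells through a fitted model).
#' @param scale_factor default 10000.
#' @return list(matrix = normalized sparse matrix, idf).
#' @export
tfidf <- function(matrix, features = NULL, idf = NULL, scale_factor = 1e4) {
  m <- as_counts(matrix)
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  depth <- Matrix::rowSums(m)
  if (any(depth == 0)) {
    stop("all-zero cells on selected features: ",
         paste(head(rownames(m)[depth == 0], 5), collapse = ", "))
  }
  if (is.null(idf)) {
    occ <- Matrix::colSums(m > 0)
    if (any(occ == 0)) stop("all-zero feature among selected features")
    idf <- nrow(m) / occ
  }
  tf <- Matrix::Diagonal(x = 1 / depth) %*% m
  val <- tf %*% Matrix::Diagonal(x = idf * scale_factor)
  val <- methods::as(val, "CsparseMatrix")
  val@x <- log1p(val@x)
  rownames(val) <- rownames(m)
  colnames(val) <- colnames(m)
  list(matrix = val, idf = idf)
}

# exact truncated SVD of a sparse matrix through the Gram matrix of the
# smaller side; returns u (n x k), d, v (p x k)
truncated_svd <- function(X, k) {
  G <- as.matrix(Matrix::tcrossprod(X))
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(eig$values) * 1e-10
  pos <- sum(eig$values > tol)
  if (pos < k) {
    warning("rank-deficient matrix: returning ", pos, " of ", k, " components")
    k <- pos
  }
  d <- sqrt(eig$values[seq_len(k)])
  u <- eig$vectors[, seq_len(k), drop = FALSE]
  v <- as.matrix(Matrix::crossprod(X, u)) %*% diag(1 / d, k)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    s <- sign(v[which.max(abs(v[, j])), j])
    if (s < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  list(u = u, d = d, v = v)
}

#' Fit an LSI model
#'
#' TF-IDF normalization followed by truncated SVD. The embedding is the
#' cell-side singular vectors scaled by the singular values. Components
#' whose correlation with log10 cell depth exceeds
#' `depth_cor_threshold` in absolute value are dropped from
#' `retained_components` (depth-decorrelation).
#'
#' @param matrix `feature_matrix` or sparse cells x features counts.
#' @param features optional feature subset used for the model.
#' @param n_components number of SVD components (default 30).
#' @param seed stored for provenance (the fit itself is deterministic).
#' @param depth_cor_threshold absolute depth-correlation above which a
#'   component is dropped (default 0.75).
#' @return list(model = `lsi_model`, embedding = cells x components
#'   matrix with a `retained` attribute).
#' @export
lsi_fit <- function(matrix, features = NULL, n_components = 30L, seed = 1L,
                    depth_cor_threshold = 0.75) {
  m <- as_counts(matrix)
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  if (n_components >= min(dim(m))) {
    stop("n_components must be smaller than both matrix dimensions")
  }
  norm <- tfidf(m)
  sv <- truncated_svd(norm$matrix, n_components)
  emb <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(emb) <- rownames(m)
  colnames(emb) <- paste0("LSI", seq_along(sv$d))

  depth <- Matrix::rowSums(m)
  dc <- suppressWarnings(apply(emb, 2, function(x) stats::cor(x, log10(depth))))
  dc[is.na(dc)] <- 0
  retained <- which(abs(dc) <= depth_cor_threshold)
  if (length(retained) == 0) retained <- seq_along(sv$d)

  rownames(sv$v) <- colnames(m)
  model <- structure(
    list(feature_ids = colnames(m), idf = norm$idf, loadings = sv$v,
         singular_values = sv$d, n_components = length(sv$d),
         retained_components = retained, depth_cor = dc, seed = seed),
    class = "lsi_model")
  attr(emb, "retained") <- retained
  list(model = model, embedding = emb)
}

#' @exportS3Method base::print
print.lsi_model <- function(x, ...) {
  cat(sprintf("lsi_model: %d features, %d components (%d retained)\n",
              length(x$feature_ids), x$n_components,
              length(x$retained_components)))
  invisible(x)
}

#' Retained (depth-decorrelated) columns of an LSI embedding
#' @param embedding embedding matrix carrying a `retained` attribute.
#' @return matrix restricted to retained components.
#' @export
retained_embedding <- function(embedding) {
  r <- attr(embedding, "retained") %||% seq_len(ncol(embedding))
  embedding[, r, drop = FALSE]
}

#' Project new cell profiles into a fitted LSI subspace
#'
#' New profiles are normalized with the model's stored idf and projected
#' through the stored loadings; training cells project exactly to their
#' fitted coordinates, and the projection is linear in the normalized
#' space (the basis of estimated LSI and bulk-profile projection).
#'
#' @param model an `lsi_model`.
#' @param matrix `feature_matrix` or sparse counts containing all model
#'   features (by column name).
#' @return cells x components embedding with the model's `retained`
#'   attribute.
#' @export
lsi_project <- function(model, matrix) {
  m <- as_counts(matrix)
  missing <- setdiff(model$feature_ids, colnames(m))
  if (length(missing)) {
    stop(length(missing), " model features missing from new matrix")
  }
  m <- m[, model$feature_ids, drop = FALSE]
  norm <- tfidf(m, idf = model$idf)
  emb <- as.matrix(norm$matrix %*% model$loadings)
  rownames(emb) <- rownames(m)
  colnames(emb) <- paste0("LSI", seq_len(ncol(emb)))
  attr(emb, "retained") <- model$retained_components
  emb
}

#' Iterative LSI with variable-feature reselection
#'
#' Iteration 1 fits LSI on the most accessible features. Preliminary
#' clusters are then computed on the retained components; per-cluster
#' pseudo-bulk log2-CPM profiles give a per-feature variance, and the most
#' variable features seed the next iteration. The final model comes from
#' the last iteration.
#'
#' @inheritParams lsi_fit
#' @param n_iterations LSI rounds (default 2); 1 reduces to [lsi_fit()]
#'   on the top accessible features.
#' @param n_top_features most accessible features used in iteration 1.
#' @param n_var_features most cluster-variable features reselected for
#'   later iterations.
#' @param cluster_resolution modularity resolution of the preliminary
#'   clustering.
#' @param k_neighbors neighbours for the preliminary clustering graph.
#' @return list(model, embedding, features, clusters) where `clusters`
#'   are the preliminary labels from the last reselection round (NULL
#'   when `n_iterations = 1`).
#' @export
iterative_lsi <- function(matrix, n_iterations = 2L, n_top_features = 25000L,
                          n_var_features = 25000L, n_components = 30L,
                          cluster_resolution = 1, k_neighbors = 30L,
                          seed = 1L, depth_cor_threshold = 0.75) {
  stopifnot(n_iterations >= 1)
  m <- as_counts(matrix)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  acc <- Matrix::colSums(m)
  features <- colnames(m)[order(-acc)][seq_len(min(n_top_features, sum(acc > 0)))]
  fit <- lsi_fit(m, features, n_components, seed, depth_cor_threshold)
  clusters <- NULL
  if (n_iterations > 1) {
    for (iter in seq_len(n_iterations - 1L)) {
      cl <- cluster_cells(retained_embedding(fit$embedding),
                          k_neighbors = k_neighbors,
                          resolution = cluster_resolution,
                          seed = seed_from(seed, iter))
      if (length(unique(cl)) < 2) {
        warning("fewer than 2 preliminary clusters; keeping top-accessible features")
        break
      }
      clusters <- cl
      pb <- rowsum_sparse(m, cl)                    # clusters x features
      cpm <- log2(pb / pmax(rowSums(pb), 1) * 1e6 + 1)
      v <- apply(cpm, 2, stats::var)
      features <- colnames(m)[order(-v)][seq_len(min(n_var_features, sum(v > 0)))]
      fit <- lsi_fit(m, features, n_components, seed, depth_cor_threshold)
    }
  }
  list(model = fit$model, embedding = fit$embedding,
       features = features, clusters = clusters)
}

# dense group x column sums of a sparse matrix
rowsum_sparse <- function(m, groups) {
  g <- factor(groups)
  G <- Matrix::sparseMatrix(i = as.integer(g), j = seq_len(nrow(m)), x = 1,
                            dims = c(nlevels(g), nrow(m)))
  out <- as.matrix(G %*% m)
  rownames(out) <- levels(g)
  out
}

#' Estimated LSI: fit on landmarks, project the rest
#'
#' Fits iterative LSI on a uniform random landmark subset and linearly
#' projects all remaining cells into the subspace with [lsi_project()].
#' Landmark cells keep their fitted coordinates; with
#' `n_landmarks = n_cells` the result equals [iterative_lsi()].
#'
#' @inheritParams iterative_lsi
#' @param n_landmarks number of landmark cells (>= `2 * n_components`).
#' @return list(model, embedding (all cells, original order), landmarks,
#'   features).
#' @export
estimated_lsi <- function(matrix, n_landmarks, seed = 1L, ...) {
  m <- as_counts(matrix)
  args <- list(...)
  n_comp <- args$n_components %||% 30L
  if (n_landmarks < 2 * n_comp) {
    stop("n_landmarks must be at least 2 * n_components")
  }
  if (n_landmarks > nrow(m)) stop("n_landmarks exceeds number of cells")
  set.seed(seed)
  landmarks <- sort(sample.int(nrow(m), n_landmarks))
  fit <- iterative_lsi(m[landmarks, , drop = FALSE], seed = seed, ...)
  emb <- matrix(0, nrow(m), ncol(fit$embedding),
                dimnames = list(rownames(m), colnames(fit$embedding)))
  emb[landmarks, ] <- fit$embedding
  rest <- setdiff(seq_len(nrow(m)), landmarks)
  if (length(rest)) {
    emb[rest, ] <- lsi_project(fit$model, m[rest, , drop = FALSE])
  }
  attr(emb, "retained") <- fit$model$retained_components
  list(model = fit$model, embedding = emb, landmarks = landmarks,
       features = fit$features)
}

#' Graph-based clustering of an embedding
#'
#' Builds a shared-nearest-neighbor graph (Jaccard overlap of
#' k-neighborhoods, pruned below 1/15) and runs modularity community
#' detection (Louvain). Deterministic under a fixed seed.
#'
#' @param embedding cells x components matrix (retained LSI components).
#' @param k_neighbors neighborhood size (default 30, capped at n-1).
#' @param resolution modularity resolution (default 1).
#' @param seed RNG seed.
#' @param prune minimum Jaccard weight for an SNN edge to be kept.
#' @return integer cluster labels named by cell.
#' @export
cluster_cells <- function(embedding, k_neighbors = 30L, resolution = 1,
                          seed = 1L, prune = 1 / 15) {
  emb <- retained_embedding(embedding)
  n <- nrow(emb)
  k <- min(k_neighbors, n - 1L)
  nn <- knn_index(emb, k)
  # neighborhoods include the cell itself
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), k + 1L),
    j = c(as.vector(nn$index), seq_len(n)),
    x = 1, dims = c(n, n))
  shared <- methods::as(Matrix::tcrossprod(A), "TsparseMatrix")
  ii <- shared@i + 1L; jj <- shared@j + 1L; s <- shared@x
  upper <- ii < jj
  ii <- ii[upper]; jj <- jj[upper]; s <- s[upper]
  jacc <- s / (2 * (k + 1L) - s)
  keep <- jacc >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = ii[keep], to = jj[keep], weight = jacc[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  memb <- igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  labels <- integer(n)
  labels[as.integer(names(memb))] <- as.integer(memb)
  stats::setNames(labels, rownames(emb))
}
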