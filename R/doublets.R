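#' Synthesize in-silico doublet profiles
#'
#' Each synthetic doublet is the element-wise sum of the count profiles of
#' two distinct cells sampled uniformly at random; parent identities are
#' recorded.
#'
#' @param matrix `feature_matrix` or sparse cells x features counts.
#' @param n_synthetic number of synthetic doublets (default: one per cell).
#' @param seed RNG seed.
#' @return list(counts = synthetic x features sparse matrix, parents =
#'   data.table(synthetic, parent1, parent2)).
#' @export
synthesize_doublets <- function(matrix, n_synthetic = NULL, seed = 1L) {
  m <- as_counts(matrix)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 cells to synthesize doublets")
  n_synthetic <- n_synthetic %||% n
  set.seed(seed)
  p1 <- sample.int(n, n_synthetic, replace = TRUE)
  p2 <- sample.int(n - 1L, n_synthetic, replace = TRUE)
  p2 <- p2 + (p2 >= p1) # uniform over pairs of distinct cells
  syn <- m[p1, , drop = FALSE] + m[p2, , drop = FALSE]
  rownames(syn) <- sprintf("synthetic%04d", seq_len(n_synthetic))
  parents <- data.table::data.table(
    synthetic = rownames(syn),
    parent1 = rownames(m)[p1], parent2 = rownames(m)[p2])
  list(counts = syn, parents = parents)
}

#' Score cells by synthetic-doublet neighborhood enrichment
#'
#' Synthetic doublets are pooled with the real cells in the retained LSI
#' component space. For each real cell, `x` synthetic points among its
#' `k` nearest pooled neighbours are compared with the expectation
#' `k * nSyn / (nSyn + nReal)`: enrichment is observed/expected and the
#' score is the -log10 upper-tail binomial p-value of observing at least
#' `x` synthetic neighbours.
#'
#' @param real_embedding cells x components matrix (retained components).
#' @param synthetic_embedding synthetic doublets projected into the same
#'   space via [lsi_project()].
#' @param k neighborhood size (default 10).
#' @param n_frags optional per-cell fragment counts used only for
#'   removal-rank tie-breaking.
#' @return data.table(barcode, n_synthetic_neighbors, enrichment, score,
#'   rank).
#' @export
doublet_scores <- function(real_embedding, synthetic_embedding, k = 10L,
                           n_frags = NULL) {
  real <- retained_embedding(real_embedding)
  syn <- retained_embedding(synthetic_embedding)
  if (ncol(real) != ncol(syn)) stop("embeddings must share component space")
  n_real <- nrow(real); n_syn <- nrow(syn)
  if (k >= n_real + n_syn) stop("k must be smaller than the pooled size")
  pooled <- rbind(real, syn)
  # a real cell is also a pooled reference point: query k+1 and drop self
  nn <- knn_index(pooled, k + 1L, query = real)
  x <- vapply(seq_len(n_real), function(i) {
    nb <- nn$index[i, ]
    nb <- nb[nb != i][seq_len(k)]
    sum(nb > n_real)
  }, numeric(1))
  p0 <- n_syn / (n_syn + n_real)
  expected <- k * p0
  enrichment <- x / expected
  score <- -stats::pbinom(x - 1, k, p0, lower.tail = FALSE, log.p = TRUE) / log(10)
  bc <- rownames(real) %||% as.character(seq_len(n_real))
  nf <- if (is.null(n_frags)) rep(0, n_real) else n_frags[bc]
  out <- data.table::data.table(barcode = bc, n_synthetic_neighbors = x,
                                enrichment = enrichment, score = score,
                                n_frags = nf)
  data.table::setorder(out, -enrichment, -score, -n_frags, barcode)
  out[, rank := .I]
  data.table::setorder(out, barcode)
  out[]
}

#' Remove the top-scoring putative doublets
#'
#' Removes the `round(filter_ratio * nCells^2 / 100000)` top-ranked cells
#' by enrichment, so the expected doublet fraction scales with cell
#' loading (~1% per 1,000 cells at ratio 1).
#'
#' @param scores output of [doublet_scores()].
#' @param filter_ratio scaling of the removal count (default 1).
#' @return character vector of removed barcodes.
#' @export
filter_doublets <- function(scores, filter_ratio = 1) {
  stopifnot(filter_ratio >= 0)
  n <- nrow(scores)
  n_remove <- round(filter_ratio * n^2 / 1e5)
  if (n_remove >= n) stop("filter_ratio would remove every cell")
  if (n_remove == 0) return(character())
  scores$barcode[order(scores$rank)][seq_len(n_remove)]
}
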