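`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a chromosome-sizes table
#'
#' Two-column TSV (chromosome name, length in bases), the standard
#' `chrom.sizes` layout.
#'
#' @param path path to a two-column TSV file.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, select = 1:2,
                          col.names = c("name", "length"))
  chrom_sizes(dt$name, dt$length)
}

#' Construct a chromosome-sizes vector
#'
#' @param names chromosome identifiers (unique).
#' @param lengths chromosome lengths in bases (positive integers).
#' @return named integer vector.
#' @export
chrom_sizes <- function(names, lengths) {
  if (anyDuplicated(names)) stop("chromosome names must be unique")
  lengths <- as.integer(lengths)
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive integers")
  }
  stats::setNames(lengths, as.character(names))
}

# parse "chrom:start-end" (half-open) into list(chrom, start, end)
parse_region <- function(region) {
  m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("malformed region: ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

# centered moving average with edge shrinkage (window must be odd)
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  if (window %% 2 == 0) window <- window + 1
  half <- (window - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# k nearest neighbours by Euclidean distance, computed block-wise.
# query defaults to reference; self matches are excluded in that case.
knn_index <- function(reference, k, query = NULL, block = 2048L) {
  reference <- as.matrix(reference)
  self_query <- is.null(query)
  query <- if (self_query) reference else as.matrix(query)
  nq <- nrow(query); nr <- nrow(reference)
  if (k >= nr + !self_query && k > nr - self_query) {
    stop("k must be smaller than the number of reference points")
  }
  rn2 <- rowSums(reference^2)
  idx <- matrix(0L, nq, k)
  dmat <- matrix(0, nq, k)
  for (s in seq(1, nq, by = block)) {
    e <- min(s + block - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, "+") - 2 * tcrossprod(q, reference)
    if (self_query) {
      d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    }
    for (i in seq_len(nrow(d2))) {
      ord <- order(d2[i, ])[seq_len(k)]
      idx[s + i - 1L, ] <- ord
      dmat[s + i - 1L, ] <- sqrt(pmax(d2[i, ord], 0))
    }
  }
  list(index = idx, dist = dmat)
}

# rank-based (Mann-Whitney) AUC with tie averaging
#' ROC area under the curve of a score against binary labels
#'
#' Rank-based (Mann-Whitney) AUC with ties averaged; equals the
#' probability that a random positive outranks a random negative.
#'
#' @param scores numeric score per observation (higher = more positive).
#' @param labels binary labels (logical or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index (1 = identical partitions, ~0 = random).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- si * sj / n
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# depth-normalize rows of a sparse cells x features matrix to a fixed total
normalize_depth <- function(mat, target = 1e4) {
  depth <- Matrix::rowSums(mat)
  depth[depth == 0] <- 1
  out <- Matrix::Diagonal(x = target / depth) %*% mat
  dimnames(out) <- dimnames(mat)
  out
}

# stable row-wise scaling of a matrix to zero mean / unit sd; constant rows
# get sd NA (caller excludes them)
row_scale <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(pmax(rowMeans(m^2) - mu^2, 0) * ncol(m) / (ncol(m) - 1))
  s[s == 0] <- NA_real_
  list(z = (m - mu) / s, sd = s)
}

# add weights w grouped by integer ids into accumulator vector acc
accumulate_by_id <- function(acc, ids, w) {
  if (length(ids) == 0) return(acc)
  tab <- rowsum(as.numeric(w), ids)
  at <- as.integer(rownames(tab))
  acc[at] <- acc[at] + tab[, 1]
  acc
}

seed_from <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
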