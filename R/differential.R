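#' Bias-matched background cell selection
#'
#' Bias features (canonically log10 fragment count and TSS enrichment)
#' are quantile-scaled to `[0, 1]` over the union of group and pool; each
#' group cell then claims its nearest pool cell in scaled bias space,
#' without replacement while the pool lasts (passes repeat for
#' `ratio > 1`). If the pool is exhausted, the remainder is sampled with
#' replacement with a warning.
#'
#' @param group barcodes of the foreground group.
#' @param pool candidate background barcodes (disjoint from `group`).
#' @param bias numeric matrix/data.frame of per-cell bias features with
#'   rownames covering group and pool.
#' @param ratio background size as a multiple of the group size (default 1).
#' @param seed RNG seed (used only for the with-replacement fallback).
#' @return character vector of background barcodes (`ratio * |group|`).
#' @export
match_background_cells <- function(group, pool, bias, ratio = 1, seed = 1L) {
  if (length(intersect(group, pool))) stop("pool must be disjoint from group")
  bias <- as.matrix(bias)
  all_bc <- c(group, pool)
  sc <- apply(bias[all_bc, , drop = FALSE], 2, function(x) {
    if (length(unique(x)) == 1) return(rep(0.5, length(x)))
    (rank(x, ties.method = "average") - 1) / (length(x) - 1)
  })
  rownames(sc) <- all_bc
  g <- sc[group, , drop = FALSE]
  p <- sc[pool, , drop = FALSE]
  d2 <- outer(rowSums(g^2), rowSums(p^2), "+") - 2 * tcrossprod(g, p)

  need <- round(ratio * length(group))
  set.seed(seed)
  chosen <- character(0)
  available <- rep(TRUE, length(pool))
  gi <- 1L
  while (length(chosen) < need && any(available)) {
    di <- d2[gi, ]
    di[!available] <- Inf
    j <- which.min(di)
    chosen <- c(chosen, pool[j])
    available[j] <- FALSE
    gi <- gi %% length(group) + 1L
  }
  if (length(chosen) < need) {
    warning("background pool smaller than required; sampling with replacement")
    chosen <- c(chosen, sample(pool, need - length(chosen), replace = TRUE))
  }
  chosen
}

# two-sided exact rank-sum p by enumeration over group assignments
# (handles ties); used when n1 + n2 <= exact_max
wilcox_exact_enum <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n <- length(r)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  sums <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
  mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
}

# vectorized two-sided normal-approximation rank-sum test with tie
# correction and continuity correction; x, y are matrices (cells x features)
wilcox_approx_p <- function(x, y) {
  n1 <- nrow(x); n2 <- nrow(y); n <- n1 + n2
  vapply(seq_len(ncol(x)), function(j) {
    v <- c(x[, j], y[, j])
    r <- rank(v)
    w <- sum(r[seq_len(n1)])
    mu <- n1 * (n + 1) / 2
    ties <- table(v)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- (abs(w - mu) - 0.5) / sqrt(sig2)
    min(2 * stats::pnorm(-max(z, 0)), 1)
  }, numeric(1))
}

#' Wilcoxon marker-feature identification
#'
#' Two-sided Wilcoxon rank-sum test per feature between a cell group and
#' its (bias-matched) background on depth-normalized counts, with exact
#' enumeration when `n1 + n2 <= exact_max` and a tie-corrected normal
#' approximation otherwise; BH-adjusted FDR. Markers satisfy
#' `fdr <= fdr_cutoff` and `log2_fold_change >= log2fc_cutoff`.
#'
#' @param matrix `feature_matrix` or sparse cells x features counts.
#' @param group,background barcode vectors (rows of `matrix`).
#' @param fdr_cutoff marker FDR threshold (default 0.01).
#' @param log2fc_cutoff marker log2 fold-change threshold (default 1);
#'   fold changes use pseudocount 1 on depth-normalized means.
#' @param target_depth per-cell normalization total (default 10000).
#' @param exact_max largest `n1 + n2` for exact enumeration (default 20).
#' @return data.table(feature, log2_fold_change, p_value, fdr,
#'   mean_in_group, mean_in_background, is_marker).
#' @export
wilcoxon_markers <- function(matrix, group, background, fdr_cutoff = 0.01,
                             log2fc_cutoff = 1, target_depth = 1e4,
                             exact_max = 20L) {
  m <- as_counts(matrix)
  if (length(group) == 0 || length(background) == 0) {
    stop("group and background must be non-empty")
  }
  norm <- normalize_depth(m, target_depth)
  x <- as.matrix(norm[group, , drop = FALSE])
  y <- as.matrix(norm[background, , drop = FALSE])

  mg <- colMeans(x); mb <- colMeans(y)
  lfc <- log2((mg + 1) / (mb + 1))

  if (nrow(x) + nrow(y) <= exact_max) {
    p <- vapply(seq_len(ncol(x)), function(j) {
      if (stats::var(c(x[, j], y[, j])) == 0) return(1)
      wilcox_exact_enum(x[, j], y[, j])
    }, numeric(1))
  } else {
    p <- wilcox_approx_p(x, y)
  }
  fdr <- stats::p.adjust(p, method = "BH")
  feats <- colnames(m) %||% as.character(seq_len(ncol(m)))
  data.table::data.table(
    feature = feats, log2_fold_change = lfc, p_value = p, fdr = fdr,
    mean_in_group = mg, mean_in_background = mb,
    is_marker = fdr <= fdr_cutoff & lfc >= log2fc_cutoff)
}

#' Marker features per cluster against bias-matched backgrounds
#'
#' For each cluster, selects a bias-matched background from all other
#' clusters ([match_background_cells()]) and runs [wilcoxon_markers()].
#'
#' @param matrix `feature_matrix` or sparse counts.
#' @param clusters named cluster labels (names = barcodes).
#' @param bias per-cell bias feature matrix (rownames = barcodes),
#'   canonically `cbind(log10(n_frags), tss_enrichment)`.
#' @param ratio background size multiple (default 1).
#' @param seed RNG seed.
#' @param ... passed to [wilcoxon_markers()].
#' @return data.table of marker results with a `group` column.
#' @export
marker_features <- function(matrix, clusters, bias, ratio = 1, seed = 1L,
                            ...) {
  bcs <- names(clusters)
  res <- lapply(sort(unique(as.character(clusters))), function(cl) {
    grp <- bcs[as.character(clusters) == cl]
    pool <- setdiff(bcs, grp)
    bg <- match_background_cells(grp, pool, bias, ratio, seed)
    out <- wilcoxon_markers(matrix, grp, bg, ...)
    out[, group := cl]
  })
  data.table::rbindlist(res)
}
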