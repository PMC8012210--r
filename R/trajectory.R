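#' Supervised trajectory through ordered clusters
#'
#' Builds a piecewise-linear path through the mean coordinates of a
#' user-ordered cluster sequence (interpolated to 100 points), excludes
#' per-cluster outliers beyond the `outlier_quantile` distance to their
#' own cluster mean, and assigns each retained cell the pseudotime of its
#' nearest path point, rescaled to `[0, 100]`. Optional refinement fits a
#' smoothing spline of coordinates against the initial pseudotime and
#' re-aligns cells to the spline (run once).
#'
#' @param embedding cells x components matrix (retained LSI components).
#' @param labels per-cell cluster labels (same order as rows).
#' @param ordered_clusters cluster sequence defining the trajectory; every
#'   entry must exist in `labels`.
#' @param outlier_quantile per-cluster distance quantile beyond which
#'   cells are excluded (default 0.9).
#' @param spline_smooth refine the path with a smoothing spline.
#' @param n_points interpolated path points (default 100).
#' @return list(pseudotime = named vector in `[0, 100]` (NA for cells off
#'   the trajectory), path = n_points x components matrix,
#'   ordered_clusters, outlier_quantile).
#' @export
fit_trajectory <- function(embedding, labels, ordered_clusters,
                           outlier_quantile = 0.9, spline_smooth = FALSE,
                           n_points = 100L) {
  emb <- retained_embedding(embedding)
  labels <- as.character(labels)
  if (length(ordered_clusters) < 2) stop("need at least 2 ordered clusters")
  missing <- setdiff(as.character(ordered_clusters), labels)
  if (length(missing)) {
    stop("cluster(s) not present in labels: ", paste(missing, collapse = ", "))
  }

  means <- t(vapply(as.character(ordered_clusters), function(cl) {
    colMeans(emb[labels == cl, , drop = FALSE])
  }, numeric(ncol(emb))))

  in_traj <- labels %in% as.character(ordered_clusters)
  keep <- rep(FALSE, nrow(emb))
  for (cl in as.character(ordered_clusters)) {
    ix <- which(labels == cl)
    d <- sqrt(rowSums((emb[ix, , drop = FALSE] -
                         matrix(means[cl, ], length(ix), ncol(emb),
                                byrow = TRUE))^2))
    keep[ix] <- d <= stats::quantile(d, outlier_quantile)
  }

  # piecewise-linear path through cluster means, arc-length interpolated
  seg_len <- sqrt(rowSums(diff(means)^2))
  cum <- c(0, cumsum(seg_len))
  tgrid <- seq(0, cum[length(cum)], length.out = n_points)
  path <- vapply(seq_len(ncol(means)), function(j) {
    stats::approx(cum, means[, j], xout = tgrid)$y
  }, numeric(n_points))

  assign_pt <- function(pts) {
    nn <- knn_index(pts, 1L, query = emb[keep, , drop = FALSE])
    (nn$index[, 1] - 1) / (nrow(pts) - 1) * 100
  }
  pt_keep <- assign_pt(path)

  if (spline_smooth && sum(keep) > 10) {
    ord <- order(pt_keep)
    sp <- vapply(seq_len(ncol(emb)), function(j) {
      fit <- stats::smooth.spline(pt_keep[ord], emb[keep, j][ord], df = 8)
      stats::predict(fit, x = seq(0, 100, length.out = n_points))$y
    }, numeric(n_points))
    path <- sp
    pt_keep <- assign_pt(path)
  }

  pseudotime <- rep(NA_real_, nrow(emb))
  pseudotime[keep] <- pt_keep
  names(pseudotime) <- rownames(emb)
  list(pseudotime = pseudotime, path = path,
       ordered_clusters = as.character(ordered_clusters),
       outlier_quantile = outlier_quantile)
}

#' Pseudotime-binned, smoothed feature matrix
#'
#' Cells on the trajectory are grouped into equal-width pseudotime bins;
#' per bin, depth-normalized log1p feature means are computed, smoothed
#' with a moving average over bins, and empty bins are linearly
#' interpolated.
#'
#' @param matrix `feature_matrix` or sparse cells x features counts.
#' @param trajectory output of [fit_trajectory()].
#' @param n_bins pseudotime bins over `[0, 100]` (default 100).
#' @param smooth_window moving-average window in bins (default 11).
#' @param target_depth per-cell normalization total (default 10000).
#' @return bins x features matrix with bin centers as rownames.
#' @export
pseudotime_binned_matrix <- function(matrix, trajectory, n_bins = 100L,
                                     smooth_window = 11L,
                                     target_depth = 1e4) {
  m <- as_counts(matrix)
  pt <- trajectory$pseudotime
  on_traj <- !is.na(pt)
  m <- m[on_traj, , drop = FALSE]
  pt <- pt[on_traj]
  bins <- pmin(floor(pt / (100 / n_bins)) + 1L, n_bins)
  occupied <- sort(unique(bins))
  if (length(occupied) < n_bins / 2) {
    stop("more than 50% of pseudotime bins are empty; trajectory too sparse")
  }
  norm <- as.matrix(log1p(normalize_depth(m, target_depth)))
  sums <- rowsum(norm, bins)
  counts <- as.vector(table(bins))
  means <- sums / counts

  full <- matrix(NA_real_, n_bins, ncol(m))
  full[occupied, ] <- means
  # linear interpolation of empty bins (edges carried from nearest bin)
  if (length(occupied) < n_bins) {
    for (j in seq_len(ncol(full))) {
      full[, j] <- stats::approx(occupied, full[occupied, j],
                                 xout = seq_len(n_bins), rule = 2)$y
    }
  }
  sm <- apply(full, 2, moving_average, window = smooth_window)
  rownames(sm) <- sprintf("%.1f", (seq_len(n_bins) - 0.5) * (100 / n_bins))
  colnames(sm) <- colnames(m)
  sm
}

#' Correlate feature dynamics along a trajectory
#'
#' Pearson correlation per candidate pair between rows of two
#' pseudotime-binned matrices (same bins), BH-FDR across tested pairs;
#' pairs with `r > r_cutoff` are flagged. Constant profiles are excluded.
#'
#' @param binned_a,binned_b bins x features matrices
#'   ([pseudotime_binned_matrix()]).
#' @param pairs data.table/data.frame(feature_a, feature_b) naming
#'   columns of `binned_a` and `binned_b`.
#' @param r_cutoff minimum correlation (default 0.5).
#' @param fdr_cutoff maximum BH FDR (default 0.05).
#' @return data.table(feature_a, feature_b, correlation, p_value, fdr,
#'   is_link).
#' @export
correlate_along_trajectory <- function(binned_a, binned_b, pairs,
                                       r_cutoff = 0.5, fdr_cutoff = 0.05) {
  pairs <- data.table::as.data.table(pairs)
  stopifnot(nrow(binned_a) == nrow(binned_b))
  za <- row_scale(t(binned_a))$z
  zb <- row_scale(t(binned_b))$z
  ia <- match(pairs$feature_a, colnames(binned_a))
  ib <- match(pairs$feature_b, colnames(binned_b))
  usable <- !is.na(ia) & !is.na(ib) & !is.na(za[ia, 1]) & !is.na(zb[ib, 1])
  if (any(!usable)) {
    message(sum(!usable), " pair(s) with constant or unknown profiles excluded")
  }
  pairs <- pairs[usable]
  ia <- ia[usable]; ib <- ib[usable]
  n <- nrow(binned_a)
  r <- rowSums(za[ia, , drop = FALSE] * zb[ib, , drop = FALSE]) / (n - 1)
  p <- cor_test_p(r, n)
  out <- data.table::data.table(
    feature_a = pairs$feature_a, feature_b = pairs$feature_b,
    correlation = r, p_value = p,
    fdr = stats::p.adjust(p, method = "BH"))
  out[, is_link := correlation > r_cutoff & fdr <= fdr_cutoff]
  out[]
}
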