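#' Low-overlap KNN cell aggregates
#'
#' Seeds are sampled uniformly; each candidate group is the `k` nearest
#' neighbours of its seed (including the seed) in LSI space. Groups
#' sharing more than `max_overlap * k` members with an already retained
#' group are dropped.
#'
#' @param embedding cells x components matrix (retained LSI components).
#' @param k aggregate size (default 100, capped at n).
#' @param n_groups candidate seeds (default 500).
#' @param max_overlap maximum pairwise shared-member fraction (default 0.8).
#' @param seed RNG seed.
#' @return list of integer member-index vectors (named g1, g2, ...).
#' @export
knn_aggregates <- function(embedding, k = 100L, n_groups = 500L,
                           max_overlap = 0.8, seed = 1L) {
  emb <- retained_embedding(embedding)
  n <- nrow(emb)
  if (n < k) stop("fewer cells than aggregate size k")
  set.seed(seed)
  seeds <- sample.int(n, min(n_groups, n))
  if (k == n) {
    groups <- list(g1 = seq_len(n))
    return(groups)
  }
  nn <- knn_index(emb, k - 1L)
  kept <- list()
  for (s in seeds) {
    members <- c(s, nn$index[s, ])
    ok <- TRUE
    for (g in kept) {
      if (length(intersect(members, g)) > max_overlap * k) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- sort(members)
  }
  if (length(kept) < 2) stop("could not form at least 2 aggregates")
  names(kept) <- paste0("g", seq_along(kept))
  kept
}

# aggregate profiles: depth-normalized log1p of summed counts per group
aggregate_profiles <- function(counts, aggregates, target = 1e4) {
  m <- as_counts(counts)
  agg <- do.call(rbind, lapply(aggregates, function(ix) {
    Matrix::colSums(m[ix, , drop = FALSE])
  }))
  depth <- rowSums(agg)
  depth[depth == 0] <- 1
  log1p(agg / depth * target)
}

cor_test_p <- function(r, n) {
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  2 * stats::pt(-abs(tt), n - 2)
}

#' Peak-peak co-accessibility links
#'
#' Pearson correlation of aggregate accessibility profiles for all
#' intra-chromosomal peak pairs whose midpoints are within `max_dist`;
#' pairs reaching `r_cutoff` are returned. Constant peaks are excluded
#' with a message.
#'
#' @param peak_matrix peak `feature_matrix` (cells x peaks).
#' @param aggregates list of cell index vectors ([knn_aggregates()]).
#' @param max_dist maximum midpoint distance in bases (default 250000).
#' @param r_cutoff minimum correlation (default 0.45).
#' @return data.table(peak_a, peak_b, chrom, distance, correlation).
#' @export
coaccessibility <- function(peak_matrix, aggregates, max_dist = 250000L,
                            r_cutoff = 0.45) {
  if (length(aggregates) < 2) stop("need at least 2 aggregates")
  feats <- peak_matrix$features
  prof <- aggregate_profiles(peak_matrix, aggregates)
  sds <- apply(prof, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    message(sum(constant), " constant peak(s) excluded from co-accessibility")
  }
  mids <- (feats$start + feats$end) / 2
  pairs <- list()
  for (chr in unique(feats$chrom)) {
    ix <- which(feats$chrom == chr & !constant)
    if (length(ix) < 2) next
    ord <- ix[order(mids[ix])]
    m <- mids[ord]
    hi <- findInterval(m + max_dist, m)
    a <- rep.int(seq_along(ord), pmax(hi - seq_along(ord), 0L))
    b <- sequence(pmax(hi - seq_along(ord), 0L), from = seq_along(ord) + 1L)
    if (length(a) == 0) next
    pairs[[chr]] <- data.table::data.table(ia = ord[a], ib = ord[b],
                                           chrom = chr,
                                           distance = m[b] - m[a])
  }
  pairs <- data.table::rbindlist(pairs)
  if (nrow(pairs) == 0) {
    return(data.table::data.table(peak_a = character(), peak_b = character(),
                                  chrom = character(), distance = numeric(),
                                  correlation = numeric()))
  }
  z <- row_scale(t(prof))$z
  n <- length(aggregates)
  pairs[, correlation := rowSums(z[ia, , drop = FALSE] *
                                   z[ib, , drop = FALSE]) / (n - 1)]
  out <- pairs[correlation >= r_cutoff,
               .(peak_a = feats$name[ia], peak_b = feats$name[ib],
                 chrom, distance, correlation)]
  out[]
}

#' Peak-to-gene links against a matched expression matrix
#'
#' For every gene, all peaks with midpoint within `max_dist` of the TSS
#' are tested: Pearson correlation between aggregate peak accessibility
#' and aggregate gene expression, BH-FDR across all tested pairs, and
#' links require `r >= r_cutoff` and `fdr <= fdr_cutoff`.
#'
#' @param peak_matrix peak `feature_matrix`.
#' @param expression cells x genes counts (same cells, columns named by
#'   gene).
#' @param aggregates list of cell index vectors.
#' @param gene_tss data.table(chrom, pos, name) of gene TSS.
#' @param max_dist maximum TSS-to-peak-midpoint distance (default 250000).
#' @param r_cutoff minimum correlation (default 0.45).
#' @param fdr_cutoff maximum BH FDR (default 0.05).
#' @param all_pairs return all tested pairs instead of links only.
#' @return data.table(peak, gene, chrom, distance, correlation, p_value,
#'   fdr, is_link).
#' @export
peak2gene <- function(peak_matrix, expression, aggregates, gene_tss,
                      max_dist = 250000L, r_cutoff = 0.45,
                      fdr_cutoff = 0.05, all_pairs = FALSE) {
  gene_tss <- data.table::as.data.table(gene_tss)
  expression <- as_counts(expression)
  missing <- setdiff(gene_tss$name, colnames(expression))
  if (length(missing)) {
    message(length(missing), " gene(s) absent from expression; skipped")
    gene_tss <- gene_tss[!name %in% missing]
  }
  feats <- peak_matrix$features
  pa <- aggregate_profiles(peak_matrix, aggregates)
  ea <- aggregate_profiles(expression, aggregates)
  mids <- (feats$start + feats$end) / 2

  cand <- list()
  for (i in seq_len(nrow(gene_tss))) {
    ix <- which(feats$chrom == gene_tss$chrom[i] &
                  abs(mids - gene_tss$pos[i]) <= max_dist)
    if (length(ix) == 0) next
    cand[[i]] <- data.table::data.table(
      peak_idx = ix, gene = gene_tss$name[i],
      chrom = gene_tss$chrom[i],
      distance = abs(mids[ix] - gene_tss$pos[i]))
  }
  cand <- data.table::rbindlist(cand)
  if (nrow(cand) == 0) stop("no peak-gene pairs within max_dist")

  zp <- row_scale(t(pa))$z
  ze <- row_scale(t(ea))$z
  usable <- !is.na(zp[cand$peak_idx, 1]) & !is.na(ze[match(cand$gene, colnames(ea)), 1])
  cand <- cand[usable]
  n <- length(aggregates)
  cand[, correlation := rowSums(zp[peak_idx, , drop = FALSE] *
                                  ze[match(gene, colnames(ea)), , drop = FALSE]) / (n - 1)]
  cand[, p_value := cor_test_p(correlation, n)]
  cand[, fdr := stats::p.adjust(p_value, method = "BH")]
  cand[, is_link := correlation >= r_cutoff & fdr <= fdr_cutoff]
  cand[, peak := feats$name[peak_idx]]
  out <- cand[, .(peak, gene, chrom, distance, correlation, p_value, fdr,
                  is_link)]
  if (!all_pairs) out <- out[is_link == TRUE]
  out[]
}
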