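#' Read position frequency matrices in JASPAR tab text format
#'
#' Records look like `>ID NAME` followed by four rows
#' `A [ 4 19 0 ... ]` (brackets optional) for A, C, G, T.
#'
#' @param path motif file path.
#' @return named list of 4 x width count matrices (rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no motif records found in ", path)
  out <- list()
  for (s in starts) {
    header <- sub("^>\\s*", "", lines[s])
    nm <- strsplit(header, "\\s+")[[1]]
    nm <- if (length(nm) >= 2) nm[2] else nm[1]
    rows <- lapply(lines[s + 1:4], function(l) {
      l <- gsub("[][]", " ", l)
      v <- strsplit(trimws(l), "\\s+")[[1]]
      as.numeric(v[-1])
    })
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    out[[nm]] <- pfm
  }
  out
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Column probabilities (with a 0.25-per-base pseudocount) scored as
#' `log2(p / 0.25)` against a uniform background.
#'
#' @param pfm 4 x width count matrix (rows A, C, G, T).
#' @return 4 x width log-odds matrix.
#' @export
pfm_to_pwm <- function(pfm) {
  p <- sweep(pfm + 0.25, 2, colSums(pfm) + 1, "/")
  log2(p / 0.25)
}

dna_codes <- function(seq_char) {
  code <- match(strsplit(seq_char, "")[[1]], c("A", "C", "G", "T"))
  code
}

# score every start position of an integer-coded sequence under a PWM;
# NA codes (N bases / separators) give -Inf
pwm_scan_scores <- function(codes, pwm) {
  L <- ncol(pwm)
  n <- length(codes) - L + 1L
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- pwm[cbind(codes[j:(j + n - 1L)], j)]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

reverse_complement_pwm <- function(pwm) {
  pwm[4:1, rev(seq_len(ncol(pwm))), drop = FALSE]
}

#' Scan peak sequences for PWM matches
#'
#' Log-odds scoring against a uniform 0.25 background on both strands; a
#' peak matches when its best position score reaches the threshold.
#' Match positions (genomic center of the matching window, with strand)
#' are recorded for footprinting.
#'
#' @param peaks data.table(chrom, start, end) (half-open).
#' @param genome named `Biostrings::DNAStringSet`.
#' @param pwms named list of PFM count matrices ([read_jaspar()]) or
#'   log-odds PWMs (used as-is when any entry is negative).
#' @param min_score absolute log-odds threshold, or `NULL` for
#'   `score_frac` of each motif's maximum achievable score.
#' @param score_frac fraction of the maximum score used when
#'   `min_score` is `NULL` (default 0.8).
#' @return list(matches = sparse binary peaks x motifs matrix,
#'   positions = data.table(motif, chrom, pos, strand, score, peak)).
#' @export
scan_motifs <- function(peaks, genome, pwms, min_score = NULL,
                        score_frac = 0.8) {
  peaks <- data.table::as.data.table(peaks)
  if (any(!peaks$chrom %in% names(genome)) ||
      any(peaks$end > Biostrings::width(genome)[
        match(peaks$chrom, names(genome))])) {
    stop("peak interval beyond the supplied genome sequence")
  }
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    peaks$start[i] + 1L, peaks$end[i]))
  }, character(1))

  maxL <- max(vapply(pwms, ncol, integer(1)))
  widths <- nchar(seqs)
  # concatenate peak sequences with NA separators so one scan covers all
  sep <- rep(NA_integer_, maxL)
  codes <- unlist(lapply(seqs, function(s) c(dna_codes(s), sep)))
  block_start <- cumsum(c(0, head(widths + maxL, -1))) # 0-based block offsets
  pos2peak <- rep(seq_along(seqs), widths + maxL)

  match_i <- integer(0); match_j <- integer(0)
  positions <- list()
  for (mi in seq_along(pwms)) {
    pwm <- pwms[[mi]]
    if (all(pwm >= 0)) pwm <- pfm_to_pwm(pwm)
    L <- ncol(pwm)
    thr <- min_score %||% (score_frac * sum(apply(pwm, 2, max)))
    fwd <- pwm_scan_scores(codes, pwm)
    rev <- pwm_scan_scores(codes, reverse_complement_pwm(pwm))
    score <- pmax(fwd, rev)
    hit <- which(score >= thr)
    if (length(hit) == 0) next
    pk <- pos2peak[hit]
    off <- hit - 1L - block_start[pk]          # 0-based offset within peak
    valid <- off + L <= widths[pk]
    hit <- hit[valid]; pk <- pk[valid]; off <- off[valid]
    if (length(hit) == 0) next
    match_i <- c(match_i, unique(pk))
    match_j <- c(match_j, rep(mi, length(unique(pk))))
    positions[[names(pwms)[mi]]] <- data.table::data.table(
      motif = names(pwms)[mi],
      chrom = peaks$chrom[pk],
      pos = peaks$start[pk] + off + L %/% 2L,
      strand = ifelse(fwd[hit] >= rev[hit], "+", "-"),
      score = score[hit],
      peak = pk)
  }
  matches <- Matrix::sparseMatrix(i = match_i, j = match_j, x = 1,
                                  dims = c(nrow(peaks), length(pwms)),
                                  dimnames = list(NULL, names(pwms)))
  list(matches = matches, positions = data.table::rbindlist(positions))
}

#' Hypergeometric enrichment of annotations in a peak subset
#'
#' Upper-tail hypergeometric test `P(X >= k)` of each annotation column
#' within a selected peak subset against the peak universe, BH-adjusted
#' across annotations. Also usable for arbitrary region-set overlap
#' enrichment by supplying a binary overlap matrix.
#'
#' @param selected indices (or logical mask) of the selected peaks within
#'   the universe.
#' @param annotation binary peaks x annotations matrix over the universe.
#' @return data.table(annotation, k, K, n, N, fold_enrichment, p_value,
#'   fdr).
#' @export
hypergeom_enrichment <- function(selected, annotation) {
  if (is.logical(selected)) selected <- which(selected)
  if (length(selected) == 0) stop("empty peak selection")
  annotation <- methods::as(annotation, "CsparseMatrix")
  N <- nrow(annotation)
  n <- length(selected)
  K <- Matrix::colSums(annotation > 0)
  k <- Matrix::colSums(annotation[selected, , drop = FALSE] > 0)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- ifelse(K > 0, (k / n) / (K / N), NA_real_)
  data.table::data.table(
    annotation = colnames(annotation) %||% as.character(seq_along(K)),
    k = as.integer(k), K = as.integer(K), n = n, N = N,
    fold_enrichment = fold, p_value = p,
    fdr = stats::p.adjust(p, method = "BH"))
}

#' GC/accessibility-matched background peak sets
#'
#' For every peak, `n_background` peaks are sampled with replacement from
#' its nearest neighbors in standardized (GC fraction, log1p mean
#' accessibility) space, excluding the peak itself.
#'
#' @param gc_fraction per-peak GC fraction.
#' @param mean_accessibility per-peak mean count across cells.
#' @param n_background background draws per peak (default 50).
#' @param n_neighbors neighborhood sampled from (default
#'   `max(100, 2 * n_background)`, capped at n-1).
#' @param seed RNG seed.
#' @return integer matrix peaks x n_background of background peak indices.
#' @export
select_background_peaks <- function(gc_fraction, mean_accessibility,
                                    n_background = 50L, n_neighbors = NULL,
                                    seed = 1L) {
  n <- length(gc_fraction)
  if (n < n_background + 1) stop("need more peaks than n_background")
  feats <- cbind(gc_fraction, log1p(mean_accessibility))
  feats <- apply(feats, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  k <- min(n_neighbors %||% max(100L, 2L * n_background), n - 1L)
  nn <- knn_index(feats, k)
  set.seed(seed)
  draws <- matrix(sample.int(k, n * n_background, replace = TRUE), n)
  bg <- matrix(nn$index[cbind(rep(seq_len(n), n_background),
                              as.vector(draws))], n)
  bg
}

#' chromVAR-style per-cell motif deviations
#'
#' For each motif and cell, the observed count in motif peaks is compared
#' with the depth expectation
#' `depth(cell) * sum(motif peak counts) / sum(all counts)`; the raw
#' deviation `(obs - exp) / exp` is centered and scaled by the mean and sd
#' of the same statistic over the GC/accessibility-matched background
#' peak sets, giving a bias-corrected z-score. Cells are processed in
#' chunks to bound memory.
#'
#' @param peak_matrix `feature_matrix` (kind "peak") or sparse
#'   cells x peaks counts.
#' @param annotation binary peaks x motifs match matrix.
#' @param backgrounds integer peaks x n_background matrix from
#'   [select_background_peaks()].
#' @param chunk_size cells per streaming chunk (default 5000).
#' @return list(raw, corrected, z): cells x motifs matrices.
#' @export
compute_deviations <- function(peak_matrix, annotation, backgrounds,
                               chunk_size = 5000L) {
  counts <- as_counts(peak_matrix)
  depth <- Matrix::rowSums(counts)
  if (any(depth == 0)) stop("zero-depth cell(s); filter before deviations")
  f <- Matrix::colSums(counts)
  total <- sum(f)
  M <- methods::as(annotation, "CsparseMatrix")
  n_bg <- ncol(backgrounds)

  raw_dev <- function(A) {
    expect_frac <- as.vector(Matrix::crossprod(A, f)) / total
    out <- matrix(0, nrow(counts), ncol(A))
    for (s in seq(1, nrow(counts), by = chunk_size)) {
      e <- min(s + chunk_size - 1L, nrow(counts))
      obs <- as.matrix(counts[s:e, , drop = FALSE] %*% A)
      expm <- outer(depth[s:e], expect_frac)
      chunk <- (obs - expm) / expm
      chunk[expm == 0] <- 0
      out[s:e, ] <- chunk
    }
    out
  }

  raw <- raw_dev(M)
  bg_mean <- matrix(0, nrow(counts), ncol(M))
  bg_m2 <- matrix(0, nrow(counts), ncol(M))
  idx <- methods::as(M, "TsparseMatrix")
  for (b in seq_len(n_bg)) {
    Mb <- Matrix::sparseMatrix(i = backgrounds[idx@i + 1L, b],
                               j = idx@j + 1L, x = 1,
                               dims = dim(M))
    rb <- raw_dev(Mb)
    delta <- rb - bg_mean
    bg_mean <- bg_mean + delta / b
    bg_m2 <- bg_m2 + delta * (rb - bg_mean)
  }
  bg_sd <- sqrt(bg_m2 / max(n_bg - 1, 1))
  corrected <- raw - bg_mean
  z <- corrected / bg_sd
  z[bg_sd == 0] <- 0
  dimnames(z) <- list(rownames(counts), colnames(M))
  dimnames(raw) <- dimnames(z)
  dimnames(corrected) <- dimnames(z)
  list(raw = raw, corrected = corrected, z = z)
}

#' Nominate positive TF regulators
#'
#' Correlates per-group mean motif deviation z-scores with per-group mean
#' expression (or gene score) of the corresponding TF gene; TFs with
#' `r > correlation_cutoff` and BH-adjusted p below `fdr_cutoff` are
#' flagged as positive regulators.
#'
#' @param z cells x motifs deviation z-score matrix.
#' @param expression cells x genes matrix (counts; depth-normalized and
#'   log1p internally).
#' @param groups per-cell group labels (clusters or pseudotime bins).
#' @param mapping data.frame(motif, gene) linking motif and gene
#'   namespaces; unmapped motifs are logged and excluded.
#' @param correlation_cutoff minimum Pearson r (default 0.5).
#' @param fdr_cutoff maximum BH-adjusted p (default 0.05).
#' @return data.table(motif, gene, correlation, p_value, fdr,
#'   is_positive_regulator).
#' @export
positive_tf_regulators <- function(z, expression, groups, mapping,
                                   correlation_cutoff = 0.5,
                                   fdr_cutoff = 0.05) {
  mapping <- data.table::as.data.table(mapping)
  expression <- as_counts(expression)
  expr <- as.matrix(log1p(normalize_depth(expression)))
  ok <- mapping$motif %in% colnames(z) & mapping$gene %in% colnames(expr)
  if (any(!ok)) {
    message(sum(!ok), " TF(s) unmapped between motif and gene namespaces; excluded")
  }
  mapping <- mapping[ok]
  g <- as.character(groups)
  gz <- rowsum_sparse(z, g) / as.vector(table(factor(g)))
  ge <- rowsum_sparse(expr, g) / as.vector(table(factor(g)))
  n <- nrow(gz)
  res <- mapping[, {
    r <- suppressWarnings(stats::cor(gz[, motif], ge[, gene]))
    tt <- if (is.na(r) || abs(r) == 1) NA_real_ else
      r * sqrt((n - 2) / (1 - r^2))
    p <- if (is.na(r)) 1 else if (abs(r) == 1) 0 else
      2 * stats::pt(-abs(tt), n - 2)
    .(correlation = r, p_value = p)
  }, by = .(motif, gene)]
  res[, fdr := stats::p.adjust(p_value, method = "BH")]
  res[, is_positive_regulator := !is.na(correlation) &
        correlation > correlation_cutoff & fdr <= fdr_cutoff]
  res[]
}
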