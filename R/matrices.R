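#' Feature-addressed sparse cell matrix
#'
#' Light container pairing a sparse cells x features count matrix with
#' its interval-addressed feature set (tiles, peaks, or genes).
#'
#' @param counts sparse cells x features matrix (rows named by barcode).
#' @param features data.table(chrom, start, end, name), one row per column.
#' @param kind one of "tile", "peak", "gene".
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(counts, features, kind) {
  features <- data.table::as.data.table(features)
  stopifnot(ncol(counts) == nrow(features), all(counts@x >= 0))
  colnames(counts) <- features$name
  structure(list(counts = counts, features = features, kind = kind),
            class = "feature_matrix")
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix (%s): %d cells x %d features, %.0f nonzero\n",
              x$kind, nrow(x$counts), ncol(x$counts),
              length(x$counts@x)))
  invisible(x)
}

#' Genome-wide fixed-width tile feature set
#'
#' Every chromosome is partitioned into `tile_size`-bp tiles; the
#' terminal tile is truncated at the chromosome end.
#'
#' @param chrom_sizes named integer vector.
#' @param tile_size tile width in bases (default 500).
#' @return data.table(chrom, start, end, name) in genome order.
#' @export
tile_features <- function(chrom_sizes, tile_size = 500L) {
  data.table::rbindlist(lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    n <- ceiling(len / tile_size)
    start <- (seq_len(n) - 1L) * as.integer(tile_size)
    data.table::data.table(chrom = chr, start = start,
                           end = pmin(start + as.integer(tile_size), len),
                           name = sprintf("%s:%d-%d", chr, start,
                                          pmin(start + as.integer(tile_size), len)))
  }))
}

#' Build the genome-wide tile matrix
#'
#' Entry (cell, tile) is the summed insertion weight whose position falls
#' in the tile (`floor(pos / tile_size)`), computed chunk-by-chunk per
#' chromosome. With `binarize`, entries are clipped to 0/1.
#'
#' @param store a `fragment_store`.
#' @param tile_size tile width in bases (default 500).
#' @param binarize store presence/absence instead of counts.
#' @param barcodes optional barcode subset (rows).
#' @return a `feature_matrix` of kind "tile".
#' @export
build_tile_matrix <- function(store, tile_size = 500L, binarize = FALSE,
                              barcodes = NULL) {
  feats <- tile_features(store$chrom_sizes, tile_size)
  offsets <- c(0L, cumsum(table(factor(feats$chrom,
                                       levels = names(store$chrom_sizes)))))
  names(offsets) <- c(names(store$chrom_sizes), "end")
  bcs <- barcodes %||% store$barcodes$barcode
  bc_map <- match(store$barcodes$barcode, bcs) # store barcode id -> row

  trip <- vector("list", length(store$chrom_sizes))
  for (chr in names(store$chrom_sizes)) {
    ins <- chunk_insertions(store, chr)
    if (is.null(ins)) next
    ins <- ins[!is.na(bc_map[bc])]
    if (nrow(ins) == 0) next
    agg <- ins[, .(w = sum(weight)),
               by = .(row = bc_map[bc], tile = pos %/% as.integer(tile_size))]
    agg[, col := offsets[[chr]] + tile + 1L]
    trip[[chr]] <- agg[, .(row, col, w)]
  }
  trip <- data.table::rbindlist(trip[!vapply(trip, is.null, logical(1))])
  x <- if (nrow(trip)) trip$w else numeric()
  if (binarize && length(x)) x <- pmin(x, 1)
  counts <- Matrix::sparseMatrix(
    i = trip$row, j = trip$col, x = as.numeric(x),
    dims = c(length(bcs), nrow(feats)),
    dimnames = list(bcs, NULL))
  feature_matrix(counts, feats, "tile")
}

#' Build a peak count matrix
#'
#' Entry (cell, peak) is the summed insertion weight inside each peak's
#' half-open interval. Peaks must be pairwise disjoint (guaranteed by
#' [iterative_overlap_merge()]).
#'
#' @param store a `fragment_store`.
#' @param peaks a peak set (data.table with chrom, start, end, name).
#' @param barcodes optional barcode subset.
#' @return a `feature_matrix` of kind "peak".
#' @export
build_peak_matrix <- function(store, peaks, barcodes = NULL) {
  peaks <- data.table::as.data.table(peaks)
  data.table::setorder(peaks, chrom, start)
  if (!"name" %in% names(peaks)) {
    peaks[, name := sprintf("%s:%d-%d", chrom, start, end)]
  }
  overl <- peaks[, any(start[-1] < head(end, -1)), by = chrom]$V1
  if (any(overl)) stop("peaks must be non-overlapping")
  peaks[, col := .I]
  bcs <- barcodes %||% store$barcodes$barcode
  bc_map <- match(store$barcodes$barcode, bcs)

  trip <- list()
  for (chr in unique(peaks$chrom)) {
    if (!chr %in% names(store$chrom_sizes)) next
    ins <- chunk_insertions(store, chr)
    if (is.null(ins)) next
    ins <- ins[!is.na(bc_map[bc])]
    if (nrow(ins) == 0) next
    pk <- peaks[chrom == chr]
    idx <- findInterval(ins$pos, pk$start)
    inside <- idx > 0 & ins$pos < pk$end[pmax(idx, 1L)]
    if (!any(inside)) next
    agg <- ins[inside][, .(w = sum(weight)),
                       by = .(row = bc_map[bc], col = pk$col[idx[inside]])]
    trip[[chr]] <- agg
  }
  trip <- data.table::rbindlist(trip)
  counts <- Matrix::sparseMatrix(
    i = if (nrow(trip)) trip$row else integer(),
    j = if (nrow(trip)) trip$col else integer(),
    x = if (nrow(trip)) as.numeric(trip$w) else numeric(),
    dims = c(length(bcs), nrow(peaks)), dimnames = list(bcs, NULL))
  feature_matrix(counts, peaks[, .(chrom, start, end, name)], "peak")
}
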