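#' TSS enrichment scoring parameters
#'
#' @param window bases collected on each side of every TSS (default 2000).
#' @param center_width width in bases of the signal window centered on the
#'   TSS (default 101).
#' @param flank_width width in bases of the background window at each
#'   outer edge of the collected region (default 100).
#' @param pseudocount added to the per-base center and flank means before
#'   taking their ratio (default 0.1).
#' @return a `tss_params` list.
#' @export
tss_params <- function(window = 2000L, center_width = 101L,
                       flank_width = 100L, pseudocount = 0.1) {
  stopifnot(center_width < 2 * window, flank_width <= window,
            center_width >= 1, flank_width >= 1)
  structure(list(window = as.integer(window),
                 center_width = as.integer(center_width),
                 flank_width = as.integer(flank_width),
                 pseudocount = pseudocount), class = "tss_params")
}

#' Read transcription start sites from a BED6 file
#'
#' The TSS is the interval start for plus-strand records and `end - 1`
#' for minus-strand records.
#'
#' @param path BED6 path (strand in column 6).
#' @return data.table(chrom, pos, strand, name).
#' @export
read_tss_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 6) stop("TSS BED must have 6 columns (strand required)")
  data.table::data.table(
    chrom = as.character(dt[[1]]),
    pos = ifelse(dt[[6]] == "-", as.integer(dt[[3]]) - 1L, as.integer(dt[[2]])),
    strand = as.character(dt[[6]]),
    name = as.character(dt[[4]])
  )
}

# per-barcode-id center/flank insertion totals around TSS
tss_window_sums <- function(store, tss, params) {
  tss <- data.table::as.data.table(tss)
  w <- params$window
  keep <- tss$chrom %in% names(store$chrom_sizes) &
    tss$pos - w >= 0 & tss$pos + w < store$chrom_sizes[tss$chrom]
  tss <- tss[keep]
  if (nrow(tss) == 0) stop("no usable TSS inside chromosome bounds after windowing")

  half_c <- (params$center_width - 1L) %/% 2L
  n_bc <- nrow(store$barcodes)
  center <- numeric(n_bc); flank <- numeric(n_bc); total <- numeric(n_bc)
  for (chr in unique(tss$chrom)) {
    ins <- chunk_insertions(store, chr)
    if (is.null(ins)) next
    tchr <- tss[chrom == chr]
    lo <- findInterval(tchr$pos - w - 0.5, ins$pos) + 1L
    hi <- findInterval(tchr$pos + w + 0.5, ins$pos)
    n_hit <- pmax(hi - lo + 1L, 0L)
    if (sum(n_hit) == 0) next
    tss_idx <- rep.int(seq_len(nrow(tchr)), n_hit)
    ins_idx <- sequence(n_hit, from = lo)
    off <- ins$pos[ins_idx] - tchr$pos[tss_idx]
    off <- ifelse(tchr$strand[tss_idx] == "-", -off, off)
    bc <- ins$bc[ins_idx]
    wgt <- ins$weight[ins_idx]
    in_center <- abs(off) <= half_c
    in_flank <- abs(off) > w - params$flank_width
    center <- accumulate_by_id(center, bc[in_center], wgt[in_center])
    flank <- accumulate_by_id(flank, bc[in_flank], wgt[in_flank])
    total <- accumulate_by_id(total, bc, wgt)
  }
  list(center = center, flank = flank, total = total,
       n_tss = nrow(tss), params = params)
}

#' Per-cell TSS enrichment scores
#'
#' Insertions within `window` of every usable TSS are aggregated into a
#' strand-oriented profile per cell (minus-strand TSS are mirrored). The
#' score is the ratio of the mean per-base insertion rate in the
#' `center_width` window centered on the TSS to the mean rate in the two
#' outermost `flank_width` background windows, each stabilized by the
#' pseudocount. Cells with no insertions in any TSS window score 0.
#'
#' @param store a `fragment_store`.
#' @param tss data.frame(chrom, pos, strand) or path handled by
#'   [read_tss_bed()].
#' @param params a [tss_params()] object.
#' @return named numeric vector of scores, one per barcode.
#' @export
tss_enrichment <- function(store, tss, params = tss_params()) {
  sums <- tss_window_sums(store, tss, params)
  c_mean <- sums$center / params$center_width
  f_mean <- sums$flank / (2 * params$flank_width)
  score <- (c_mean + params$pseudocount) / (f_mean + params$pseudocount)
  score[sums$total == 0] <- 0
  stats::setNames(score, store$barcodes$barcode)
}

#' Per-cell quality-control table
#'
#' One row per barcode with fragment count and TSS enrichment, plus a
#' per-sample fragment-size histogram (1-1000 bp) and an optional
#' fraction-of-fragments-near-promoters metric (midpoint within `window`
#' of a TSS; reported, never used for filtering).
#'
#' @inheritParams tss_enrichment
#' @return list with `cells` (data.table: barcode, sample, n_frags,
#'   tss_enrichment, fraction_in_promoters) and `size_histogram`
#'   (data.table: sample, size, weight).
#' @export
compute_cell_qc <- function(store, tss, params = tss_params()) {
  if (is.character(tss)) tss <- read_tss_bed(tss)
  score <- tss_enrichment(store, tss, params)

  n_bc <- nrow(store$barcodes)
  prom <- numeric(n_bc)
  hist_list <- list()
  tss <- data.table::as.data.table(tss)
  for (chr in names(store$chrom_sizes)) {
    chunk <- read_chunk(store, chr)
    if (is.null(chunk)) next
    size <- pmin(pmax(chunk$end - chunk$start, 1L), 1000L)
    hist_list[[chr]] <- data.table::data.table(
      sample = store$barcodes$sample[chunk$bc], size = size,
      weight = chunk$count)
    tpos <- sort(tss[chrom == chr, pos])
    if (length(tpos)) {
      mid <- (chunk$start + chunk$end) %/% 2L
      near <- findInterval(mid + params$window + 0.5, tpos) -
        findInterval(mid - params$window - 0.5, tpos) > 0
      prom <- accumulate_by_id(prom, chunk$bc[near], chunk$count[near])
    }
  }
  cells <- data.table::data.table(
    barcode = store$barcodes$barcode,
    sample = store$barcodes$sample,
    n_frags = store$barcodes$n_frags,
    tss_enrichment = unname(score),
    fraction_in_promoters = prom / pmax(store$barcodes$n_frags, 1L)
  )
  size_hist <- data.table::rbindlist(hist_list)[
    , .(weight = sum(weight)), by = .(sample, size)]
  data.table::setorder(size_hist, sample, size)
  list(cells = cells, size_histogram = size_hist[])
}

#' Filter cells on QC thresholds
#'
#' Retains barcodes with `tss_enrichment >= min_tss` and
#' `n_frags >= min_frags` (both inclusive) and sets `pass_qc`.
#'
#' @param qc the `cells` table from [compute_cell_qc()].
#' @param min_tss minimum TSS enrichment (default 4).
#' @param min_frags minimum fragments per cell (default 1000).
#' @return list with `cells` (input plus `pass_qc` column) and
#'   `retained` (character vector of passing barcodes).
#' @export
filter_cells <- function(qc, min_tss = 4, min_frags = 1000) {
  stopifnot(min_tss >= 0, min_frags >= 0)
  qc <- data.table::as.data.table(qc)
  qc <- data.table::copy(qc)
  qc[, pass_qc := tss_enrichment >= min_tss & n_frags >= min_frags]
  retained <- qc[pass_qc == TRUE, barcode]
  if (length(retained) == 0) {
    stop("no cells pass QC; consider lowering min_tss (", min_tss,
         ") or min_frags (", min_frags, ")")
  }
  list(cells = qc[], retained = retained)
}
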