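#' Sample-aware pseudo-bulk replicate plan
#'
#' Within each cluster, samples contributing at least `min_cells` cells
#' each become a replicate (subsampled down to `max_cells`). When fewer
#' than `min_replicates` samples qualify, replicates are instead drawn by
#' sampling `sample_ratio` of the cluster's cells without replacement per
#' replicate, preferring cells not yet used (minimal reuse). Clusters
#' whose fallback replicates would fall below `min_cells` are flagged and
#' excluded.
#'
#' @param cells data.frame with barcode, sample and cluster columns.
#' @param min_cells minimum cells per replicate (default 40).
#' @param max_cells maximum cells per replicate (default 500).
#' @param min_replicates minimum replicates per retained cluster (default 2).
#' @param sample_ratio fraction of cluster cells per fallback replicate
#'   (default 0.8).
#' @param seed RNG seed.
#' @return list(plan = data.table(cluster, replicate, sample, members
#'   list-column), flagged = character vector of excluded clusters).
#' @export
make_pseudobulk_plan <- function(cells, min_cells = 40L, max_cells = 500L,
                                 min_replicates = 2L, sample_ratio = 0.8,
                                 seed = 1L) {
  cells <- data.table::as.data.table(cells)
  if (!all(c("barcode", "sample", "cluster") %in% names(cells))) {
    stop("cells must have barcode, sample and cluster columns")
  }
  set.seed(seed)
  rows <- list(); flagged <- character()
  for (cl in sort(unique(as.character(cells$cluster)))) {
    sub <- cells[as.character(cluster) == cl]
    tab <- sub[, .N, by = sample][N >= min_cells]
    if (nrow(tab) >= min_replicates) {
      for (i in seq_len(nrow(tab))) {
        mem <- sub[sample == tab$sample[i], barcode]
        if (length(mem) > max_cells) mem <- sample(mem, max_cells)
        rows[[length(rows) + 1]] <- data.table::data.table(
          cluster = cl, replicate = paste0(cl, "_rep", i),
          sample = tab$sample[i], members = list(mem))
      }
    } else {
      size <- min(floor(sample_ratio * nrow(sub)), max_cells)
      if (size < min_cells) { flagged <- c(flagged, cl); next }
      unused <- sub$barcode
      for (i in seq_len(min_replicates)) {
        if (length(unused) >= size) {
          mem <- sample(unused, size)
        } else {
          extra <- sample(setdiff(sub$barcode, unused),
                          size - length(unused))
          mem <- c(unused, extra)
        }
        unused <- setdiff(unused, mem)
        rows[[length(rows) + 1]] <- data.table::data.table(
          cluster = cl, replicate = paste0(cl, "_rep", i),
          sample = "subsampled", members = list(mem))
      }
    }
  }
  if (length(rows) == 0) stop("no cluster can satisfy the pseudo-bulk plan")
  list(plan = data.table::rbindlist(rows), flagged = flagged)
}

#' Per-group insertion coverage in bedGraph form
#'
#' For each cell group, per-base insertion counts are emitted as
#' canonical bedGraph intervals (adjacent equal-valued bases merged).
#' Total interval mass equals twice the group's fragment weight.
#'
#' @param store a `fragment_store`.
#' @param groups named list of barcode vectors.
#' @param out optional directory; when given, one
#'   `<group>.bedGraph` file is written per group.
#' @return named list of data.table(chrom, start, end, value).
#' @export
export_group_coverage <- function(store, groups, out = NULL) {
  if (any(lengths(groups) == 0)) stop("empty group in coverage export")
  bc_id <- stats::setNames(seq_len(nrow(store$barcodes)),
                           store$barcodes$barcode)
  res <- lapply(groups, function(members) {
    ids <- unname(bc_id[members])
    per_chrom <- lapply(names(store$chrom_sizes), function(chr) {
      ins <- chunk_insertions(store, chr, bc_ids = ids)
      if (is.null(ins)) return(NULL)
      agg <- ins[, .(value = sum(weight)), by = pos]
      data.table::setorder(agg, pos)
      runs <- c(TRUE, diff(agg$pos) != 1L | diff(agg$value) != 0)
      rid <- cumsum(runs)
      agg[, .(chrom = chr, start = pos[1], end = pos[.N] + 1L,
              value = value[1]), by = .(rid)][, rid := NULL][]
    })
    data.table::rbindlist(per_chrom)
  })
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (g in names(res)) {
      data.table::fwrite(res[[g]], file.path(out, paste0(g, ".bedGraph")),
                         sep = "\t", col.names = FALSE)
    }
  }
  res
}

#' Naive summit caller on an insertion coverage profile
#'
#' Smooths the per-base insertion profile with a centered moving average
#' and reports local maxima with smoothed height at least `min_score`.
#' On a plateau the leftmost position is chosen. This internal caller
#' exists so the pipeline and tests run without an external peak caller;
#' externally called summit BEDs can be supplied instead
#' ([read_summits_bed()]).
#'
#' @param coverage data.table(chrom, start, end, value) from
#'   [export_group_coverage()].
#' @param smoothing_window moving-average window in bases (default 75).
#' @param min_score minimum smoothed height (default 1).
#' @return data.table(chrom, pos, score).
#' @export
call_summits_naive <- function(coverage, smoothing_window = 75L,
                               min_score = 1) {
  coverage <- data.table::as.data.table(coverage)
  out <- lapply(unique(coverage$chrom), function(chr) {
    cc <- coverage[chrom == chr]
    lo <- min(cc$start); hi <- max(cc$end)
    v <- numeric(hi - lo)
    for (i in seq_len(nrow(cc))) {
      v[(cc$start[i] - lo + 1L):(cc$end[i] - lo)] <- cc$value[i]
    }
    sm <- moving_average(v, smoothing_window)
    r <- rle(sm)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    prev <- c(-Inf, r$values[-length(r$values)])
    nxt <- c(r$values[-1], -Inf)
    is_summit <- r$values > prev & r$values > nxt & r$values >= min_score
    if (!any(is_summit)) return(NULL)
    data.table::data.table(chrom = chr,
                           pos = lo + starts[is_summit] - 1L,
                           score = r$values[is_summit])
  })
  out <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  score = numeric()))
  }
  out
}

#' Read a summit BED (e.g. from an external peak caller)
#' @param path BED path: chrom, start, end, name, score; summit position
#'   taken as `start` of the (1-bp) interval.
#' @return data.table(chrom, pos, score).
#' @export
read_summits_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  data.table::data.table(chrom = as.character(dt[[1]]),
                         pos = as.integer(dt[[2]]),
                         score = if (ncol(dt) >= 5) as.numeric(dt[[5]]) else 1)
}

#' Extend summits into fixed-width scored peak candidates
#'
#' Each summit is extended `(width - 1) / 2` bases on each side
#' (truncated at chromosome bounds) and its score converted to
#' score-per-million within the replicate:
#' `score / (sum(scores) / 1e6)`.
#'
#' @param summits data.table(chrom, pos, score) for one replicate.
#' @param width odd fixed peak width (default 501).
#' @param chrom_sizes named integer vector.
#' @return data.table(chrom, start, end, summit, score_per_million).
#' @export
summits_to_candidates <- function(summits, width = 501L, chrom_sizes) {
  if (width %% 2 == 0) stop("peak width must be odd")
  summits <- data.table::as.data.table(summits)
  half <- (width - 1L) %/% 2L
  out <- summits[, .(chrom, summit = pos,
                     start = pmax(pos - half, 0L),
                     end = pmin(pos + half + 1L, chrom_sizes[chrom]),
                     score_per_million = score / (sum(score) / 1e6))]
  out[, .(chrom, start, end, summit, score_per_million)]
}

#' Iterative overlap merging of scored peak candidates
#'
#' Repeatedly keeps the highest-scoring remaining candidate and discards
#' every candidate overlapping it by at least one base, until exhausted.
#' Score ties are broken by earlier start, then chromosome. The output is
#' coordinate-sorted, pairwise disjoint and idempotent under re-merging;
#' `n_overlapping` records how many discarded candidates overlapped each
#' kept peak.
#'
#' @param candidates data.table with chrom, start, end and
#'   score_per_million (extra columns are carried through).
#' @return the kept candidates, coordinate-sorted, plus `n_overlapping`.
#' @export
iterative_overlap_merge <- function(candidates) {
  cand <- data.table::as.data.table(candidates)
  if (nrow(cand) == 0) return(cand)
  ord <- order(-cand$score_per_million, cand$start, cand$chrom)
  cand <- cand[ord]
  kept <- logical(nrow(cand))
  kept_ranges <- list()
  for (i in seq_len(nrow(cand))) {
    chr <- cand$chrom[i]
    kr <- kept_ranges[[chr]]
    if (is.null(kr) || !any(cand$start[i] < kr$end & cand$end[i] > kr$start)) {
      kept[i] <- TRUE
      kept_ranges[[chr]] <- data.table::rbindlist(list(
        kr, data.table::data.table(start = cand$start[i], end = cand$end[i])))
    }
  }
  out <- cand[kept]
  dropped <- cand[!kept]
  out[, n_overlapping := 0L]
  if (nrow(dropped) > 0) {
    for (chr in unique(out$chrom)) {
      ok <- out$chrom == chr
      dk <- dropped[chrom == chr]
      if (nrow(dk) == 0) next
      hits <- IRanges::countOverlaps(
        IRanges::IRanges(out$start[ok] + 1L, out$end[ok]),
        IRanges::IRanges(dk$start + 1L, dk$end))
      out$n_overlapping[ok] <- hits
    }
  }
  data.table::setorder(out, chrom, start)
  out[]
}

#' Reproducible fixed-width peak set across pseudo-bulk replicates
#'
#' Candidates are merged within each cluster by [iterative_overlap_merge()];
#' kept peaks supported by fewer than `min_rep_support` replicates
#' (a replicate supports a peak when any of its candidates overlaps it)
#' are dropped. The per-cluster sets are then merged globally by
#' score-per-million, retaining each kept peak's cluster of origin.
#'
#' @param candidates data.table with chrom, start, end, summit,
#'   score_per_million, replicate and cluster columns (rbind of
#'   [summits_to_candidates()] per replicate).
#' @param min_rep_support minimum supporting replicates (default 2).
#' @param blacklist optional data.table(chrom, start, end); overlapping
#'   candidates are removed before merging.
#' @param genome optional `DNAStringSet` for GC-fraction annotation.
#' @return peak set data.table: chrom, start, end, summit,
#'   score_per_million, n_replicates_support, group_of_origin,
#'   gc_fraction, name.
#' @export
reproducible_peak_set <- function(candidates, min_rep_support = 2L,
                                  blacklist = NULL, genome = NULL) {
  cand <- data.table::as.data.table(candidates)
  if (!is.null(blacklist)) {
    blacklist <- data.table::as.data.table(blacklist)
    drop <- rep(FALSE, nrow(cand))
    for (chr in unique(blacklist$chrom)) {
      sel <- cand$chrom == chr
      bl <- blacklist[chrom == chr]
      drop[sel] <- IRanges::countOverlaps(
        IRanges::IRanges(cand$start[sel] + 1L, cand$end[sel]),
        IRanges::IRanges(bl$start + 1L, bl$end)) > 0
    }
    cand <- cand[!drop]
  }
  per_cluster <- lapply(split(cand, cand$cluster), function(cc) {
    merged <- iterative_overlap_merge(cc)
    support <- integer(nrow(merged))
    for (chr in unique(merged$chrom)) {
      mk <- merged$chrom == chr
      ck <- cc[chrom == chr]
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(merged$start[mk] + 1L, merged$end[mk]),
        IRanges::IRanges(ck$start + 1L, ck$end))
      support[mk] <- vapply(seq_len(sum(mk)), function(i) {
        length(unique(ck$replicate[S4Vectors::subjectHits(ov)[
          S4Vectors::queryHits(ov) == i]]))
      }, integer(1))
    }
    merged[, n_replicates_support := support]
    merged[n_replicates_support >= min_rep_support]
  })
  pooled <- data.table::rbindlist(per_cluster)
  if (nrow(pooled) == 0) {
    stop("no reproducible peaks at min_rep_support = ", min_rep_support)
  }
  final <- iterative_overlap_merge(pooled)
  data.table::setnames(final, "cluster", "group_of_origin")
  final[, `:=`(replicate = NULL, n_overlapping = NULL)]
  final[, name := sprintf("%s:%d-%d", chrom, start, end)]
  if (!is.null(genome)) final[, gc_fraction := peak_gc(final, genome)]
  data.table::setorder(final, chrom, start)
  final[]
}

#' GC fraction of peak intervals
#' @param peaks data.table(chrom, start, end).
#' @param genome a named `Biostrings::DNAStringSet`.
#' @return numeric GC fractions.
#' @export
peak_gc <- function(peaks, genome) {
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(peaks)), function(i) {
    Biostrings::subseq(genome[[peaks$chrom[i]]], peaks$start[i] + 1L,
                       peaks$end[i])
  }))
  as.numeric(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
}

#' Write a peak set as BED6+
#'
#' Columns: chrom, start, end, name (cluster of origin), score
#' (score-per-million x 10, capped at 1000), strand ".", then
#' score_per_million, n_replicates_support and gc_fraction.
#'
#' @param peaks peak set from [reproducible_peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- data.table::data.table(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$group_of_origin %||% peaks$name,
    score = pmin(round(peaks$score_per_million * 10), 1000),
    strand = ".",
    score_per_million = peaks$score_per_million,
    n_replicates_support = peaks$n_replicates_support %||% NA_integer_,
    gc_fraction = peaks$gc_fraction %||% NA_real_)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Call a reproducible peak set from a fragment store and pseudo-bulk plan
#'
#' Convenience wrapper: per-replicate coverage, naive summit calling,
#' fixed-width candidates, then [reproducible_peak_set()].
#'
#' @param store a `fragment_store`.
#' @param plan output of [make_pseudobulk_plan()].
#' @param width fixed peak width (default 501).
#' @param smoothing_window summit smoothing window (default 75).
#' @param min_score minimum smoothed summit height (default 1).
#' @param min_rep_support minimum supporting replicates (default 2).
#' @param blacklist,genome passed to [reproducible_peak_set()].
#' @return peak set data.table.
#' @export
call_peaks <- function(store, plan, width = 501L, smoothing_window = 75L,
                       min_score = 1, min_rep_support = 2L,
                       blacklist = NULL, genome = NULL) {
  groups <- stats::setNames(plan$plan$members, plan$plan$replicate)
  cov <- export_group_coverage(store, groups)
  cand <- data.table::rbindlist(lapply(names(cov), function(rep_id) {
    summits <- call_summits_naive(cov[[rep_id]], smoothing_window, min_score)
    if (nrow(summits) == 0) return(NULL)
    cc <- summits_to_candidates(summits, width, store$chrom_sizes)
    cc[, `:=`(replicate = rep_id,
              cluster = plan$plan$cluster[plan$plan$replicate == rep_id])]
  }))
  reproducible_peak_set(cand, min_rep_support, blacklist, genome)
}
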