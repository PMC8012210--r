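kmer_window_start <- function(pos, k) pos - (k %/% 2L) + 1L # 0-based

#' Hexamer Tn5 insertion-bias table
#'
#' Observed frequency of the k-mer centered on every insertion (read on
#' the reference strand) against the genomic background k-mer frequency;
#' the ratio is the per-k-mer insertion bias. Insertions whose k-mer
#' window crosses a sequence edge are skipped and counted.
#'
#' @param store a `fragment_store`.
#' @param genome named `Biostrings::DNAStringSet` covering the store's
#'   chromosomes.
#' @param k k-mer width (default 6).
#' @return list(k, table = data.table(kmer, observed, background, bias),
#'   bias = named ratio vector, n_skipped).
#' @export
build_kmer_bias <- function(store, genome, k = 6L) {
  if (!all(names(store$chrom_sizes) %in% names(genome))) {
    stop("genome sequence missing for store chromosome(s)")
  }
  bg_counts <- Reduce(`+`, lapply(names(store$chrom_sizes), function(chr) {
    Biostrings::oligonucleotideFrequency(genome[[chr]], width = k)
  }))
  background <- bg_counts / sum(bg_counts)

  obs <- NULL; skipped <- 0L
  for (chr in names(store$chrom_sizes)) {
    ins <- chunk_insertions(store, chr)
    if (is.null(ins)) next
    w0 <- kmer_window_start(ins$pos, k)
    ok <- w0 >= 0 & w0 + k <= store$chrom_sizes[[chr]]
    skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    seq_chr <- as.character(genome[[chr]])
    km <- substring(seq_chr, w0[ok] + 1L, w0[ok] + k)
    dt <- data.table::data.table(kmer = km, w = ins$weight[ok])
    obs <- data.table::rbindlist(list(obs, dt[, .(w = sum(w)), by = kmer]))
  }
  if (skipped > 0) message(skipped, " insertion(s) skipped at sequence edges")
  obs <- obs[!grepl("[^ACGT]", kmer), .(w = sum(w)), by = kmer]
  tab <- data.table::data.table(kmer = names(background),
                                background = as.numeric(background))
  tab[, observed := 0]
  tab[obs, observed := i.w, on = "kmer"]
  tab[, observed := observed / sum(observed)]
  tab[, bias := ifelse(background > 0, observed / background, NA_real_)]
  structure(list(k = as.integer(k), table = tab[],
                 bias = stats::setNames(tab$bias, tab$kmer),
                 n_skipped = skipped),
            class = "kmer_bias")
}

#' Uniform (identity) k-mer bias table
#'
#' All ratios 1; bias adjustment under this table is the identity.
#' @param k k-mer width (default 6).
#' @return a `kmer_bias` object.
#' @export
uniform_kmer_bias <- function(k = 6L) {
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  tab <- data.table::data.table(kmer = kmers, background = 1 / length(kmers),
                                observed = 1 / length(kmers), bias = 1)
  structure(list(k = as.integer(k), table = tab,
                 bias = stats::setNames(rep(1, length(kmers)), kmers),
                 n_skipped = 0L),
            class = "kmer_bias")
}

# expected Tn5-bias profile over strand-oriented offsets -flank..flank:
# sum over sites of the bias ratio of the k-mer at each offset
footprint_expected <- function(sites, flank, bias, genome) {
  k <- bias$k
  width <- 2L * flank + 1L
  expected <- numeric(width)
  for (i in seq_len(nrow(sites))) {
    chr <- sites$chrom[i]
    center <- sites$pos[i]
    gpos <- if (sites$strand[i] == "-") center + flank:(-flank) else
      center + (-flank):flank
    w0 <- kmer_window_start(gpos, k)
    ok <- w0 >= 0 & w0 + k <= length(genome[[chr]])
    km <- rep(NA_character_, width)
    if (any(ok)) {
      km[ok] <- substring(as.character(genome[[chr]]), w0[ok] + 1L, w0[ok] + k)
    }
    r <- bias$bias[km]
    r[is.na(r)] <- 1
    expected <- expected + r
  }
  expected
}

#' Tn5 bias-adjusted aggregate TF footprints
#'
#' Per cell group, insertions are aggregated over strand-oriented offsets
#' around every motif site (minus-strand sites contribute reversed
#' offsets). The expected profile sums each offset's k-mer bias ratio
#' over sites. Both profiles are rescaled by their mean over the
#' outermost `edge` bases on each side, and the normalized footprint is
#' their ratio, so Tn5 sequence preference is divided out.
#'
#' @param store a `fragment_store`.
#' @param groups named list of barcode vectors.
#' @param sites data.table(chrom, pos, strand) of motif site centers.
#' @param flank bases on each side of the site center (default 250).
#' @param bias a `kmer_bias` table ([build_kmer_bias()] or
#'   [uniform_kmer_bias()]).
#' @param genome named `Biostrings::DNAStringSet`.
#' @param edge flank-edge width used for rescaling (default 50).
#' @return data.table(group, position, observed, expected, normalized).
#' @export
footprint <- function(store, groups, sites, flank = 250L, bias, genome,
                      edge = 50L) {
  sites <- data.table::as.data.table(sites)
  if (nrow(sites) == 0) stop("no motif sites supplied")
  if (any(lengths(groups) == 0)) stop("empty cell group")
  expected <- footprint_expected(sites, flank, bias, genome)
  offsets <- (-flank):flank
  edge_idx <- c(seq_len(edge), length(offsets) - seq_len(edge) + 1L)
  exp_norm <- expected / mean(expected[edge_idx])

  bc_id <- stats::setNames(seq_len(nrow(store$barcodes)),
                           store$barcodes$barcode)
  out <- lapply(names(groups), function(gname) {
    ids <- unname(bc_id[groups[[gname]]])
    obs <- numeric(length(offsets))
    for (chr in unique(sites$chrom)) {
      ins <- chunk_insertions(store, chr, bc_ids = ids)
      if (is.null(ins)) next
      schr <- sites[chrom == chr]
      lo <- findInterval(schr$pos - flank - 0.5, ins$pos) + 1L
      hi <- findInterval(schr$pos + flank + 0.5, ins$pos)
      n_hit <- pmax(hi - lo + 1L, 0L)
      if (sum(n_hit) == 0) next
      site_idx <- rep.int(seq_len(nrow(schr)), n_hit)
      ins_idx <- sequence(n_hit, from = lo)
      off <- ins$pos[ins_idx] - schr$pos[site_idx]
      off <- ifelse(schr$strand[site_idx] == "-", -off, off)
      obs <- accumulate_by_id(obs, off + flank + 1L, ins$weight[ins_idx])
    }
    if (mean(obs[edge_idx]) == 0) {
      stop("group '", gname, "' has no insertions in the flank edges; ",
           "insufficient depth for footprinting")
    }
    obs_norm <- obs / mean(obs[edge_idx])
    data.table::data.table(group = gname, position = offsets,
                           observed = obs, expected = expected,
                           normalized = obs_norm / exp_norm)
  })
  data.table::rbindlist(out)
}
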