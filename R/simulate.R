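#' Configuration for the synthetic fragment generator
#'
#' Defines a ground-truthed multi-sample scATAC-seq experiment: planted
#' cell types with type-specific accessible peaks, shared peaks, TSS
#' regions (producing TSS enrichment), fragment-count quality tiers
#' (mean +/- sd, e.g. low 1000 +/- 500, medium 5000 +/- 1000, high
#' 10000 +/- 2500), spiked heterotypic doublets, optional Tn5 hexamer
#' insertion bias, protected footprint sites, enhancer-gene couplings and
#' an optional continuous-lineage mode.
#'
#' @param n_chroms,chrom_length genome shape (default 2 x 1e6 bp).
#' @param n_genes genes placed on the genome (default 60).
#' @param n_cell_types planted types (or lineage stages; default 3).
#' @param cells_per_type singlet cells per type (scalar or vector).
#' @param n_samples samples cells are split over (default 2).
#' @param frags_per_cell c(mean, sd) of the truncated-normal per-cell
#'   fragment count (default the medium tier, 5000 +/- 1000).
#' @param doublet_fraction fraction of emitted barcodes that are
#'   heterotypic doublets (default 0).
#' @param n_peaks_shared,n_peaks_per_type planted peak counts.
#' @param peak_width planted peak width in bases (default 400).
#' @param frac_tss,frac_shared,frac_type fragment mixture fractions for
#'   TSS regions, shared peaks and type-specific peaks; the remainder is
#'   uniform background.
#' @param frac_type_peaks_in_body fraction of type-specific peaks placed
#'   inside gene bodies (plants gene-body signal; default 0.5).
#' @param n_linked_pairs enhancer-gene pairs: a type-specific peak placed
#'   20-80 kb from a gene's TSS whose expression will follow the
#'   enhancer's activity (default 0).
#' @param kmer_bias optional list(kmer =, fold =): insertion preference
#'   for one hexamer, imposed by rejection sampling.
#' @param footprint_sites optional integer: protected TF sites planted at
#'   shared-peak centers (no insertions within `protect_halfwidth`).
#' @param protect_halfwidth protected half-width in bases (default 10).
#' @param lineage continuous lineage mode: cells get a latent time in
#'   `[0, 1]` and the "type" peak sets become stage sets with triangular
#'   activity ramps; type labels become stages (default FALSE).
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 1e6, n_genes = 60L,
                       n_cell_types = 3L, cells_per_type = 500L,
                       n_samples = 2L,
                       frags_per_cell = c(mean = 5000, sd = 1000),
                       doublet_fraction = 0,
                       n_peaks_shared = 150L, n_peaks_per_type = 50L,
                       peak_width = 400L,
                       frac_tss = 0.15, frac_shared = 0.25, frac_type = 0.3,
                       frac_type_peaks_in_body = 0.5,
                       n_linked_pairs = 0L,
                       kmer_bias = NULL, footprint_sites = NULL,
                       protect_halfwidth = 10L,
                       lineage = FALSE, seed = 1L) {
  stopifnot(doublet_fraction >= 0, doublet_fraction < 1,
            frac_tss + frac_shared + frac_type < 1,
            all(cells_per_type > 0), frags_per_cell[1] > 0)
  cfg <- as.list(environment())
  if (length(cfg$cells_per_type) == 1) {
    cfg$cells_per_type <- rep(cfg$cells_per_type, n_cell_types)
  }
  structure(cfg, class = "sim_config")
}

random_genome <- function(n_chroms, chrom_length) {
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  seqs
}

# truncated normal fragment counts (>= 50)
draw_counts <- function(n, mean, sd) {
  pmax(round(stats::rnorm(n, mean, sd)), 50L)
}

# fragment midpoints within a peak: summit-shaped (normal around the
# center, sd = width/6), truncated to the peak interval
peak_midpoints <- function(start, end) {
  center <- (start + end) / 2
  width <- end - start
  m <- round(center + stats::rnorm(length(start), 0, width / 6))
  pmin(pmax(m, start), end - 1L)
}

rand_fragment_lengths <- function(n) {
  nf <- stats::runif(n) < 0.6
  len <- integer(n)
  len[nf] <- pmin(pmax(round(stats::rnorm(sum(nf), 85, 15)), 50L), 120L)
  len[!nf] <- pmin(pmax(round(stats::rnorm(sum(!nf), 215, 20)), 180L), 250L)
  len
}

#' Simulate a ground-truthed multi-sample scATAC-seq experiment
#'
#' Per cell, a truncated-normal fragment count is drawn; fragment
#' midpoints come from a mixture of TSS regions, shared peaks,
#' type-specific (or lineage-stage-ramped) peaks and uniform background;
#' fragment lengths follow a nucleosome-free (50-120 bp) /
#' mono-nucleosome (180-250 bp) mixture. Heterotypic doublets merge two
#' distinct-type parents' fragments under one barcode, each parent drawn
#' at 0.6x the tier depth (the two nuclei share the droplet's reads).
#' Hexamer bias and footprint protection are imposed by rejection
#' sampling with redraws, so emitted per-cell counts match the drawn
#' counts exactly.
#'
#' @param config a [sim_config()].
#' @return list: fragments (data.table chrom,start,end,barcode,count,
#'   sample), truth (barcode, sample, type, is_doublet, parent_types,
#'   latent_time), genome (`DNAStringSet`), chrom_sizes, genes, tss,
#'   peaks (with `kind`), linked_pairs, footprint_sites, config.
#' @export
simulate_fragments <- function(config = sim_config()) {
  cfg <- config
  if (cfg$lineage && cfg$doublet_fraction > 0) {
    stop("lineage mode does not support spiked doublets")
  }
  set.seed(cfg$seed)
  chrsz <- chrom_sizes(paste0("chr", seq_len(cfg$n_chroms)),
                       rep(cfg$chrom_length, cfg$n_chroms))
  genome <- random_genome(cfg$n_chroms, cfg$chrom_length)

  types <- if (cfg$lineage) paste0("stage", seq_len(cfg$n_cell_types)) else
    paste0("type", seq_len(cfg$n_cell_types))

  # -- layout: genes on a grid, peaks between/inside them ------------------
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  genes <- data.table::rbindlist(lapply(names(chrsz), function(chr) {
    n <- min(per_chrom, cfg$n_genes)
    slot <- floor(chrsz[[chr]] / n)
    start <- (seq_len(n) - 1L) * slot + round(slot * 0.15)
    len <- sample(2000:8000, n, replace = TRUE)
    data.table::data.table(chrom = chr, start = start, end = start + len,
                           strand = sample(c("+", "-"), n, replace = TRUE))
  }))[seq_len(cfg$n_genes)]
  genes[, name := sprintf("gene%03d", .I)]
  tss <- genes[, .(chrom, pos = ifelse(strand == "-", end - 1L, start),
                   strand, name)]

  # candidate peak slots: between-gene midpoints, far from TSS
  slot_w <- cfg$peak_width
  n_type_total <- cfg$n_peaks_per_type * cfg$n_cell_types
  n_body <- round(cfg$frac_type_peaks_in_body * n_type_total)
  # non-overlapping peak slots on a grid inside intergenic gaps
  slots <- data.table::rbindlist(lapply(names(chrsz), function(chr) {
    gchr <- genes[chrom == chr]
    gaps_end <- c(gchr$start, chrsz[[chr]])
    gaps_start <- c(0L, gchr$end)
    ok <- gaps_end - gaps_start > 6L * slot_w
    data.table::rbindlist(lapply(which(ok), function(i) {
      lo <- gaps_start[i] + 2L * slot_w
      hi <- gaps_end[i] - 3L * slot_w
      pos <- seq(lo, hi, by = 3L * slot_w)
      data.table::data.table(chrom = chr, start = pos, end = pos + slot_w)
    }))
  }))
  n_free_needed <- cfg$n_peaks_shared + (n_type_total - n_body) +
    cfg$n_linked_pairs
  if (nrow(slots) < n_free_needed) {
    stop("planted peaks exceed the genome: enlarge chrom_length or reduce peaks")
  }
  slots <- slots[sample(.N)]
  draw_free <- local({
    used <- 0L
    function(n) {
      out <- slots[used + seq_len(n)]
      used <<- used + n
      out
    }
  })

  peaks <- draw_free(cfg$n_peaks_shared + (n_type_total - n_body))
  peaks[, kind := c(rep("shared", cfg$n_peaks_shared),
                    rep(types, length.out = n_type_total - n_body))]
  if (n_body > 0) {
    # non-overlapping in-gene slots over the TSS-distal part of the body,
    # buffered away from the TSS so promoter-proximal reads do not leak in
    body_slots <- genes[, {
      len <- end - start
      if (strand == "+") {
        lo <- start + max(round(0.4 * len), 600L)
        hi <- end - slot_w
      } else {
        lo <- start
        hi <- min(end - round(0.4 * len), end - 600L) - slot_w
      }
      pos <- if (hi >= lo) seq(lo, hi, by = round(1.5 * slot_w)) else integer()
      .(start = pos, end = pos + slot_w)
    }, by = .(chrom, gene_start = start, strand)]
    if (nrow(body_slots) < n_body) {
      stop("not enough gene-body room for frac_type_peaks_in_body")
    }
    body_slots <- body_slots[sample(.N, n_body)]
    body_peaks <- body_slots[, .(chrom, start, end,
                                 kind = rep(types, length.out = n_body))]
    peaks <- rbind(peaks, body_peaks)
  }
  linked_pairs <- NULL
  if (cfg$n_linked_pairs > 0) {
    enh <- draw_free(cfg$n_linked_pairs)
    enh[, kind := rep(types, length.out = cfg$n_linked_pairs)]
    # pair each enhancer with a distinct same-chromosome gene 5-200 kb away
    # so the pair falls inside the default peak-to-gene testing window; a
    # gene drives at most one link, otherwise couplings would overwrite
    gene_pick <- character(nrow(enh))
    for (i in seq_len(nrow(enh))) {
      cand <- tss[chrom == enh$chrom[i] & !name %in% gene_pick]
      if (nrow(cand) == 0) cand <- tss[!name %in% gene_pick]
      d <- abs(cand$pos - (enh$start[i] + slot_w %/% 2L))
      ok <- which(d >= 5000 & d <= 200000)
      if (length(ok) == 0) ok <- which.min(d)
      gene_pick[i] <- cand$name[ok[sample.int(length(ok), 1)]]
    }
    peaks <- rbind(peaks, enh)
    linked_pairs <- data.table::data.table(
      peak = sprintf("%s:%d-%d", enh$chrom, enh$start, enh$end),
      gene = gene_pick, type = enh$kind)
  }
  peaks[, name := sprintf("%s:%d-%d", chrom, start, end)]

  fsites <- NULL
  if (!is.null(cfg$footprint_sites)) {
    sp <- peaks[kind == "shared"][seq_len(min(cfg$footprint_sites, sum(peaks$kind == "shared")))]
    fsites <- sp[, .(chrom, pos = (start + end) %/% 2L,
                     strand = sample(c("+", "-"), .N, replace = TRUE))]
  }

  # -- cells ---------------------------------------------------------------
  n_singlet <- sum(cfg$cells_per_type)
  cell_type <- rep(types, cfg$cells_per_type)
  n_dbl <- if (cfg$doublet_fraction > 0) {
    round(cfg$doublet_fraction / (1 - cfg$doublet_fraction) * n_singlet)
  } else 0L
  n_cells <- n_singlet + n_dbl
  samples <- paste0("S", 1 + (seq_len(n_cells) - 1L) %% cfg$n_samples)
  barcodes <- sprintf("%s#cell%05d", samples, seq_len(n_cells))

  latent <- rep(NA_real_, n_cells)
  if (cfg$lineage) latent[seq_len(n_singlet)] <- stats::runif(n_singlet)

  dbl_types <- NULL
  if (n_dbl > 0) {
    t1 <- sample(seq_along(types), n_dbl, replace = TRUE)
    t2 <- ((t1 - 1L + sample(seq_len(length(types) - 1L), n_dbl,
                             replace = TRUE)) %% length(types)) + 1L
    dbl_types <- cbind(t1, t2)
  }

  truth <- data.table::data.table(
    barcode = barcodes, sample = samples,
    type = c(cell_type, if (n_dbl) rep("doublet", n_dbl)),
    is_doublet = c(rep(FALSE, n_singlet), rep(TRUE, n_dbl)),
    parent_types = c(rep(NA_character_, n_singlet),
                     if (n_dbl) paste(types[dbl_types[, 1]],
                                      types[dbl_types[, 2]], sep = "+")),
    latent_time = latent)

  # -- per-fragment generation frame --------------------------------------
  mu <- cfg$frags_per_cell[[1]]; sdv <- cfg$frags_per_cell[[2]]
  singlet_counts <- draw_counts(n_singlet, mu, sdv)
  frame <- data.table::data.table(
    cell = rep(seq_len(n_singlet), singlet_counts),
    type_idx = rep(match(cell_type, types), singlet_counts),
    t = rep(latent[seq_len(n_singlet)], singlet_counts))
  if (n_dbl > 0) {
    for (side in 1:2) {
      pc <- draw_counts(n_dbl, 0.6 * mu, 0.6 * sdv)
      frame <- rbind(frame, data.table::data.table(
        cell = rep(n_singlet + seq_len(n_dbl), pc),
        type_idx = rep(dbl_types[, side], pc),
        t = NA_real_))
    }
  }
  N <- nrow(frame)

  # lineage: reassign per-fragment stage by triangular ramps over t
  if (cfg$lineage) {
    centers <- seq(0, 1, length.out = cfg$n_cell_types)
    h <- 1 / (cfg$n_cell_types - 1)
    wmat <- vapply(centers, function(c0) pmax(1 - abs(frame$t - c0) / h, 0),
                   numeric(N))
    wmat <- wmat / rowSums(wmat)
    u <- stats::runif(N)
    cw <- t(apply(wmat, 1, cumsum)) # N x S cumulative stage weights
    # column recycling of u aligns u[i] with row i in each column
    frame[, type_idx := pmin(1L + rowSums(cw < u), cfg$n_cell_types)]
    truth[seq_len(n_singlet),
          type := types[cut(latent_time, breaks = cfg$n_cell_types,
                            labels = FALSE, include.lowest = TRUE)]]
  }

  # fragment class: tss / shared / type-specific / background
  u <- stats::runif(N)
  cls <- data.table::fcase(
    u < cfg$frac_tss, 1L,
    u < cfg$frac_tss + cfg$frac_shared, 2L,
    u < cfg$frac_tss + cfg$frac_shared + cfg$frac_type, 3L,
    default = 4L)

  shared_idx <- which(peaks$kind == "shared")
  type_sets <- lapply(types, function(tp) which(peaks$kind == tp))

  chrom_cum <- cumsum(as.numeric(chrsz)) / sum(as.numeric(chrsz))

  draw_mid <- function(rows) {
    n <- length(rows)
    chromv <- character(n); mid <- numeric(n)
    rc <- cls[rows]
    # TSS-proximal fragments
    is1 <- rc == 1L
    if (any(is1)) {
      ti <- sample.int(nrow(tss), sum(is1), replace = TRUE)
      chromv[is1] <- tss$chrom[ti]
      mid[is1] <- tss$pos[ti] + round(stats::rnorm(sum(is1), 0, 50))
    }
    # shared peaks
    is2 <- rc == 2L
    if (any(is2)) {
      pi <- shared_idx[sample.int(length(shared_idx), sum(is2), replace = TRUE)]
      chromv[is2] <- peaks$chrom[pi]
      mid[is2] <- peak_midpoints(peaks$start[pi], peaks$end[pi])
    }
    # type/stage-specific peaks
    is3 <- rc == 3L
    if (any(is3)) {
      tix <- frame$type_idx[rows[is3]]
      pick <- integer(sum(is3))
      for (s in seq_along(types)) {
        sel <- tix == s
        if (!any(sel)) next
        pick[sel] <- type_sets[[s]][sample.int(length(type_sets[[s]]),
                                               sum(sel), replace = TRUE)]
      }
      chromv[is3] <- peaks$chrom[pick]
      mid[is3] <- peak_midpoints(peaks$start[pick], peaks$end[pick])
    }
    # uniform background
    is4 <- rc == 4L
    if (any(is4)) {
      ci <- findInterval(stats::runif(sum(is4)), chrom_cum) + 1L
      chromv[is4] <- names(chrsz)[ci]
      mid[is4] <- floor(stats::runif(sum(is4)) * chrsz[ci])
    }
    list(chrom = chromv, mid = mid)
  }

  gen_rows <- function(rows) {
    dm <- draw_mid(rows)
    len <- rand_fragment_lengths(length(rows))
    start <- round(dm$mid - len / 2)
    start <- pmin(pmax(start, 0L), chrsz[dm$chrom] - len)
    data.table::data.table(chrom = dm$chrom, start = as.integer(start),
                           end = as.integer(start + len))
  }

  frag <- gen_rows(seq_len(N))

  # rejection resampling for hexamer bias and/or footprint protection
  needs_reject <- !is.null(cfg$kmer_bias) || !is.null(fsites)
  if (needs_reject) {
    genome_chr <- lapply(as.list(as.character(genome)), identity)
    names(genome_chr) <- names(genome)
    accept_prob <- function(fr) {
      p <- rep(1, nrow(fr))
      if (!is.null(cfg$kmer_bias)) {
        k <- nchar(cfg$kmer_bias$kmer)
        for (col in c("start", "endm1")) {
          pos <- if (col == "start") fr$start else fr$end - 1L
          w0 <- kmer_window_start(pos, k)
          km <- rep("", nrow(fr))
          for (chr in names(chrsz)) {
            sel <- fr$chrom == chr & w0 >= 0 & w0 + k <= chrsz[[chr]]
            if (!any(sel)) next
            km[sel] <- substring(genome_chr[[chr]], w0[sel] + 1L, w0[sel] + k)
          }
          w <- ifelse(km == cfg$kmer_bias$kmer, cfg$kmer_bias$fold, 1)
          p <- p * w / cfg$kmer_bias$fold
        }
      }
      if (!is.null(fsites)) {
        for (chr in unique(fsites$chrom)) {
          sp <- sort(fsites[chrom == chr, pos])
          sel <- fr$chrom == chr
          for (pos in list(fr$start[sel], fr$end[sel] - 1L)) {
            hit <- findInterval(pos + cfg$protect_halfwidth + 0.5, sp) -
              findInterval(pos - cfg$protect_halfwidth - 0.5, sp) > 0
            psel <- p[sel]
            psel[hit] <- 0
            p[sel] <- psel
          }
        }
      }
      p
    }
    todo <- seq_len(N)
    for (round in seq_len(100)) {
      p <- accept_prob(frag[todo])
      rejected <- todo[stats::runif(length(todo)) > p]
      if (length(rejected) == 0) break
      frag[rejected, c("chrom", "start", "end") := gen_rows(rejected)]
      todo <- rejected
    }
  }

  fragments <- data.table::data.table(
    chrom = frag$chrom, start = frag$start, end = frag$end,
    barcode = barcodes[frame$cell], count = 1L,
    sample = samples[frame$cell])
  data.table::setorder(fragments, chrom, start)

  list(fragments = fragments, truth = truth, genome = genome,
       chrom_sizes = chrsz, genes = genes, tss = tss, peaks = peaks,
       linked_pairs = linked_pairs, footprint_sites = fsites,
       config = cfg)
}

#' Write a simulation to standard on-disk formats
#'
#' Per-sample gzipped fragment TSVs, genome FASTA, chrom.sizes, gene
#' annotation TSV, TSS BED6, planted-peak TSV and truth TSV.
#'
#' @param sim output of [simulate_fragments()].
#' @param dir output directory (created).
#' @return named list of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (sm in unique(sim$fragments$sample)) {
    p <- file.path(dir, paste0("fragments_", sm, ".tsv.gz"))
    data.table::fwrite(sim$fragments[sample == sm,
                                     .(chrom, start, end, barcode, count)],
                       p, sep = "\t", col.names = FALSE, compress = "gzip")
    paths[[paste0("fragments_", sm)]] <- p
  }
  paths$genome <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  paths$chrom_sizes <- file.path(dir, "chrom.sizes")
  data.table::fwrite(data.table::data.table(names(sim$chrom_sizes),
                                            sim$chrom_sizes),
                     paths$chrom_sizes, sep = "\t", col.names = FALSE)
  paths$genes <- file.path(dir, "genes.tsv")
  data.table::fwrite(sim$genes[, .(chrom, start, end, strand, name)],
                     paths$genes, sep = "\t")
  paths$tss <- file.path(dir, "tss.bed")
  data.table::fwrite(sim$tss[, .(chrom, pos, end = pos + 1L, name,
                                 score = 0L, strand)],
                     paths$tss, sep = "\t", col.names = FALSE)
  paths$peaks <- file.path(dir, "planted_peaks.tsv")
  data.table::fwrite(sim$peaks, paths$peaks, sep = "\t")
  paths$truth <- file.path(dir, "truth.tsv")
  data.table::fwrite(sim$truth, paths$truth, sep = "\t")
  paths
}

#' Simulate matched expression coupled to accessibility
#'
#' Expression is Poisson with per-type rates: for coupled genes the rate
#' follows the gene's relative per-type gene-body accessibility (computed
#' from the emitted fragments) raised to `coupling`; genes in planted
#' enhancer-gene pairs instead follow their enhancer peak's per-type
#' accessibility. A per-cell lognormal depth factor is applied. Doublet
#' barcodes mix their two parent types' rates.
#'
#' @param sim output of [simulate_fragments()].
#' @param coupling accessibility-expression coupling exponent (0 =
#'   independent; default 1).
#' @param coupled_genes gene names to couple (default all).
#' @param base_rate mean counts per gene per cell (default 2).
#' @param seed RNG seed.
#' @return sparse cells x genes count matrix (rows = barcodes).
#' @export
simulate_paired_expression <- function(sim, coupling = 1,
                                       coupled_genes = NULL,
                                       base_rate = 2, seed = 1L) {
  set.seed(seed)
  genes <- sim$genes
  truth <- sim$truth
  types <- setdiff(unique(truth$type), "doublet")
  coupled_genes <- coupled_genes %||% genes$name

  # per-type mean accessibility of each gene body and each planted peak
  frags <- data.table::copy(sim$fragments)
  frags[, mid := (start + end) %/% 2L]
  type_of <- stats::setNames(truth$type, truth$barcode)
  acc_region <- function(reg) {
    out <- matrix(0, length(types), nrow(reg),
                  dimnames = list(types, reg$name))
    for (chr in unique(reg$chrom)) {
      rc <- reg[chrom == chr]
      fc <- frags[chrom == chr]
      idx <- findInterval(fc$mid, rc$start)
      inside <- idx > 0 & fc$mid < rc$end[pmax(idx, 1L)]
      if (!any(inside)) next
      tt <- type_of[fc$barcode[inside]]
      sel <- tt %in% types
      tab <- table(factor(tt[sel], levels = types),
                   factor(rc$name[idx[inside][sel]], levels = rc$name))
      out[, colnames(tab)] <- out[, colnames(tab)] + as.matrix(tab)
    }
    n_per_type <- table(factor(type_of[type_of %in% types], levels = types))
    sweep(out, 1, pmax(as.numeric(n_per_type), 1), "/")
  }
  gene_sorted <- data.table::copy(genes)[order(chrom, start)]
  acc_gene <- acc_region(gene_sorted)

  rel <- matrix(1, length(types), nrow(genes),
                dimnames = list(types, genes$name))
  cp <- intersect(coupled_genes, genes$name)
  ra <- acc_gene[, cp, drop = FALSE]
  ra <- sweep(ra + 1e-6, 2, colMeans(ra + 1e-6), "/")
  rel[, cp] <- ra^coupling

  if (!is.null(sim$linked_pairs)) {
    pk <- sim$peaks[name %in% sim$linked_pairs$peak][order(chrom, start)]
    acc_pk <- acc_region(pk)
    for (i in seq_len(nrow(sim$linked_pairs))) {
      v <- acc_pk[, sim$linked_pairs$peak[i]] + 1e-6
      rel[, sim$linked_pairs$gene[i]] <- (v / mean(v))^max(coupling, 1)
    }
  }

  rate_g <- base_rate * exp(stats::rnorm(nrow(genes), 0, 0.4))
  depth_f <- exp(stats::rnorm(nrow(truth), 0, 0.3))
  type_rate <- sweep(rel, 2, rate_g, "*") # types x genes

  cell_rel <- matrix(0, nrow(truth), nrow(genes))
  singlet <- !truth$is_doublet
  cell_rel[singlet, ] <- type_rate[match(truth$type[singlet], types), ]
  if (any(!singlet)) {
    pts <- strsplit(truth$parent_types[!singlet], "+", fixed = TRUE)
    p1 <- vapply(pts, `[`, character(1), 1)
    p2 <- vapply(pts, `[`, character(1), 2)
    cell_rel[!singlet, ] <- (type_rate[match(p1, types), , drop = FALSE] +
                               type_rate[match(p2, types), , drop = FALSE]) / 2
  }
  lam <- cell_rel * depth_f
  counts <- matrix(stats::rpois(length(lam), lam), nrow(truth))
  dimnames(counts) <- list(truth$barcode, genes$name)
  methods::as(counts, "CsparseMatrix")
}
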