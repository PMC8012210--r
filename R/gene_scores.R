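#' Gene activity score model specification
#'
#' Parameterizes the family of gene-score models: the genomic region basis
#' (gene body, optionally extended upstream), the distance-decay shape,
#' whether neighboring gene boundaries truncate a gene's window, gene-size
#' scaling and per-cell depth normalization. The default is the gene-body
#' + bi-directional exponential decay + gene-boundary model that performed
#' best in benchmarking of the 56-model family ("model 42"-class).
#'
#' @param use_gene_body include the whole gene body as the zero-distance
#'   region; if `FALSE`, only a window of `promoter_halfwidth` bases
#'   around the TSS is used.
#' @param upstream_body_extension bases the body is extended on the
#'   strand-upstream side before decay starts (default 5000).
#' @param decay decay shape outside the (extended) body: "exponential"
#'   (`exp(-d / decay_constant)`), "linear" (to 0 at `max_extension`) or
#'   "none" (flat weight 1).
#' @param decay_constant exponential decay length scale in bases
#'   (default 5000).
#' @param weight_floor additive constant on the decay weight (default
#'   `exp(-1)`), so distal signal within `max_extension` never drops to 0.
#' @param max_extension maximum distance in bases beyond the extended
#'   body contributing signal (default 100000).
#' @param respect_gene_boundaries truncate a gene's window at neighboring
#'   extended gene bodies.
#' @param scale_max upper bound of the linear inverse-gene-length scaling
#'   into `[1, scale_max]` (default 5; 1 disables).
#' @param target_depth per-cell gene-score normalization total
#'   (default 10000).
#' @param promoter_halfwidth promoter window half-width when
#'   `use_gene_body = FALSE` (default 2500).
#' @return a `gene_score_model` list.
#' @export
gene_score_model <- function(use_gene_body = TRUE,
                             upstream_body_extension = 5000L,
                             decay = c("exponential", "linear", "none"),
                             decay_constant = 5000,
                             weight_floor = exp(-1),
                             max_extension = 100000L,
                             respect_gene_boundaries = TRUE,
                             scale_max = 5,
                             target_depth = 10000,
                             promoter_halfwidth = 2500L) {
  decay <- match.arg(decay)
  stopifnot(decay_constant > 0, max_extension >= 0, scale_max >= 1,
            weight_floor >= 0)
  structure(list(use_gene_body = use_gene_body,
                 upstream_body_extension = as.integer(upstream_body_extension),
                 decay = decay, decay_constant = decay_constant,
                 weight_floor = weight_floor,
                 max_extension = as.integer(max_extension),
                 respect_gene_boundaries = respect_gene_boundaries,
                 scale_max = scale_max, target_depth = target_depth,
                 promoter_halfwidth = as.integer(promoter_halfwidth)),
            class = "gene_score_model")
}

#' Named presets for the gene-score model classes
#'
#' Representatives of the model classes spanned by the 56-model grid:
#' promoter-only, flat gene body, gene body + exponential decay without
#' boundary awareness, gene body + linear decay, and the default
#' boundary-aware exponential-decay model.
#'
#' @return named list of [gene_score_model()] objects.
#' @export
gene_model_presets <- function() {
  list(
    promoter_only = gene_score_model(use_gene_body = FALSE, decay = "none",
                                     weight_floor = 0, max_extension = 0L,
                                     respect_gene_boundaries = FALSE,
                                     scale_max = 1),
    gene_body = gene_score_model(decay = "none", weight_floor = 0,
                                 max_extension = 0L,
                                 respect_gene_boundaries = FALSE,
                                 scale_max = 1),
    body_exponential = gene_score_model(respect_gene_boundaries = FALSE),
    body_linear = gene_score_model(decay = "linear"),
    body_exponential_boundary = gene_score_model()
  )
}

#' Distance-decay weight of the gene-score model
#'
#' `distance` is the signed base distance from the extended gene body
#' (0 anywhere inside it). Weight is `decay(|d|) + weight_floor` within
#' `max_extension` and exactly 0 beyond it; at `d = 0` the exponential
#' model gives `1 + weight_floor`.
#'
#' @param distance numeric vector of signed distances in bases.
#' @param spec a [gene_score_model()].
#' @return numeric weights.
#' @export
gene_score_weight <- function(distance, spec = gene_score_model()) {
  d <- abs(distance)
  base <- switch(spec$decay,
                 exponential = exp(-d / spec$decay_constant),
                 linear = pmax(1 - d / max(spec$max_extension, 1), 0),
                 none = rep(1, length(d)))
  w <- base + spec$weight_floor
  w[d > spec$max_extension] <- 0
  w
}

#' Read a gene annotation table
#'
#' Accepts BED6 (chrom, start, end, name, score, strand) or a GTF-lite
#' TSV with columns chrom, start, end, strand, name (header optional).
#'
#' @param path annotation path.
#' @return data.table(chrom, start, end, strand, name).
#' @export
read_genes <- function(path) {
  dt <- data.table::fread(path, header = "auto")
  if (all(c("chrom", "start", "end", "strand", "name") %in% names(dt))) {
    return(dt[, .(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), strand = as.character(strand),
                  name = as.character(name))])
  }
  if (ncol(dt) < 6) stop("gene annotation needs BED6 or a GTF-lite TSV")
  data.table::data.table(chrom = as.character(dt[[1]]),
                         start = as.integer(dt[[2]]),
                         end = as.integer(dt[[3]]),
                         strand = as.character(dt[[6]]),
                         name = as.character(dt[[4]]))
}

#' Per-gene weighted tile footprints
#'
#' For every gene, the body is extended `upstream_body_extension` bases on
#' the strand-upstream side; the candidate window reaches `max_extension`
#' beyond each end but is truncated at the nearest neighboring extended
#' gene body when `respect_gene_boundaries`. Every tile overlapping the
#' window receives the decay weight evaluated at the distance from the
#' tile center to the extended body (0 inside it).
#'
#' @param genes data.table(chrom, start, end, strand, name); zero-length
#'   genes are rejected.
#' @param chrom_sizes named integer vector.
#' @param spec a [gene_score_model()].
#' @param tile_size tile width matching the tile matrix (default 500).
#' @return data.table(gene, tile, weight, gene_length) with global tile
#'   indices matching [tile_features()] order.
#' @export
gene_windows <- function(genes, chrom_sizes, spec = gene_score_model(),
                         tile_size = 500L) {
  genes <- data.table::as.data.table(genes)
  if (any(genes$end <= genes$start)) stop("zero-length gene in annotation")
  if (!all(genes$strand %in% c("+", "-"))) stop("genes must carry strand")
  genes <- genes[chrom %in% names(chrom_sizes)]

  n_truncated <- 0L
  g <- data.table::copy(genes)
  if (spec$use_gene_body) {
    g[, ext_start := ifelse(strand == "+", start - spec$upstream_body_extension, start)]
    g[, ext_end := ifelse(strand == "-", end + spec$upstream_body_extension, end)]
  } else {
    tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
    g[, ext_start := tss - spec$promoter_halfwidth]
    g[, ext_end := tss + spec$promoter_halfwidth + 1L]
  }
  clipped <- g$ext_start < 0 | g$ext_end > chrom_sizes[g$chrom]
  n_truncated <- sum(clipped)
  g[, ext_start := pmax(ext_start, 0L)]
  g[, ext_end := pmin(ext_end, chrom_sizes[chrom])]
  if (n_truncated > 0) {
    message(n_truncated, " gene window(s) truncated at chromosome bounds")
  }

  g[, `:=`(win_start = pmax(ext_start - spec$max_extension, 0L),
           win_end = pmin(ext_end + spec$max_extension, chrom_sizes[chrom]))]
  if (spec$respect_gene_boundaries && nrow(g) > 1) {
    data.table::setorder(g, chrom, ext_start, ext_end)
    g[, left_bound := shift(cummax(ext_end), fill = 0L), by = chrom]
    g[, right_bound := shift(ext_start, type = "lead",
                             fill = .Machine$integer.max), by = chrom]
    g[, win_start := pmin(ext_start, pmax(win_start, left_bound))]
    g[, win_end := pmax(ext_end, pmin(win_end, right_bound))]
  }

  offsets <- c(0L, cumsum(vapply(chrom_sizes, function(l)
    as.integer(ceiling(l / tile_size)), integer(1))))
  names(offsets) <- c(names(chrom_sizes), "end")

  out <- lapply(seq_len(nrow(g)), function(i) {
    t0 <- g$win_start[i] %/% as.integer(tile_size)
    t1 <- (g$win_end[i] - 1L) %/% as.integer(tile_size)
    tl <- t0:t1
    center <- tl * tile_size + tile_size / 2
    d <- pmax(g$ext_start[i] - center, center - (g$ext_end[i] - 1), 0)
    w <- gene_score_weight(d, spec)
    keep <- w > 0
    data.table::data.table(gene = g$name[i],
                           tile = offsets[[g$chrom[i]]] + tl[keep] + 1L,
                           weight = w[keep],
                           gene_length = g$end[i] - g$start[i])
  })
  data.table::rbindlist(out)
}

#' Build the gene-score matrix
#'
#' `score(cell, gene) = size_scale(gene) * sum_tiles weight * tile count`,
#' followed by per-cell depth normalization to `target_depth`. The size
#' scale maps inverse gene length linearly into `[1, scale_max]`, boosting
#' short genes whose footprint integrates fewer tiles.
#'
#' @param tile_matrix a tile `feature_matrix` (same tiling as `windows`).
#' @param windows output of [gene_windows()].
#' @param spec the [gene_score_model()] used to build `windows`.
#' @return a `feature_matrix` of kind "gene" (cells x genes).
#' @export
build_gene_score_matrix <- function(tile_matrix, windows,
                                    spec = gene_score_model()) {
  counts <- tile_matrix$counts
  genes <- unique(windows[, .(gene, gene_length)])
  gidx <- stats::setNames(seq_len(nrow(genes)), genes$gene)
  W <- Matrix::sparseMatrix(i = windows$tile, j = gidx[windows$gene],
                            x = windows$weight,
                            dims = c(ncol(counts), nrow(genes)))
  raw <- counts %*% W

  inv <- 1 / genes$gene_length
  scale <- if (diff(range(inv)) == 0 || spec$scale_max == 1) {
    rep(1, nrow(genes))
  } else {
    1 + (spec$scale_max - 1) * (inv - min(inv)) / (max(inv) - min(inv))
  }
  scored <- raw %*% Matrix::Diagonal(x = scale)

  depth <- Matrix::rowSums(scored)
  depth[depth == 0] <- 1
  normed <- Matrix::Diagonal(x = spec$target_depth / depth) %*% scored
  normed <- methods::as(normed, "CsparseMatrix")
  rownames(normed) <- rownames(counts)
  feats <- data.table::data.table(chrom = NA_character_, start = NA_integer_,
                                  end = NA_integer_, name = genes$gene)
  feature_matrix(normed, feats, "gene")
}

#' Evaluate gene-score models against matched expression
#'
#' Scores one or more gene-score matrices against a matched cell x gene
#' expression matrix over cell aggregates, with four tests: per-gene
#' Pearson correlation across aggregates and per-aggregate correlation
#' across genes, each on the top differentially expressed and the top
#' variable gene sets.
#'
#' @param scores a gene `feature_matrix`, or a named list of them (one
#'   per model).
#' @param expression cells x genes matrix (columns named by gene),
#'   same cells as `scores`.
#' @param aggregates factor/character of cell group labels (same order
#'   as rows).
#' @param n_diff,n_var sizes of the differential (default 1000) and
#'   variable (default 2000) gene sets; capped at the available genes
#'   with a message.
#' @return list with `tests` (model, test, gene_set, mean_cor) and
#'   `summary` (model, mean_cor, rank).
#' @export
evaluate_gene_models <- function(scores, expression, aggregates,
                                 n_diff = 1000L, n_var = 2000L) {
  if (inherits(scores, "feature_matrix")) scores <- list(model = scores)
  expression <- as(expression, "CsparseMatrix")
  expr_norm <- as.matrix(log1p(normalize_depth(expression)))
  groups <- as.character(aggregates)

  agg_means <- function(m) {
    t(vapply(split(seq_len(nrow(m)), groups),
             function(ix) colMeans(m[ix, , drop = FALSE]),
             numeric(ncol(m))))
  }
  agg_expr <- agg_means(expr_norm)

  gvar <- apply(expr_norm, 2, stats::var)
  drange <- apply(agg_expr, 2, function(x) diff(range(x)))
  if (n_diff > ncol(expression) || n_var > ncol(expression)) {
    message("fewer genes than requested; using all ", ncol(expression))
  }
  sets <- list(
    differential = colnames(expression)[order(-drange)][seq_len(min(n_diff, ncol(expression)))],
    variable = colnames(expression)[order(-gvar)][seq_len(min(n_var, ncol(expression)))]
  )

  rows <- list()
  for (mn in names(scores)) {
    sm <- normalize_depth(scores[[mn]]$counts)
    common <- intersect(colnames(sm), colnames(expression))
    agg_sc <- agg_means(as.matrix(log1p(sm[, common, drop = FALSE])))
    ae <- agg_expr[, common, drop = FALSE]
    for (sn in names(sets)) {
      gs <- intersect(sets[[sn]], common)
      per_gene <- vapply(gs, function(gg) {
        suppressWarnings(stats::cor(agg_sc[, gg], ae[, gg]))
      }, numeric(1))
      per_agg <- vapply(rownames(ae), function(a) {
        suppressWarnings(stats::cor(agg_sc[a, gs], ae[a, gs]))
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.table::data.table(
        model = mn, gene_set = sn,
        test = c("per_gene", "per_aggregate"),
        mean_cor = c(mean(per_gene, na.rm = TRUE),
                     mean(per_agg, na.rm = TRUE)))
    }
  }
  tests <- data.table::rbindlist(rows)
  summary <- tests[, .(mean_cor = mean(mean_cor)), by = model]
  summary[, rank := data.table::frank(-mean_cor, ties.method = "min")]
  list(tests = tests, summary = summary[])
}
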