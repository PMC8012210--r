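cs <- chrom_sizes(c("chr1", "chr2"), c(1200L, 2000L))

test_that("tile matrix places insertions by floor(pos / tile_size)", {
  # a 1200-bp chromosome has 3 tiles, the last truncated to [1000, 1200)
  tf <- tile_features(chrom_sizes("chr1", 1200L), 500L)
  expect_equal(nrow(tf), 3)
  expect_equal(tf[3, .(start, end)],
               data.table::data.table(start = 1000L, end = 1200L))

  frags <- data.table::data.table(chrom = "chr2", start = 1250L, end = 1251L,
                                  barcode = "A", count = 1L)
  store <- create_fragment_store(frags, cs)
  tm <- build_tile_matrix(store, tile_size = 500L)
  # both insertions of the point fragment land in chr2 tile floor(1250/500)
  # = 2 (0-based), i.e. global column 3 (chr1 tiles) + 3
  expect_equal(ncol(tm$counts), 3 + 4)
  expect_equal(unname(tm$counts["A", 6]), 2)
  expect_equal(sum(tm$counts), 2)
})

test_that("tile column sums conserve 2x the fragment weight", {
  frags <- random_frags(400, chroms = c(chr1 = 1200L, chr2 = 2000L), seed = 2)
  frags[, end := pmin(end, cs[chrom])]
  frags <- frags[start < end]
  store <- create_fragment_store(frags, cs)
  tm <- build_tile_matrix(store, tile_size = 100L)
  expect_equal(ncol(tm$counts), sum(ceiling(cs / 100)))
  per_cell <- Matrix::rowSums(tm$counts)
  depth <- store$barcodes$n_frags
  expect_equal(unname(per_cell[store$barcodes$barcode]), 2 * depth)
  bin <- build_tile_matrix(store, tile_size = 100L, binarize = TRUE)
  expect_true(all(bin$counts@x == 1))
})

test_that("peak matrix counts insertions in half-open peaks, matching brute force", {
  peaks <- data.table::data.table(chrom = "chr1",
                                  start = c(100L, 400L), end = c(200L, 600L))
  frags <- data.table::data.table(chrom = "chr1",
                                  start = c(150L, 199L, 200L),
                                  end = c(151L, 200L, 201L),
                                  barcode = "A", count = 1L)
  store <- create_fragment_store(frags, cs)
  pm <- build_peak_matrix(store, peaks)
  # insertion exactly at peak end (200) is excluded (half-open)
  expect_equal(unname(pm$counts["A", 1]), 4)
  expect_equal(sum(pm$counts), 4)

  set.seed(9)
  big <- random_frags(500, chroms = c(chr1 = 1200L, chr2 = 2000L), seed = 9)
  big <- big[end <= cs[chrom]]
  store2 <- create_fragment_store(big, cs)
  peaks2 <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0L, 600L, 500L), end = c(300L, 900L, 1500L))
  pm2 <- build_peak_matrix(store2, peaks2)
  ins <- insertion_sites(big)
  for (j in 1:3) {
    want <- ins[chrom == peaks2$chrom[j] & pos >= peaks2$start[j] &
                  pos < peaks2$end[j],
                .(w = sum(weight)), by = barcode]
    got <- pm2$counts[, j]
    expect_equal(unname(got[want$barcode]), as.numeric(want$w))
  }
  expect_lte(sum(pm2$counts), sum(ins$weight))
  expect_error(build_peak_matrix(store2, data.table::data.table(
    chrom = "chr1", start = c(0L, 100L), end = c(200L, 300L))),
    "non-overlapping")
})

test_that("gene score weights follow the decay formula and its bounds", {
  spec <- gene_score_model()
  expect_equal(gene_score_weight(0, spec), 1 + exp(-1), tolerance = 1e-12)
  expect_equal(gene_score_weight(5000, spec), exp(-1) + exp(-1),
               tolerance = 1e-12)
  expect_equal(gene_score_weight(100001, spec), 0)
  expect_equal(gene_score_weight(-100001, spec), 0)
  # symmetric and non-increasing in |distance|
  d <- seq(0, 100000, by = 500)
  expect_equal(gene_score_weight(d, spec), gene_score_weight(-d, spec))
  expect_true(all(diff(gene_score_weight(d, spec)) <= 0))
})

test_that("gene windows truncate at neighboring extended bodies", {
  cs1 <- chrom_sizes("chr1", 400000L)
  spec <- gene_score_model() # upstream ext 5 kb, max ext 100 kb
  genes <- data.table::data.table(
    chrom = "chr1", start = c(100000L, 120000L), end = c(110000L, 130000L),
    strand = c("+", "+"), name = c("g1", "g2"))
  gw <- gene_windows(genes, cs1, spec, tile_size = 500L)
  # g1 extended body = [95000,110000); g2 extended = [115000,130000)
  # g1 window right edge truncated at g2's extended start (115000)
  g1_tiles <- gw[gene == "g1", tile]
  expect_equal(max(g1_tiles), 115000 / 500) # tile [114500,115000) = index 230
  # g2 window left edge truncated at g1's extended end (110000)
  g2_tiles <- gw[gene == "g2", tile]
  expect_equal(min(g2_tiles), 110000 / 500 + 1)
  # without boundaries both windows reach max_extension
  spec2 <- gene_score_model(respect_gene_boundaries = FALSE)
  gw2 <- gene_windows(genes, cs1, spec2, tile_size = 500L)
  expect_gt(max(gw2[gene == "g1", tile]), max(g1_tiles))

  # minus-strand gene: upstream extension applied at the end side
  gm <- data.table::data.table(chrom = "chr1", start = 200000L,
                               end = 210000L, strand = "-", name = "gm")
  gwm <- gene_windows(gm, cs1, gene_score_model(max_extension = 0L),
                      tile_size = 500L)
  expect_equal(range(gwm$tile),
               c(200000 / 500 + 1, (210000 + 5000) / 500))
})

test_that("gene scores equal a dense weighted-sum oracle on a toy", {
  cs1 <- chrom_sizes("chr1", 50000L)
  genes <- data.table::data.table(
    chrom = "chr1", start = c(5000L, 20000L, 40000L),
    end = c(8000L, 26000L, 43000L), strand = c("+", "-", "+"),
    name = c("a", "b", "c"))
  spec <- gene_score_model(max_extension = 3000L, scale_max = 5,
                           target_depth = 1000)
  gw <- gene_windows(genes, cs1, spec, tile_size = 500L)
  set.seed(3)
  counts <- Matrix::rsparsematrix(4, 100, density = 0.3,
                                  rand.x = function(n) rpois(n, 2) + 1)
  rownames(counts) <- paste0("c", 1:4)
  tm <- feature_matrix(counts, tile_features(cs1, 500L), "tile")
  gs <- build_gene_score_matrix(tm, gw, spec)

  # dense oracle
  W <- matrix(0, 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (i in seq_len(nrow(gw))) W[gw$tile[i], gw$gene[i]] <- gw$weight[i]
  raw <- as.matrix(counts) %*% W
  inv <- 1 / (genes$end - genes$start)
  scale <- 1 + 4 * (inv - min(inv)) / (max(inv) - min(inv))
  sc <- sweep(raw, 2, scale, "*")
  sc <- sc / pmax(rowSums(sc), 1e-300) * 1000
  expect_equal(as.matrix(gs$counts), sc, tolerance = 1e-10,
               ignore_attr = TRUE)

  # all-zero cell stays all-zero; scores monotone in gene-body counts
  zero <- counts; zero[2, ] <- 0
  tm0 <- feature_matrix(methods::as(zero, "CsparseMatrix"),
                        tile_features(cs1, 500L), "tile")
  gs0 <- build_gene_score_matrix(tm0, gw, spec)
  expect_true(all(gs0$counts[2, ] == 0))
})

test_that("model evaluation ranks identity highest and flips sign", {
  set.seed(4)
  expr <- matrix(rpois(200 * 30, 5), 200, 30,
                 dimnames = list(paste0("c", 1:200), paste0("g", 1:30)))
  groups <- rep(c("x", "y", "z", "w"), each = 50)
  expr[groups == "x", 1:10] <- expr[groups == "x", 1:10] + 20
  expr[groups == "y", 11:20] <- expr[groups == "y", 11:20] + 20
  fm <- function(m) feature_matrix(methods::as(m, "CsparseMatrix"),
                                   data.table::data.table(
                                     chrom = NA, start = NA, end = NA,
                                     name = colnames(m)), "gene")
  ev <- evaluate_gene_models(
    list(identity = fm(expr), noise = fm(matrix(rpois(200 * 30, 5), 200, 30,
                                                dimnames = dimnames(expr)))),
    expr, groups, n_diff = 10, n_var = 20)
  expect_equal(ev$summary[model == "identity", rank], 1L)
  expect_gt(ev$tests[model == "identity", mean(mean_cor)], 0.9)
})

test_that("gene-body models outrank promoter-only on planted body signal", {
  sim <- small_sim()
  tiles <- small_tiles()
  presets <- gene_model_presets()
  gw_body <- gene_windows(sim$genes, sim$chrom_sizes,
                          presets$body_exponential_boundary)
  gw_prom <- gene_windows(sim$genes, sim$chrom_sizes, presets$promoter_only)
  gs_body <- build_gene_score_matrix(tiles, gw_body,
                                     presets$body_exponential_boundary)
  gs_prom <- build_gene_score_matrix(tiles, gw_prom, presets$promoter_only)
  expr <- simulate_paired_expression(sim, coupling = 1, seed = 5)
  groups <- sim$truth$type[match(rownames(tiles$counts), sim$truth$barcode)]
  ev <- evaluate_gene_models(list(body = gs_body, promoter = gs_prom),
                             expr[rownames(tiles$counts), ], groups,
                             n_diff = 12, n_var = 24)
  diff_test <- ev$tests[gene_set == "differential" & test == "per_gene"]
  expect_gt(diff_test[model == "body", mean_cor],
            diff_test[model == "promoter", mean_cor])
})
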