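test_that("pseudo-bulk plan follows sample-aware and fallback arithmetic", {
  cells3 <- data.table::data.table(
    barcode = sprintf("b%03d", 1:300),
    sample = rep(c("s1", "s2", "s3"), each = 100), cluster = "A")
  plan3 <- make_pseudobulk_plan(cells3, min_cells = 40, seed = 1)
  expect_equal(nrow(plan3$plan), 3)
  expect_equal(lengths(plan3$plan$members), rep(100L, 3))
  expect_setequal(plan3$plan$sample, c("s1", "s2", "s3"))

  # 60 cells in one sample -> 2 subsampled replicates of 0.8 * 60 = 48
  cells1 <- data.table::data.table(
    barcode = sprintf("b%03d", 1:60), sample = "s1", cluster = "A")
  plan1 <- make_pseudobulk_plan(cells1, min_cells = 40, seed = 2)
  expect_equal(nrow(plan1$plan), 2)
  expect_equal(lengths(plan1$plan$members), c(48L, 48L))
  expect_equal(plan1$plan$sample, rep("subsampled", 2))
  # minimal reuse: overlap is exactly 2*48 - 60 = 36
  expect_length(intersect(plan1$plan$members[[1]],
                          plan1$plan$members[[2]]), 36)

  plan1b <- make_pseudobulk_plan(cells1, min_cells = 40, seed = 2)
  expect_identical(plan1$plan, plan1b$plan)

  # a tiny cluster is flagged, an all-tiny input errors
  tiny <- data.table::data.table(barcode = paste0("t", 1:20),
                                 sample = "s1", cluster = "B")
  planT <- make_pseudobulk_plan(rbind(cells1, tiny), min_cells = 40, seed = 1)
  expect_equal(planT$flagged, "B")
  expect_error(make_pseudobulk_plan(tiny, min_cells = 40), "no cluster")
})

test_that("group coverage is canonical bedGraph and conserves mass", {
  cs <- chrom_sizes("chr1", 5000L)
  frags <- data.table::data.table(chrom = "chr1", start = c(100L, 100L, 300L),
                                  end = c(200L, 200L, 301L),
                                  barcode = c("a", "b", "a"), count = c(1L, 2L, 1L))
  store <- create_fragment_store(frags, cs)
  cov <- export_group_coverage(store, list(g1 = c("a", "b")))$g1
  # single-base insertion piles: 100 (w3), 199 (w3), 300 (w2, two ends)
  expect_equal(cov$start, c(100L, 199L, 300L))
  expect_equal(cov$end, cov$start + 1L)
  expect_equal(cov$value, c(3, 3, 2))
  expect_equal(sum(cov$value * (cov$end - cov$start)), 2 * sum(frags$count))

  # adjacent equal-valued bases merge into one interval
  flat <- data.table::data.table(chrom = "chr1", start = 1000:1009,
                                 end = 1001:1010, barcode = "a", count = 1L)
  store2 <- create_fragment_store(flat, cs)
  cov2 <- export_group_coverage(store2, list(g = "a"))$g
  expect_equal(nrow(cov2), 1)
  expect_equal(cov2$value, 2)
  expect_equal(c(cov2$start, cov2$end), c(1000L, 1010L))
})

test_that("naive summit calling finds apexes with leftmost tie-breaking", {
  mk_cov <- function(pos, val) data.table::data.table(
    chrom = "chr1", start = pos, end = pos + 1L, value = val)
  # triangular bump
  tri <- mk_cov(1000:1020, c(1:11, 10:1))
  s <- call_summits_naive(tri, smoothing_window = 1, min_score = 1)
  expect_equal(s$pos, 1010L)
  # two bumps 2 kb apart
  two <- rbind(mk_cov(1000:1020, c(1:11, 10:1)),
               mk_cov(3000:3020, c(1:11, 10:1)))
  s2 <- call_summits_naive(two, smoothing_window = 1, min_score = 1)
  expect_equal(s2$pos, c(1010L, 3010L))
  # plateau: leftmost position wins
  plat <- mk_cov(500:520, c(1:5, rep(6, 11), 5:1))
  s3 <- call_summits_naive(plat, smoothing_window = 1, min_score = 1)
  expect_equal(s3$pos, 505L)
  # flat zero profile yields nothing
  expect_equal(nrow(call_summits_naive(mk_cov(10:20, rep(0, 11)),
                                       smoothing_window = 1, min_score = 1)), 0)
})

test_that("summit extension truncates at bounds and normalizes per million", {
  cs <- chrom_sizes("chr1", 100000L)
  summits <- data.table::data.table(chrom = "chr1", pos = c(1000L, 100L),
                                    score = c(30, 10))
  cand <- summits_to_candidates(summits, width = 501L, chrom_sizes = cs)
  expect_equal(cand[1, .(start, end)],
               data.table::data.table(start = 750L, end = 1251L))
  expect_equal(cand[2, start], 0L) # truncated at chromosome start
  expect_equal(cand$score_per_million, c(30, 10) / (40 / 1e6))
  # proportional replicate scores give identical score-per-million
  cand2 <- summits_to_candidates(
    data.table::data.table(chrom = "chr1", pos = c(1000L, 100L),
                           score = c(300, 100)), 501L, cs)
  expect_equal(cand2$score_per_million, cand$score_per_million)
  expect_error(summits_to_candidates(summits, width = 500L, cs), "odd")
})

test_that("iterative overlap merge follows the greedy hand trace", {
  cand <- data.table::data.table(
    chrom = "chr1", start = c(0L, 250L, 600L), end = c(501L, 751L, 1101L),
    summit = c(250L, 500L, 850L), score_per_million = c(10, 8, 9))
  kept <- iterative_overlap_merge(cand)
  expect_equal(kept$start, c(0L, 600L)) # A and C; B overlaps A
  expect_equal(kept$n_overlapping, c(1L, 1L)) # B overlapped both kept peaks
  # non-overlapping input is identity, and merging is idempotent
  disj <- data.table::data.table(chrom = "chr1", start = c(0L, 1000L),
                                 end = c(501L, 1501L), summit = c(250L, 1250L),
                                 score_per_million = c(1, 2))
  m1 <- iterative_overlap_merge(disj)
  expect_equal(m1[, .(chrom, start, end)], disj[, .(chrom, start, end)])
  m2 <- iterative_overlap_merge(m1)
  expect_equal(m2, m1)
})

test_that("greedy merge equals an exhaustive max-score-first oracle", {
  oracle <- function(cand) {
    cand <- cand[order(-score_per_million, start, chrom)]
    kept <- integer()
    for (i in seq_len(nrow(cand))) {
      ov <- FALSE
      for (j in kept) {
        if (cand$chrom[i] == cand$chrom[j] &&
            cand$start[i] < cand$end[j] && cand$end[i] > cand$start[j]) {
          ov <- TRUE; break
        }
      }
      if (!ov) kept <- c(kept, i)
    }
    out <- cand[kept]
    data.table::setorder(out, chrom, start)
    out[, .(chrom, start, end, score_per_million)]
  }
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:20, 1)
    cand <- data.table::data.table(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(3000, n))
    cand[, end := start + 501L]
    cand[, score_per_million := round(runif(n) * 100, 1)]
    got <- iterative_overlap_merge(cand)[, .(chrom, start, end,
                                             score_per_million)]
    expect_equal(got, oracle(cand))
  }
})

test_that("reproducible peak set enforces replicate support and global merge", {
  mk <- function(starts, score, rep_id, cluster) data.table::data.table(
    chrom = "chr1", start = starts, end = starts + 501L,
    summit = starts + 250L, score_per_million = score,
    replicate = rep_id, cluster = cluster)
  # peak at 1000 in both replicates, peak at 5000 only in rep1
  cand <- rbind(mk(c(1000L, 5000L), c(50, 40), "r1", "A"),
                mk(1010L, 45, "r2", "A"))
  ps <- reproducible_peak_set(cand, min_rep_support = 2)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$start, 1000L)
  expect_equal(ps$n_replicates_support, 2L)
  # identical replicate candidates are all retained
  cand2 <- rbind(mk(c(1000L, 5000L), c(50, 40), "r1", "A"),
                 mk(c(1000L, 5000L), c(50, 40), "r2", "A"))
  ps2 <- reproducible_peak_set(cand2, min_rep_support = 2)
  expect_equal(ps2$start, c(1000L, 5000L))
  # global merge keeps the higher-scoring copy of a shared peak
  cand3 <- rbind(cand2,
                 rbind(mk(c(990L, 8000L), c(90, 20), "r1", "B"),
                       mk(c(990L, 8000L), c(90, 20), "r2", "B")))
  ps3 <- reproducible_peak_set(cand3, min_rep_support = 2)
  shared <- ps3[start < 1500]
  expect_equal(nrow(shared), 1)
  expect_equal(shared$group_of_origin, "B")
  # blacklist removal
  ps4 <- reproducible_peak_set(cand2, min_rep_support = 2,
                               blacklist = data.table::data.table(
                                 chrom = "chr1", start = 900L, end = 1100L))
  expect_equal(ps4$start, 5000L)
})

test_that("final peak sets are disjoint fixed-width and recover planted sites", {
  sim <- small_sim()
  store <- small_store()
  truth <- sim$truth
  cl <- setNames(truth$type, truth$barcode)
  cells <- data.table::data.table(
    barcode = names(cl),
    sample = store$barcodes$sample[match(names(cl), store$barcodes$barcode)],
    cluster = cl)
  plan <- make_pseudobulk_plan(cells, min_cells = 30, seed = 101)
  peaks <- call_peaks(store, plan, genome = sim$genome)
  # pairwise disjoint, constant width except chromosome-edge truncation
  data.table::setorder(peaks, chrom, start)
  gaps <- peaks[, start[-1] - end[-.N], by = chrom]$V1
  expect_true(all(gaps >= 0))
  widths <- peaks$end - peaks$start
  expect_true(all(widths == 501 | peaks$start == 0 |
                    peaks$end == sim$chrom_sizes[peaks$chrom]))
  expect_true(all(peaks$gc_fraction >= 0 & peaks$gc_fraction <= 1))
  pl <- sim$peaks
  hit <- vapply(seq_len(nrow(pl)), function(i) {
    any(peaks$chrom == pl$chrom[i] &
          abs(peaks$summit - (pl$start[i] + pl$end[i]) / 2) <= 100)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
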