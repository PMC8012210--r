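consensus_pfm <- function(consensus, height = 20) {
  pfm <- matrix(0, 4, length(consensus),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) pfm[consensus[j], j] <- height
  pfm
}

test_that("JASPAR parsing and PWM conversion", {
  p <- tempfile()
  writeLines(c(">MA0001.1 TESTTF",
               "A [ 10  0  0 ]",
               "C [  0 10  0 ]",
               "G [  0  0 10 ]",
               "T [  0  0  0 ]"), p)
  pwms <- read_jaspar(p)
  expect_named(pwms, "TESTTF")
  expect_equal(dim(pwms$TESTTF), c(4L, 3L))
  pwm <- pfm_to_pwm(pwms$TESTTF)
  expect_equal(unname(pwm["A", 1]), log2((10.25 / 11) / 0.25))
  expect_lt(pwm["T", 1], 0)
})

test_that("motif scanning finds planted consensus on both strands", {
  set.seed(1)
  seqs <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
    character(1))
  cons <- c("T", "G", "A", "C", "G", "T", "A", "A") # not a palindrome
  fwd_str <- paste(cons, collapse = "")
  rc_str <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd_str)))
  substr(seqs[1], 101, 108) <- fwd_str
  substr(seqs[2], 151, 158) <- rc_str
  genome <- Biostrings::DNAStringSet(setNames(seqs, paste0("chr", 1:3)))
  peaks <- data.table::data.table(chrom = paste0("chr", 1:3),
                                  start = 0L, end = 300L)
  sc <- scan_motifs(peaks, genome, list(M = consensus_pfm(cons)),
                    score_frac = 0.95)
  expect_equal(as.vector(sc$matches[, "M"] > 0), c(TRUE, TRUE, FALSE))
  # match centers at the planted positions
  expect_equal(sc$positions[peak == 1, pos], 100L + 4L)
  expect_equal(sc$positions[peak == 2, pos], 150L + 4L)
  expect_equal(sc$positions[peak == 2, strand], "-")
  expect_error(scan_motifs(data.table::data.table(chrom = "chr1",
                                                  start = 0L, end = 999L),
                           genome, list(M = consensus_pfm(cons))), "beyond")
})

test_that("scan scores equal brute-force per-position PWM sums", {
  set.seed(2)
  seq60 <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq60))
  pfm <- matrix(rpois(4 * 5, 5) + 1, 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(pfm)
  # brute force best score over positions and strands
  codes <- match(strsplit(seq60, "")[[1]], c("A", "C", "G", "T"))
  brute <- function(pw) {
    vapply(1:(60 - 4), function(s)
      sum(pw[cbind(codes[s:(s + 4)], 1:5)]), numeric(1))
  }
  rcpwm <- pwm[4:1, 5:1]
  best <- max(pmax(brute(pwm), brute(rcpwm)))
  peaks <- data.table::data.table(chrom = "chr1", start = 0L, end = 60L)
  sc <- scan_motifs(peaks, genome, list(M = pwm), min_score = best - 1e-9)
  expect_equal(nrow(sc$positions), 1)
  expect_equal(sc$positions$score, best, tolerance = 1e-12)
})

test_that("hypergeometric enrichment matches the closed-form sum", {
  ann <- Matrix::sparseMatrix(i = 1:20, j = rep(1, 20), x = 1,
                              dims = c(100, 1), dimnames = list(NULL, "m"))
  sel <- c(1:5, 50:54) # n = 10, k = 5, K = 20, N = 100
  res <- hypergeom_enrichment(sel, ann)
  closed <- sum(vapply(5:10, function(i)
    choose(20, i) * choose(80, 10 - i) / choose(100, 10), numeric(1)))
  expect_equal(res$p_value, closed, tolerance = 1e-12)
  expect_equal(round(closed, 4), 0.0255)
  expect_equal(res$fold_enrichment, (5 / 10) / (20 / 100))
  # k = n = K = N -> p = 1; k = 0 -> p = 1
  annN <- Matrix::sparseMatrix(i = 1:4, j = rep(1, 4), x = 1, dims = c(4, 1))
  expect_equal(hypergeom_enrichment(1:4, annN)$p_value, 1)
  ann0 <- Matrix::sparseMatrix(i = 3:4, j = c(1, 1), x = 1, dims = c(10, 1))
  expect_equal(hypergeom_enrichment(1:2, ann0)$p_value, 1)
  expect_error(hypergeom_enrichment(integer(), ann), "empty")
  # exhaustive agreement with phyper-free enumeration for tiny universes
  for (N in 4:12) {
    K <- sample.int(N, 1); n <- sample.int(N, 1)
    annS <- Matrix::sparseMatrix(i = seq_len(K), j = rep(1, K), x = 1,
                                 dims = c(N, 1))
    sel <- seq_len(n)
    k <- sum(sel <= K)
    man <- sum(vapply(k:min(n, K), function(i)
      choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1)))
    expect_equal(hypergeom_enrichment(sel, annS)$p_value, man,
                 tolerance = 1e-10)
  }
})

test_that("background peaks are matched on GC and accessibility", {
  set.seed(3)
  gc <- runif(400, 0.2, 0.8)
  acc <- rexp(400, 1)
  bg <- select_background_peaks(gc, acc, n_background = 30, seed = 4)
  expect_equal(dim(bg), c(400L, 30L))
  expect_true(all(bg != row(bg))) # never the peak itself
  diffs <- abs(rowMeans(matrix(gc[bg], 400)) - gc)
  expect_lt(mean(diffs), 0.05)
  bg2 <- select_background_peaks(gc, acc, n_background = 30, seed = 4)
  expect_identical(bg, bg2)
})

test_that("deviations vanish under exact depth proportionality", {
  # counts proportional to depth per peak -> raw deviations identically 0
  base <- c(5, 1, 3, 8, 2, 6, 4, 7, 2, 5)
  depth_f <- c(1, 2, 4, 0.5, 3)
  counts <- outer(depth_f, base)
  rownames(counts) <- paste0("c", 1:5)
  m <- methods::as(counts, "CsparseMatrix")
  ann <- Matrix::sparseMatrix(i = c(1, 3, 5), j = rep(1, 3), x = 1,
                              dims = c(10, 1), dimnames = list(NULL, "m"))
  bg <- matrix(rep(c(2, 4, 6), each = 10), 10, 3)
  dev <- compute_deviations(m, ann, bg)
  expect_equal(max(abs(dev$raw)), 0, tolerance = 1e-12)
  # a motif covering all peaks deviates by 0 with z forced to 0
  annAll <- Matrix::sparseMatrix(i = 1:10, j = rep(1, 10), x = 1,
                                 dims = c(10, 1))
  devAll <- compute_deviations(m, annAll, bg)
  expect_equal(max(abs(devAll$z)), 0)
})

test_that("deviation z-scores are depth-scale invariant and near-null for random motifs", {
  sim <- small_sim()
  store <- small_store()
  pm <- build_peak_matrix(store, sim$peaks[, .(chrom, start, end, name)])
  fp <- pm$features # peak matrix columns are coordinate-sorted
  gc <- peak_gc(fp, sim$genome)
  bg <- select_background_peaks(gc, Matrix::colMeans(pm$counts),
                                n_background = 25, seed = 5)
  set.seed(6)
  ann <- Matrix::sparseMatrix(
    i = sample.int(nrow(fp), 40), j = rep(1, 40),
    dims = c(nrow(fp), 1), dimnames = list(NULL, "rand"), x = 1)
  dev <- compute_deviations(pm, ann, bg)
  expect_lt(abs(mean(dev$z)), 0.5)
  scaled <- pm
  scaled$counts <- pm$counts * 3
  dev3 <- compute_deviations(scaled, ann, bg)
  expect_equal(dev$z, dev3$z, tolerance = 1e-8)
  # planted signal: type1 cells have elevated z at type1 peaks
  type1_names <- sim$peaks[kind == "type1", name]
  ann1 <- Matrix::sparseMatrix(
    i = which(fp$name %in% type1_names),
    j = rep(1, sum(fp$name %in% type1_names)),
    dims = c(nrow(fp), 1), dimnames = list(NULL, "type1"), x = 1)
  dev1 <- compute_deviations(pm, ann1, bg)
  type_of <- sim$truth$type[match(rownames(pm$counts), sim$truth$barcode)]
  expect_gt(mean(dev1$z[type_of == "type1", 1]),
            mean(dev1$z[type_of != "type1", 1]) + 1)
})

test_that("positive TF regulators require positive correlation", {
  set.seed(7)
  groups <- rep(paste0("g", 1:6), each = 10)
  z <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("mA", "mB")))
  shift <- rep(seq(0, 5, 1), each = 10)
  z[, "mA"] <- z[, "mA"] + shift
  expr <- matrix(rpois(60 * 2, 5), 60, 2,
                 dimnames = list(NULL, c("gA", "gB")))
  expr[, "gA"] <- rpois(60, exp(shift)) # rises with mA deviation
  expr[, "gB"] <- rpois(60, exp(5 - shift)) # anti-correlated with mA
  mapping <- data.frame(motif = c("mA", "mA", "mX"),
                        gene = c("gA", "gB", "gX"))
  expect_message(res <- positive_tf_regulators(z, expr, groups, mapping,
                                               correlation_cutoff = 0.5),
                 "unmapped")
  expect_true(res[motif == "mA" & gene == "gA", is_positive_regulator])
  expect_false(res[motif == "mA" & gene == "gB", is_positive_regulator])
  expect_lt(res[motif == "mA" & gene == "gB", correlation], 0)
})
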