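toy_counts <- function(n, p, seed = 1, density = 0.2) {
  set.seed(seed)
  m <- Matrix::rsparsematrix(n, p, density = density,
                             rand.x = function(k) rpois(k, 3) + 1)
  dimnames(m) <- list(paste0("c", seq_len(n)), paste0("f", seq_len(p)))
  m + 0 # force dgCMatrix
}

test_that("tf-idf matches hand arithmetic on a 2x2 matrix", {
  m <- Matrix::Matrix(matrix(c(1, 1, 0, 1), 2, 2,
                             dimnames = list(c("a", "b"), c("f1", "f2"))),
                      sparse = TRUE)
  out <- tfidf(m)
  # f1 in both cells: idf 1; f2 in one of two: idf 2
  expect_equal(out$idf, c(f1 = 1, f2 = 2))
  expect_equal(out$matrix["a", "f1"], log(1 + 1 * 1 * 1e4))
  expect_equal(out$matrix["a", "f2"], 0) # zero stays zero
  expect_equal(out$matrix["b", "f1"], log(1 + 0.5 * 1 * 1e4))
  expect_equal(out$matrix["b", "f2"], log(1 + 0.5 * 2 * 1e4))
  # all-zero cell errors, naming the barcode
  m0 <- m; m0["a", ] <- 0
  expect_error(tfidf(m0 + 0), "a")
})

test_that("lsi_fit agrees with a dense SVD oracle up to sign", {
  m <- toy_counts(50, 200, seed = 2)
  fit <- lsi_fit(m, n_components = 10)
  dense <- as.matrix(tfidf(m)$matrix)
  sv <- svd(dense)
  expect_equal(fit$model$singular_values, sv$d[1:10], tolerance = 1e-8)
  oracle_emb <- sv$u[, 1:10] %*% diag(sv$d[1:10])
  for (j in 1:10) {
    expect_equal(abs(fit$embedding[, j]), abs(oracle_emb[, j]),
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
  # loadings orthonormal
  expect_equal(crossprod(fit$model$loadings), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("duplicated cells land at identical coordinates", {
  m <- toy_counts(30, 100, seed = 3)
  m2 <- rbind(m, m[5, , drop = FALSE])
  rownames(m2)[31] <- "dup"
  fit <- lsi_fit(m2, n_components = 8)
  expect_equal(fit$embedding["dup", ], fit$embedding["c5", ],
               tolerance = 1e-8)
})

test_that("projection reproduces training coordinates and is linear", {
  m <- toy_counts(40, 150, seed = 4)
  fit <- lsi_fit(m, n_components = 8)
  proj <- lsi_project(fit$model, m)
  expect_equal(proj, fit$embedding, tolerance = 1e-6, ignore_attr = TRUE)

  # linearity in the normalized space: project rows of the normalized
  # matrix through the loadings
  norm <- tfidf(m, idf = fit$model$idf)$matrix
  x <- as.matrix(norm[1, , drop = FALSE])
  y <- as.matrix(norm[2, , drop = FALSE])
  pa <- (2 * x + 3 * y) %*% fit$model$loadings
  expect_equal(as.vector(pa),
               as.vector(2 * x %*% fit$model$loadings +
                           3 * y %*% fit$model$loadings), tolerance = 1e-10)

  # summed-cell (bulk-like) profile projects to finite coordinates
  bulk <- Matrix::Matrix(matrix(Matrix::colSums(m), 1,
                                dimnames = list("bulk", colnames(m))),
                         sparse = TRUE)
  expect_true(all(is.finite(lsi_project(fit$model, bulk))))

  expect_error(lsi_project(fit$model, m[, 1:100]), "missing")
})

test_that("retained components are depth-decorrelated", {
  tiles <- small_tiles()
  fit <- small_lsi()
  depth <- Matrix::rowSums(tiles$counts[, fit$features])
  emb <- fit$embedding
  r <- attr(emb, "retained")
  cors <- apply(emb[, r, drop = FALSE], 2, cor, y = log10(depth))
  expect_true(all(abs(cors) <= 0.75 + 1e-8))
})

test_that("one-iteration iterative LSI equals lsi_fit on top features", {
  m <- toy_counts(40, 300, seed = 6, density = 0.3)
  it1 <- iterative_lsi(m, n_iterations = 1, n_top_features = 100,
                       n_components = 8, seed = 9)
  feats <- colnames(m)[order(-Matrix::colSums(m))][1:100]
  direct <- lsi_fit(m, feats, n_components = 8, seed = 9)
  expect_equal(it1$embedding, direct$embedding)
  expect_identical(it1$features, feats)
})

test_that("iterative LSI recovers planted cell types and is seed-stable", {
  sim <- small_sim()
  fit <- small_lsi()
  truth <- sim$truth
  cl <- cluster_cells(fit$embedding, seed = 101)
  ari <- adjusted_rand_index(cl, truth$type[match(names(cl), truth$barcode)])
  expect_gte(ari, 0.9)
  fit2 <- iterative_lsi(small_tiles(), n_top_features = 2000L,
                        n_var_features = 2000L, n_components = 15L,
                        seed = 101)
  expect_identical(fit$features, fit2$features)
  expect_equal(fit$embedding, fit2$embedding)
})

test_that("estimated LSI degenerates to full LSI at 100% landmarks", {
  tiles <- small_tiles()
  full <- iterative_lsi(tiles, n_top_features = 2000L, n_var_features = 2000L,
                        n_components = 15L, seed = 101)
  est <- estimated_lsi(tiles, n_landmarks = nrow(tiles$counts), seed = 101,
                       n_top_features = 2000L, n_var_features = 2000L,
                       n_components = 15L)
  expect_equal(est$embedding, full$embedding, ignore_attr = TRUE)
  expect_error(estimated_lsi(tiles, n_landmarks = 10, n_components = 15L),
               "2 \\* n_components")
})

test_that("landmark-projected embeddings preserve cluster structure", {
  sim <- small_sim()
  tiles <- small_tiles()
  truth <- sim$truth
  full <- small_lsi()
  cl_full <- cluster_cells(full$embedding, seed = 101)
  for (s in c(101, 202)) {
    est <- estimated_lsi(tiles, n_landmarks = 60L, seed = s,
                         n_top_features = 2000L, n_var_features = 2000L,
                         n_components = 15L)
    cl_est <- cluster_cells(est$embedding, seed = 101)
    expect_gte(adjusted_rand_index(cl_full, cl_est), 0.8)
  }
})

test_that("clustering separates two Gaussian blobs and permutes consistently", {
  set.seed(7)
  emb <- rbind(matrix(rnorm(200, 0), 100, 2),
               matrix(rnorm(200, 8), 100, 2))
  rownames(emb) <- paste0("c", 1:200)
  cl <- cluster_cells(emb, k_neighbors = 15, resolution = 0.2, seed = 1)
  expect_equal(length(unique(cl)), 2)
  # whatever the resolution, the two blobs are never mixed
  cl_hi <- cluster_cells(emb, k_neighbors = 15, seed = 1)
  expect_true(all(rowSums(table(cl_hi, rep(1:2, each = 100)) > 0) == 1))
  perm <- sample(200)
  cl_p <- cluster_cells(emb[perm, ], k_neighbors = 15, resolution = 0.2,
                        seed = 1)
  expect_equal(adjusted_rand_index(cl[rownames(emb)[perm]], cl_p), 1)
})
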