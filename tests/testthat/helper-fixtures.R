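# shared fixtures; the expensive simulation is built once per test run
.fixtures <- new.env(parent = emptyenv())

# small 3-type simulation with linked pairs, cached
small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- sim_config(cells_per_type = 80L, n_genes = 24L,
                      chrom_length = 4e5, n_linked_pairs = 6L,
                      frags_per_cell = c(mean = 2500, sd = 500), seed = 101)
    .fixtures$sim <- simulate_fragments(cfg)
  }
  .fixtures$sim
}

small_store <- function() {
  if (is.null(.fixtures$store)) {
    sim <- small_sim()
    .fixtures$store <- create_fragment_store(sim$fragments, sim$chrom_sizes)
  }
  .fixtures$store
}

small_tiles <- function() {
  if (is.null(.fixtures$tiles)) {
    .fixtures$tiles <- build_tile_matrix(small_store())
  }
  .fixtures$tiles
}

small_lsi <- function() {
  if (is.null(.fixtures$lsi)) {
    .fixtures$lsi <- iterative_lsi(small_tiles(), n_top_features = 2000L,
                                   n_var_features = 2000L,
                                   n_components = 15L, seed = 101)
  }
  .fixtures$lsi
}

# write a fragment table as a bare TSV and return the path
write_frag_tsv <- function(dt, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  path
}

# random fragment table on one or two chromosomes
random_frags <- function(n, chroms = c(chr1 = 10000L), n_barcodes = 5L,
                         seed = 1L) {
  set.seed(seed)
  chrom <- sample(names(chroms), n, replace = TRUE)
  start <- floor(runif(n) * (chroms[chrom] - 300L))
  data.table::data.table(
    chrom = chrom, start = as.integer(start),
    end = as.integer(start + sample(50:250, n, replace = TRUE)),
    barcode = sprintf("BC%02d", sample.int(n_barcodes, n, replace = TRUE)),
    count = sample(1:3, n, replace = TRUE))
}
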