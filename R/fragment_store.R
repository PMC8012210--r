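#' @section Fragment store:
#' Fragments are stored on disk in a directory container with one
#' compressed chunk per chromosome. Each chunk holds parallel integer
#' arrays (start, end, barcode id, count) sorted by start, plus a global
#' barcode dictionary, so any region query touches a single chromosome
#' block and the store never has to be loaded whole.
#' @name fragment_store
NULL

STORE_META <- "meta.json"
STORE_BARCODES <- "barcodes.rds"
STORE_CHUNKDIR <- "chunks"

new_fragment_store <- function(path, samples, chrom_sizes, barcodes, skipped) {
  structure(
    list(path = normalizePath(path), samples = samples,
         chrom_sizes = chrom_sizes, barcodes = barcodes,
         skipped = skipped),
    class = "fragment_store"
  )
}

#' @exportS3Method base::print
print.fragment_store <- function(x, ...) {
  cat("fragment_store:", x$path, "\n")
  cat("  samples:   ", paste(x$samples, collapse = ", "), "\n")
  cat("  barcodes:  ", nrow(x$barcodes), "\n")
  cat("  fragments: ", sum(x$barcodes$n_frags), "(weighted)\n")
  cat("  chroms:    ", paste(names(x$chrom_sizes), collapse = ", "), "\n")
  invisible(x)
}

chunk_path <- function(store, chrom) {
  file.path(store$path, STORE_CHUNKDIR, paste0(chrom, ".rds"))
}

#' Import scATAC-seq fragment files into an on-disk store
#'
#' Parses one or more fragment files (TSV: chrom, start, end, barcode,
#' optional duplicate count; plain or gzip) into a chunked on-disk store.
#' Coordinates follow the 10x `fragments.tsv` dialect: 0-based half-open,
#' Tn5 offsets already applied upstream. Fragments on chromosomes absent
#' from `chrom_sizes`, or exceeding a chromosome bound, are skipped and
#' counted; barcodes with fewer than `min_frags` total fragments are
#' dropped.
#'
#' @param fragments path to a fragment file, or a named character vector
#'   of paths (names = sample ids) for multi-sample import.
#' @param sample_id sample identifier when `fragments` is a single
#'   unnamed path.
#' @param chrom_sizes named integer vector (see [chrom_sizes()]).
#' @param min_frags minimum total fragment count (duplicate-weighted) for
#'   a barcode to be retained.
#' @param out directory to create the store in (default: tempdir).
#' @param dedup collapse identical (chrom, start, end, barcode) records
#'   to a single count-1 record instead of retaining multiplicity.
#' @return a `fragment_store` object.
#' @export
import_fragments <- function(fragments, sample_id = NULL, chrom_sizes,
                             min_frags = 1L, out = NULL, dedup = FALSE) {
  if (is.null(names(fragments))) {
    if (length(fragments) != 1) {
      stop("multiple fragment files must be named by sample")
    }
    names(fragments) <- sample_id %||% "sample1"
  }
  frags <- data.table::rbindlist(lapply(names(fragments), function(sm) {
    dt <- read_fragment_file(fragments[[sm]])
    dt[, sample := sm]
    dt
  }))
  create_fragment_store(frags, chrom_sizes, out = out,
                        min_frags = min_frags, dedup = dedup)
}

read_fragment_file <- function(path) {
  dt <- if (grepl("\\.gz$", path)) {
    data.table::fread(cmd = paste("gzip -dc", shQuote(path)), header = FALSE,
                      sep = "\t", fill = TRUE, colClasses = "character")
  } else {
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = "character")
  }
  if (ncol(dt) < 4) stop("fragment file must have >= 4 columns: ", path)
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  count <- if (ncol(dt) >= 5) {
    suppressWarnings(as.integer(dt[[5]]))
  } else {
    rep(1L, nrow(dt))
  }
  bad <- which(is.na(start) | is.na(end) | dt[[1]] == "" | dt[[4]] == "" |
                 is.na(count) | count < 1L)
  if (length(bad)) {
    stop(sprintf("malformed fragment record at line %d of %s", bad[1], path))
  }
  data.table::data.table(chrom = dt[[1]], start = start, end = end,
                         barcode = dt[[4]], count = count)
}

#' Build a fragment store from an in-memory fragment table
#'
#' Core builder behind [import_fragments()]; also used to ingest
#' simulated fragments without a TSV round trip.
#'
#' @param frags data.frame with columns chrom, start, end, barcode,
#'   count (optional, default 1) and sample (optional, default
#'   "sample1").
#' @inheritParams import_fragments
#' @return a `fragment_store`.
#' @export
create_fragment_store <- function(frags, chrom_sizes, out = NULL,
                                  min_frags = 1L, dedup = FALSE) {
  frags <- data.table::as.data.table(frags)
  if (!"count" %in% names(frags)) frags[, count := 1L]
  if (!"sample" %in% names(frags)) frags[, sample := "sample1"]
  if (any(frags$start < 0L) || any(frags$start >= frags$end)) {
    stop("fragments must satisfy 0 <= start < end")
  }

  n_in <- nrow(frags)
  frags <- frags[chrom %in% names(chrom_sizes)]
  skipped_chrom <- n_in - nrow(frags)
  frags[, chrom_len := chrom_sizes[chrom]]
  oob <- frags$end > frags$chrom_len
  skipped_bounds <- sum(oob)
  frags <- frags[!oob][, chrom_len := NULL]
  if (skipped_chrom + skipped_bounds > 0) {
    message(sprintf("skipped %d fragment(s): %d on unlisted chromosomes, %d beyond chromosome bounds",
                    skipped_chrom + skipped_bounds, skipped_chrom, skipped_bounds))
  }

  if (dedup) {
    frags <- frags[, .(count = 1L), by = .(chrom, start, end, barcode, sample)]
  }

  bc_sample <- frags[, .(n_samples = data.table::uniqueN(sample)), by = barcode]
  if (any(bc_sample$n_samples > 1)) {
    stop("barcode(s) present in more than one sample; prefix barcodes per sample before import")
  }
  bc <- frags[, .(sample = sample[1], n_frags = sum(count)), by = barcode]
  bc <- bc[n_frags >= min_frags]
  if (nrow(bc) == 0) stop("no barcodes/fragments retained after filtering")
  data.table::setorder(bc, barcode)
  bc[, id := .I]
  frags <- frags[barcode %in% bc$barcode]
  frags[, bc := bc$id[match(barcode, bc$barcode)]]

  out <- out %||% tempfile("fragment_store_")
  dir.create(file.path(out, STORE_CHUNKDIR), recursive = TRUE, showWarnings = FALSE)
  samples <- sort(unique(bc$sample))
  for (chr in names(chrom_sizes)) {
    chunk <- frags[chrom == chr, .(start, end, bc, count)]
    if (nrow(chunk) == 0) next
    data.table::setorder(chunk, start, end, bc)
    saveRDS(chunk, file.path(out, STORE_CHUNKDIR, paste0(chr, ".rds")),
            compress = "gzip")
  }
  barcodes <- bc[, .(barcode, sample, n_frags)]
  skipped <- c(unlisted_chrom = skipped_chrom, out_of_bounds = skipped_bounds)
  saveRDS(barcodes, file.path(out, STORE_BARCODES))
  jsonlite::write_json(
    list(format = "chromflow-fragment-store-v1", samples = samples,
         chrom_sizes = as.list(chrom_sizes), skipped = as.list(skipped)),
    file.path(out, STORE_META), auto_unbox = TRUE
  )
  new_fragment_store(out, samples, chrom_sizes, barcodes, skipped)
}

#' Open an existing fragment store directory
#' @param path store directory created by [import_fragments()].
#' @return a `fragment_store`.
#' @export
open_fragment_store <- function(path) {
  meta <- jsonlite::read_json(file.path(path, STORE_META))
  cs <- chrom_sizes(names(meta$chrom_sizes), unlist(meta$chrom_sizes))
  new_fragment_store(path, unlist(meta$samples), cs,
                     readRDS(file.path(path, STORE_BARCODES)),
                     unlist(meta$skipped))
}

# load one chromosome chunk (start, end, bc, count); NULL if no fragments
read_chunk <- function(store, chrom) {
  p <- chunk_path(store, chrom)
  if (!file.exists(p)) return(NULL)
  readRDS(p)
}

#' Query fragments overlapping a genomic region
#'
#' Returns exactly the fragments overlapping `region` by at least one
#' base (half-open coordinates), optionally restricted to a barcode set,
#' sorted by start. Only the region's chromosome chunk is read.
#'
#' @param store a `fragment_store`.
#' @param region "chrom:start-end" string (0-based half-open).
#' @param barcodes optional character vector restricting the result.
#' @return data.table(chrom, start, end, barcode, count).
#' @export
query_fragments <- function(store, region, barcodes = NULL) {
  r <- parse_region(region)
  if (!r$chrom %in% names(store$chrom_sizes)) {
    stop("unknown chromosome: ", r$chrom)
  }
  chunk <- read_chunk(store, r$chrom)
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), barcode = character(),
                                  count = integer())
  if (is.null(chunk)) return(empty)
  hit <- chunk[start < r$end & end > r$start]
  hit[, barcode := store$barcodes$barcode[bc]]
  if (!is.null(barcodes)) hit <- hit[barcode %in% barcodes]
  if (nrow(hit) == 0) return(empty)
  out <- hit[, .(chrom = r$chrom, start, end, barcode, count)]
  data.table::setorder(out, start, end, barcode)
  out[]
}

#' Tn5 insertion sites of a fragment table
#'
#' Each fragment contributes two insertion events: one at `start` and one
#' at `end - 1` (the last covered base of the half-open interval), each
#' with the fragment's duplicate multiplicity as weight.
#'
#' @param fragments data.frame with chrom, start, end, barcode and
#'   optional count columns (e.g. from [query_fragments()]).
#' @return data.table(chrom, pos, barcode, weight).
#' @export
insertion_sites <- function(fragments) {
  dt <- data.table::as.data.table(fragments)
  if (!"count" %in% names(dt)) dt[, count := 1L]
  out <- data.table::rbindlist(list(
    dt[, .(chrom, pos = start, barcode, weight = count)],
    dt[, .(chrom, pos = end - 1L, barcode, weight = count)]
  ))
  data.table::setorder(out, chrom, pos)
  out[]
}

# per-chromosome insertion table with integer barcode ids (pos, bc, weight),
# sorted by pos; optionally restricted to barcode ids
chunk_insertions <- function(store, chrom, bc_ids = NULL) {
  chunk <- read_chunk(store, chrom)
  if (is.null(chunk)) return(NULL)
  if (!is.null(bc_ids)) chunk <- chunk[bc %in% bc_ids]
  if (nrow(chunk) == 0) return(NULL)
  ins <- data.table::rbindlist(list(
    chunk[, .(pos = start, bc, weight = count)],
    chunk[, .(pos = end - 1L, bc, weight = count)]
  ))
  data.table::setorder(ins, pos)
  ins
}

#' Export a fragment store back to a fragments TSV
#'
#' Writes chrom, start, end, barcode, count sorted by chromosome and
#' start; re-importing the export reproduces the store's records.
#'
#' @param store a `fragment_store`.
#' @param path output TSV path (".gz" suffix gzips).
#' @return `path`, invisibly.
#' @export
export_fragments <- function(store, path) {
  first <- TRUE
  for (chr in names(store$chrom_sizes)) {
    chunk <- read_chunk(store, chr)
    if (is.null(chunk)) next
    out <- chunk[, .(chrom = chr, start, end,
                     barcode = store$barcodes$barcode[bc], count)]
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                       append = !first)
    first <- FALSE
  }
  if (first) stop("store contains no fragments")
  invisible(path)
}

# total duplicate-weighted fragment count per barcode, named vector
store_depth <- function(store) {
  stats::setNames(store$barcodes$n_frags, store$barcodes$barcode)
}
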