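pipeline_stages <- c("import", "qc", "doublets", "reduce", "cluster",
                     "peaks", "peak_matrix", "markers", "trajectory")

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE, version = 2)
  unname(tools::md5sum(f))
}

file_hashes <- function(paths) {
  paths <- unlist(paths)
  unname(tools::md5sum(paths[file.exists(paths)]))
}

write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates import, QC, doublet removal, iterative LSI, clustering,
#' pseudo-bulk peak calling, peak matrix construction, marker testing and
#' (optionally) a supervised trajectory from one configuration. Each
#' stage writes its standard-format outputs plus a JSON provenance record
#' (parameters, seed, input hashes chained through upstream stages); a
#' rerun skips stages whose provenance is unchanged unless `force`.
#'
#' @param config YAML path or list. Top-level fields: `outdir`, `seed`,
#'   `fragments` (named sample -> path), `chrom_sizes`, `tss`, optional
#'   `simulate` (arguments to [sim_config()]; generates the inputs),
#'   per-stage parameter lists (`qc`, `doublets`, `reduce`, `cluster`,
#'   `peaks`, `markers`) and optional `trajectory` (list with `order`).
#' @param force recompute every stage.
#' @param stages run only up to / including these stages (dependencies
#'   always run or load from cache).
#' @return invisible list of stage results (`store`, `qc`, `doublets`,
#'   `reduce`, `cluster`, `peaks`, `peak_matrix`, `markers`,
#'   `trajectory`).
#' @export
run_pipeline <- function(config, force = FALSE, stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$outdir %||% stop("config$outdir is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  logfile <- file.path(out, "pipeline.log")
  logmsg <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }

  if (!is.null(config$simulate)) {
    simdir <- file.path(out, "sim")
    sim_hash <- hash_object(list(config$simulate, seed))
    prov <- file.path(simdir, "provenance.json")
    if (force || !file.exists(prov) ||
        jsonlite::read_json(prov)$hash != sim_hash) {
      logmsg("simulate: generating synthetic inputs")
      cfg <- do.call(sim_config, c(config$simulate, list(seed = seed)))
      sim <- simulate_fragments(cfg)
      paths <- write_simulation(sim, simdir)
      jsonlite::write_json(list(stage = "simulate", hash = sim_hash,
                                seed = seed), prov, auto_unbox = TRUE)
    } else {
      logmsg("simulate: up to date, skipping")
      paths <- list()
      for (sm in list.files(simdir, pattern = "^fragments_.*gz$")) {
        paths[[sub("\\.tsv\\.gz$", "", sm)]] <- file.path(simdir, sm)
      }
      paths$chrom_sizes <- file.path(simdir, "chrom.sizes")
      paths$tss <- file.path(simdir, "tss.bed")
      paths$genes <- file.path(simdir, "genes.tsv")
    }
    frag_files <- list.files(simdir, pattern = "^fragments_.*gz$",
                             full.names = TRUE)
    names(frag_files) <- sub("^fragments_(.*)\\.tsv\\.gz$", "\\1",
                             basename(frag_files))
    config$fragments <- as.list(frag_files)
    config$chrom_sizes <- file.path(simdir, "chrom.sizes")
    config$tss <- file.path(simdir, "tss.bed")
  }

  want <- stages %||% pipeline_stages
  if (is.null(config$trajectory)) want <- setdiff(want, "trajectory")
  run_until <- max(match(want, pipeline_stages))

  res <- list()
  prev_hash <- ""
  for (stage in pipeline_stages[seq_len(run_until)]) {
    if (stage == "trajectory" && is.null(config$trajectory)) next
    sdir <- file.path(out, stage)
    dir.create(sdir, showWarnings = FALSE)
    params <- config[[stage]] %||% list()
    inputs <- if (stage == "import") {
      file_hashes(c(config$fragments, config$chrom_sizes))
    } else character()
    hash <- hash_object(list(stage, params, seed, prev_hash, inputs))
    prov_path <- file.path(sdir, "provenance.json")
    state_path <- file.path(sdir, "state.rds")
    cached <- !force && file.exists(prov_path) && file.exists(state_path) &&
      identical(jsonlite::read_json(prov_path)$hash, hash)
    if (cached) {
      logmsg("%s: up to date, skipping", stage)
      res[[stage]] <- readRDS(state_path)
    } else {
      logmsg("%s: running", stage)
      res[[stage]] <- tryCatch(
        pipeline_stage(stage, config, params, res, seed, sdir),
        error = function(e) {
          stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
               call. = FALSE)
        })
      saveRDS(res[[stage]], state_path)
      jsonlite::write_json(list(stage = stage, hash = hash, seed = seed,
                                params = params,
                                time = format(Sys.time())),
                           prov_path, auto_unbox = TRUE)
    }
    prev_hash <- hash
  }
  invisible(res)
}

pipeline_stage <- function(stage, config, params, res, seed, sdir) {
  switch(stage,
    import = {
      cs <- if (is.character(config$chrom_sizes)) {
        read_chrom_sizes(config$chrom_sizes)
      } else {
        chrom_sizes(names(config$chrom_sizes), unlist(config$chrom_sizes))
      }
      store <- import_fragments(unlist(config$fragments), chrom_sizes = cs,
                                min_frags = params$min_frags %||% 100L,
                                out = file.path(sdir, "store"))
      list(store_path = store$path)
    },
    qc = {
      store <- open_fragment_store(res$import$store_path)
      tss <- if (is.character(config$tss)) read_tss_bed(config$tss) else
        data.table::as.data.table(config$tss)
      qc <- compute_cell_qc(store, tss)
      filt <- filter_cells(qc$cells, min_tss = params$min_tss %||% 4,
                           min_frags = params$min_frags %||% 1000)
      write_tsv(filt$cells, file.path(sdir, "qc.tsv"))
      write_tsv(qc$size_histogram, file.path(sdir, "fragment_sizes.tsv"))
      list(cells = filt$cells, retained = filt$retained)
    },
    doublets = {
      store <- open_fragment_store(res$import$store_path)
      tiles <- build_tile_matrix(store, params$tile_size %||% 500L,
                                 barcodes = res$qc$retained)
      lsi <- iterative_lsi(tiles, n_iterations = params$lsi_iterations %||% 2L,
                           n_components = params$n_components %||% 30L,
                           seed = seed)
      syn <- synthesize_doublets(tiles, seed = seed)
      syn_emb <- lsi_project(lsi$model, syn$counts)
      nf <- stats::setNames(res$qc$cells$n_frags, res$qc$cells$barcode)
      scores <- doublet_scores(lsi$embedding, syn_emb,
                               k = params$k %||% 10L, n_frags = nf)
      removed <- filter_doublets(scores, params$filter_ratio %||% 1)
      write_tsv(scores, file.path(sdir, "doublet_scores.tsv"))
      writeLines(removed, file.path(sdir, "removed_barcodes.txt"))
      list(scores = scores, removed = removed,
           kept = setdiff(res$qc$retained, removed))
    },
    reduce = {
      store <- open_fragment_store(res$import$store_path)
      kept <- res$doublets$kept %||% res$qc$retained
      tiles <- build_tile_matrix(store, params$tile_size %||% 500L,
                                 barcodes = kept)
      fit <- if (!is.null(params$landmarks)) {
        estimated_lsi(tiles, n_landmarks = params$landmarks, seed = seed,
                      n_iterations = params$iterations %||% 2L,
                      n_components = params$n_components %||% 30L,
                      n_var_features = params$n_var_features %||% 25000L)
      } else {
        iterative_lsi(tiles, n_iterations = params$iterations %||% 2L,
                      n_components = params$n_components %||% 30L,
                      n_var_features = params$n_var_features %||% 25000L,
                      cluster_resolution = params$cluster_resolution %||% 1,
                      seed = seed)
      }
      emb <- data.table::as.data.table(fit$embedding, keep.rownames = "barcode")
      write_tsv(emb, file.path(sdir, "embedding.tsv"))
      list(model = fit$model, embedding = fit$embedding,
           features = fit$features, tile_size = params$tile_size %||% 500L)
    },
    cluster = {
      labels <- cluster_cells(res$reduce$embedding,
                              k_neighbors = params$k_neighbors %||% 30L,
                              resolution = params$resolution %||% 1,
                              seed = seed)
      write_tsv(data.table::data.table(barcode = names(labels),
                                       cluster = labels),
                file.path(sdir, "clusters.tsv"))
      list(labels = labels)
    },
    peaks = {
      store <- open_fragment_store(res$import$store_path)
      labels <- res$cluster$labels
      cells <- data.table::data.table(
        barcode = names(labels),
        sample = store$barcodes$sample[match(names(labels),
                                             store$barcodes$barcode)],
        cluster = labels)
      plan <- make_pseudobulk_plan(cells,
                                   min_cells = params$min_cells %||% 40L,
                                   max_cells = params$max_cells %||% 500L,
                                   min_replicates = params$min_replicates %||% 2L,
                                   seed = seed)
      peaks <- call_peaks(store, plan, width = params$width %||% 501L,
                          min_score = params$min_score %||% 1,
                          min_rep_support = params$min_rep_support %||% 2L)
      write_peaks_bed(peaks, file.path(sdir, "peaks.bed"))
      list(plan = plan, peaks = peaks)
    },
    peak_matrix = {
      store <- open_fragment_store(res$import$store_path)
      kept <- res$doublets$kept %||% res$qc$retained
      pm <- build_peak_matrix(store, res$peaks$peaks, barcodes = kept)
      list(peak_matrix = pm)
    },
    markers = {
      qc <- res$qc$cells
      kept <- rownames(res$peak_matrix$peak_matrix$counts)
      bias <- cbind(log10(pmax(qc$n_frags, 1)), qc$tss_enrichment)
      rownames(bias) <- qc$barcode
      mk <- marker_features(res$peak_matrix$peak_matrix,
                            res$cluster$labels[kept], bias[kept, ],
                            fdr_cutoff = params$fdr %||% 0.01,
                            log2fc_cutoff = params$lfc %||% 1,
                            seed = seed)
      write_tsv(mk, file.path(sdir, "markers.tsv"))
      list(markers = mk)
    },
    trajectory = {
      traj <- fit_trajectory(res$reduce$embedding,
                             res$cluster$labels,
                             ordered_clusters = config$trajectory$order,
                             outlier_quantile = params$outlier_quantile %||% 0.9)
      write_tsv(data.table::data.table(
        barcode = names(traj$pseudotime), pseudotime = traj$pseudotime),
        file.path(sdir, "pseudotime.tsv"))
      list(trajectory = traj)
    },
    stop("unknown stage: ", stage))
}
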