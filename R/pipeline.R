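## One-shot driver wiring the stages together on files: prep -> featurize
## -> fit -> composite -> rsnp, with fail-fast input validation and a
## machine-readable run manifest.

#' Configure a full pipeline run
#'
#' Collects the file paths and tunables of every stage. Mandatory inputs
#' are the peak table, the genome FASTA and the motif file; `snps` is
#' required only when the `"rsnp"` stage is enabled, `tss` only for
#' promoter filtering.
#'
#' @param peaks,genome,motifs Paths to the peak table, genome FASTA and
#'   MEME motif file.
#' @param out_dir Output directory.
#' @param snps,tss Optional BED paths (SNP positions; TSS annotation).
#' @param dialect Peak-table dialect ([peak_dialect()]).
#' @param stages Stages to run, a subset of
#'   `c("prep", "featurize", "fit", "composite", "rsnp")` in this order.
#' @param width,mode Uniformization window width and mode.
#' @param filter,qmax,flank Peak filtering mode and its tunables.
#' @param group_size Score-cluster size for the exported motif-discovery
#'   FASTAs (clusters are exported whenever `"prep"` runs).
#' @param strands,alpha Scanning strands and presence/mapping threshold.
#' @param method,grid,n_iter,test_fraction Regression method and
#'   cross-validation protocol.
#' @param tau Normalized-coefficient threshold for composite selection.
#' @param k Cluster count for composites (`NULL`: silhouette choice).
#' @param min_pair_freq Composite co-occurrence threshold.
#' @param count_mode rSNP base-counting mode.
#' @param seed Seed used for every stochastic stage.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(peaks, genome, motifs, out_dir,
                            snps = NULL, tss = NULL,
                            dialect = peak_dialect(),
                            stages = c("prep", "featurize", "fit",
                                       "composite", "rsnp"),
                            width = 200, mode = "interval",
                            filter = "none", qmax = 0.05, flank = 2000,
                            group_size = 200,
                            strands = "both", alpha = 0.8,
                            method = "l1", grid = NULL, n_iter = 30,
                            test_fraction = 1/3, tau = 0.4, k = NULL,
                            min_pair_freq = 0.8, count_mode = "distinct",
                            seed = 17) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(peaks = peaks, genome = genome, motifs = motifs,
                 out_dir = out_dir, snps = snps, tss = tss,
                 dialect = dialect, stages = stages, width = width,
                 mode = mode, filter = filter, qmax = qmax, flank = flank,
                 group_size = group_size, strands = strands, alpha = alpha,
                 method = method, grid = grid, n_iter = n_iter,
                 test_fraction = test_fraction, tau = tau, k = k,
                 min_pair_freq = min_pair_freq, count_mode = count_mode,
                 seed = seed),
            class = "pipeline_config")
}

.validate_config <- function(config) {
  for (f in c("peaks", "genome", "motifs")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("pipeline config: input file for '", f, "' is missing",
           call. = FALSE)
  }
  if ("rsnp" %in% config$stages &&
      (is.null(config$snps) || !file.exists(config$snps)))
    stop("pipeline config: the 'rsnp' stage is enabled but no SNP BED ",
         "file was provided", call. = FALSE)
  if (config$filter == "promoter" &&
      (is.null(config$tss) || !file.exists(config$tss)))
    stop("pipeline config: promoter filtering needs a TSS BED file",
         call. = FALSE)
  invisible(TRUE)
}

#' Run the full pipeline on a configuration
#'
#' Validates all referenced inputs up front (fail fast, before any
#' compute), then executes the enabled stages in order, writing each
#' stage's outputs under `out_dir` and finally a `manifest.json` with the
#' package version, seed, parameters and MD5 checksums of every emitted
#' file. With the same configuration and seed the emitted ranking is
#' identical across runs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  .validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  peaks <- read_peak_table(config$peaks, config$dialect)
  genome <- read_fasta(config$genome)
  motifs <- read_meme_motifs(config$motifs)

  ## prep
  tss <- if (!is.null(config$tss)) read_bed(config$tss) else NULL
  peaks <- filter_peaks(peaks, config$filter, qmax = config$qmax,
                        tss = tss, flank = config$flank)
  peak_seqs <- uniformize_peaks(peaks, genome, width = config$width,
                                mode = config$mode)
  if ("prep" %in% config$stages) {
    uni <- peak_seqs[, c("chrom", "win_start", "win_end", "score",
                         "qvalue", "center", "id")]
    names(uni) <- c("chrom", "start", "end", "score", "qvalue", "center",
                    "id")
    write_peak_table(uni,
                     emit(file.path(config$out_dir, "peaks_uniform.tsv")))
    clusters <- cluster_by_score(peak_seqs, config$group_size)
    for (p in export_cluster_fastas(clusters,
                                    file.path(config$out_dir, "clusters")))
      emit(p)
    emit(file.path(config$out_dir, "clusters", "manifest.tsv"))
  }

  fm <- ranking <- NULL
  if (any(c("featurize", "fit", "composite", "rsnp") %in% config$stages)) {
    fm <- vectorize_peaks(peak_seqs, motifs, strands = config$strands)
    if ("featurize" %in% config$stages) {
      write_matrix_tsv(fm$V, emit(file.path(config$out_dir, "features.tsv")))
      write_matrix_tsv(fm$raw, emit(file.path(config$out_dir, "raw.tsv")))
      write.table(data.frame(id = names(fm$y), log_score = fm$y),
                  emit(file.path(config$out_dir, "y.tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  cv <- NULL
  if (any(c("fit", "composite") %in% config$stages)) {
    cv <- cv_peak_regression(fm, method = config$method, grid = config$grid,
                             n_iter = config$n_iter,
                             test_fraction = config$test_fraction,
                             seed = config$seed)
    ranking <- normalize_and_rank(cv)
    if ("fit" %in% config$stages) {
      write.table(ranking, emit(file.path(config$out_dir, "ranking.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(hyperparameter = cv$grid,
                             mean_test_correlation = cv$mean_cor_by_grid),
                  emit(file.path(config$out_dir, "cv_summary.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(method = cv$method,
                                best_hyperparameter = cv$best_hyperparameter,
                                mean_correlation = cv$mean_correlation,
                                mean_best_per_iteration =
                                  cv$mean_best_per_iteration,
                                intercept = cv$intercept,
                                coefficients = as.list(cv$coefficients)),
                           emit(file.path(config$out_dir, "model.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("composite" %in% config$stages) {
    sel <- select_motifs(ranking, config$tau)
    B <- presence_calls(fm, config$alpha)[, sel, drop = FALSE]
    cc <- kmeans_composites(B, k = config$k, seed = config$seed)
    assign_df <- data.frame(peak_id = names(cc$assignment),
                            cluster = unname(cc$assignment))
    write.table(assign_df, emit(file.path(config$out_dir, "composite_clusters.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report_composites(cc, config$min_pair_freq),
                emit(file.path(config$out_dir, "composite_report.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("rsnp" %in% config$stages) {
    sel <- if (!is.null(ranking)) {
      s <- ranking$motif_id[ranking$normalized_coefficient > config$tau]
      if (length(s)) s else NULL
    } else NULL
    pos <- motif_positions(peak_seqs, motifs, motif_ids = sel,
                           alpha = config$alpha, strands = config$strands)
    er <- enrichment_report(pos, read_snps(config$snps), peak_seqs,
                            count_mode = config$count_mode)
    write.table(data.frame(n = er$n, k = er$k, N = er$N, K = er$K,
                           motif_pct = er$motif_pct,
                           total_pct = er$total_pct, p_value = er$p_value),
                emit(file.path(config$out_dir, "rsnp_report.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package = "peakreg",
                   version = as.character(utils::packageVersion("peakreg")),
                   r_version = R.version.string,
                   seed = config$seed,
                   stages = config$stages,
                   parameters = config[setdiff(names(config),
                                               c("dialect", "grid"))],
                   checksums = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
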