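## Peak-sequence preparation: uniformize peaks to a fixed width, filter
## them (none / Q-value / promoter proximity), and group score-sorted
## peaks into fixed-size clusters for external motif discovery.

#' Uniformize peaks to fixed-width sequences
#'
#' Every peak is converted to a window of exactly `width` bp and its
#' sequence extracted from the genome. In `"center"` mode the window is
#' `[center - width/2, center + width/2)` around the annotated peak center;
#' in `"interval"` mode the peak interval `[start, end)` is symmetrically
#' enlarged or trimmed to `width`, with the odd leftover base applied on
#' the right. Windows that would cross a chromosome boundary are shifted
#' inward (with a warning) so the emitted sequence always has full width.
#'
#' @param peaks Peak data frame (see [read_peak_table()]).
#' @param genome Named character vector of chromosome sequences, e.g. from
#'   [read_fasta()].
#' @param width Window width in bp (default 200).
#' @param mode `"center"` (requires a `center` column without NAs) or
#'   `"interval"`.
#' @return Data frame of peak sequences: `id`, `chrom`, `win_start`,
#'   `win_end`, `seq`, `score`, `qvalue`, `center`.
#' @export
uniformize_peaks <- function(peaks, genome, width = 200,
                             mode = c("interval", "center")) {
  mode <- match.arg(mode)
  if (width < 1) stop("width must be positive", call. = FALSE)
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  if (mode == "center" && any(is.na(peaks$center)))
    stop("mode 'center' requires a center position on every peak",
         call. = FALSE)
  n <- nrow(peaks)
  if (mode == "center") {
    wstart <- peaks$center - width %/% 2
    wend <- wstart + width
  } else {
    delta <- width - (peaks$end - peaks$start)
    # enlargement: add delta%/%2 left, remainder right.
    # trimming (delta < 0): remove (-delta)%/%2 left, remainder right.
    wstart <- peaks$start - ifelse(delta >= 0, delta %/% 2, -((-delta) %/% 2))
    wend <- wstart + width
  }
  chrlen <- nchar(genome)[peaks$chrom]
  if (any(chrlen < width))
    stop("chromosome shorter than the requested window width", call. = FALSE)
  shift_r <- pmax(0, -wstart)
  shift_l <- pmax(0, wend - chrlen)
  if (any(shift_r > 0 | shift_l > 0))
    warning(sum(shift_r > 0 | shift_l > 0),
            " window(s) crossed a chromosome boundary and were shifted inward")
  wstart <- wstart + shift_r - shift_l
  wend <- wend + shift_r - shift_l
  seqs <- substring(genome[peaks$chrom], wstart + 1, wend)
  out <- data.frame(id = peaks$id, chrom = peaks$chrom,
                    win_start = as.integer(wstart),
                    win_end = as.integer(wend),
                    seq = unname(seqs), score = peaks$score,
                    qvalue = if ("qvalue" %in% names(peaks)) peaks$qvalue else NA_real_,
                    center = if ("center" %in% names(peaks)) peaks$center else NA_integer_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter peaks before regression
#'
#' Three filtering modes: `"none"` keeps everything, `"qvalue"` keeps peaks
#' whose multiple-testing-adjusted significance is at most `qmax`, and
#' `"promoter"` keeps peaks whose interval overlaps a promoter window
#' `[tss - flank, tss + flank)` around any annotated transcription start
#' site.
#'
#' @param peaks Peak data frame.
#' @param mode Filtering mode.
#' @param qmax Q-value threshold (default 0.05).
#' @param tss Data frame of TSS intervals (see [read_bed()]); the BED start
#'   of each record is taken as the TSS position. Required for
#'   `mode = "promoter"`.
#' @param flank Promoter half-width in bp around each TSS (default 2000).
#' @return The surviving subset of `peaks`.
#' @export
filter_peaks <- function(peaks, mode = c("none", "qvalue", "promoter"),
                         qmax = 0.05, tss = NULL, flank = 2000) {
  mode <- match.arg(mode)
  if (mode == "none") return(peaks)
  if (mode == "qvalue") {
    if (any(is.na(peaks$qvalue)))
      stop("Q-value filtering requires a Q-value on every peak; missing for: ",
           paste(utils::head(peaks$id[is.na(peaks$qvalue)], 5), collapse = ", "),
           call. = FALSE)
    return(peaks[peaks$qvalue <= qmax, , drop = FALSE])
  }
  if (is.null(tss) || !nrow(tss))
    stop("promoter filtering requires a non-empty TSS annotation", call. = FALSE)
  keep <- logical(nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    ti <- tss$start[tss$chrom == chr]
    pi <- which(peaks$chrom == chr)
    if (!length(ti) || !length(pi)) next
    ps <- peaks$start[pi]; pe <- peaks$end[pi]
    # overlap of [start, end) with any [t - flank, t + flank)
    hit <- vapply(seq_along(pi), function(j)
      any(ps[j] < ti + flank & pe[j] > ti - flank), logical(1))
    keep[pi] <- hit
  }
  peaks[keep, , drop = FALSE]
}

#' Group score-sorted peaks into fixed-size clusters
#'
#' Peaks are sorted by ascending enrichment score (ties broken by id) and
#' chunked into consecutive groups of `group_size`. A final remainder group
#' smaller than half of `group_size` is merged into the preceding cluster,
#' so no degenerate small cluster is handed to motif discovery.
#'
#' @param peak_seqs Data frame of peak sequences ([uniformize_peaks()]),
#'   or any peak data frame with `score` and `id` columns.
#' @param group_size Target cluster size (default 200).
#' @return List of class `"peak_clusters"`: one data frame per cluster, in
#'   ascending-score order, each with a `rank` attribute.
#' @export
cluster_by_score <- function(peak_seqs, group_size = 200) {
  if (group_size < 1) stop("group_size must be >= 1", call. = FALSE)
  n <- nrow(peak_seqs)
  if (is.null(n) || n == 0)
    return(structure(list(), class = "peak_clusters"))
  ord <- order(peak_seqs$score, peak_seqs$id)
  sorted <- peak_seqs[ord, , drop = FALSE]
  n_full <- n %/% group_size
  rem <- n %% group_size
  sizes <- rep(group_size, n_full)
  if (rem > 0) {
    if (rem >= group_size / 2 || n_full == 0) sizes <- c(sizes, rem)
    else sizes[n_full] <- sizes[n_full] + rem
  }
  stopifnot(sum(sizes) == n)
  bounds <- cumsum(c(0, sizes))
  clusters <- lapply(seq_along(sizes), function(k) {
    cl <- sorted[(bounds[k] + 1):bounds[k + 1], , drop = FALSE]
    rownames(cl) <- NULL
    attr(cl, "rank") <- k
    cl
  })
  structure(clusters, class = "peak_clusters")
}

#' @export
print.peak_clusters <- function(x, ...) {
  cat("Peak clusters:", length(x), "cluster(s) of sizes",
      paste(vapply(x, nrow, integer(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Export peak clusters as FASTA files for motif discovery
#'
#' Writes one FASTA per cluster (record ids are peak ids) plus a
#' `manifest.tsv` mapping cluster rank to file path and size. These files
#' are the input handed to an external motif-discovery run (e.g. MEME in
#' ZOOPS mode); the discovered motifs come back through
#' [read_meme_motifs()].
#'
#' @param clusters A `"peak_clusters"` list from [cluster_by_score()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of FASTA paths, in cluster-rank order.
#' @export
export_cluster_fastas <- function(clusters, outdir) {
  if (!length(clusters)) stop("no clusters to export", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create directory ", outdir, call. = FALSE)
  paths <- character(length(clusters))
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    paths[k] <- file.path(outdir, sprintf("cluster_%03d.fa", k))
    seqs <- cl$seq
    names(seqs) <- cl$id
    write_fasta(seqs, paths[k])
  }
  manifest <- data.frame(rank = seq_along(clusters), path = paths,
                         n_peaks = vapply(clusters, nrow, integer(1)))
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths
}
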