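## Fully synthetic inputs with known ground truth: background sequences
## with motif instances planted at controlled frequencies, peak scores
## generated from a linear model on the pipeline's own features, and SNP
## sets with an optional depletion factor inside planted footprints.

#' Specify a synthetic ChIP-Seq benchmark
#'
#' Defines the study conditions for the generator: peak number and width,
#' motif set size and length, the planted per-motif regression weights
#' (padded with zeros to `n_motifs`; zero-weight motifs are decoys), the
#' per-(peak, motif) plant probability, the noise level of the latent
#' log-score model, and the SNP rate with an optional depletion factor
#' inside planted motif footprints.
#'
#' @param n_peaks Number of peaks (default 500).
#' @param width Peak window width in bp (default 200).
#' @param n_motifs Number of motifs (default 50).
#' @param motif_length Motif length in bp (default 8).
#' @param weights Planted regression weights (default `c(3, 2, 1, -1, -2)`,
#'   padded with zeros).
#' @param plant_prob Probability of planting an instance of each motif in
#'   each peak (default 0.3).
#' @param noise_sigma Gaussian noise sd on the latent log score
#'   (default 0.1).
#' @param intercept Latent-model intercept (default 5, a typical log
#'   enrichment-score magnitude).
#' @param snp_rate Per-base SNP probability (default 0.005).
#' @param snp_depletion Multiplier on `snp_rate` inside planted motif
#'   footprints; 1 means no depletion (default 1).
#' @param consensus_prob Probability mass on the consensus letter at each
#'   motif position (default 0.85, an informative but noisy PSSM).
#' @param background Background base composition (default uniform).
#' @param pseudocount Pseudocount attached to generated motifs.
#' @param seed Random seed.
#' @return List of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_peaks = 500, width = 200, n_motifs = 50,
                           motif_length = 8,
                           weights = c(3, 2, 1, -1, -2),
                           plant_prob = 0.3, noise_sigma = 0.1,
                           intercept = 5, snp_rate = 0.005,
                           snp_depletion = 1, consensus_prob = 0.85,
                           background = rep(0.25, 4), pseudocount = 0.01,
                           seed = 1) {
  if (length(weights) > n_motifs)
    stop("more weights than motifs", call. = FALSE)
  if (motif_length > width) stop("motif longer than the peak width", call. = FALSE)
  if (plant_prob < 0 || plant_prob > 1)
    stop("plant_prob must be in [0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (snp_rate < 0 || snp_rate > 1) stop("snp_rate must be in [0, 1]", call. = FALSE)
  w <- c(weights, rep(0, n_motifs - length(weights)))
  structure(list(n_peaks = n_peaks, width = width, n_motifs = n_motifs,
                 motif_length = motif_length, weights = w,
                 plant_prob = plant_prob, noise_sigma = noise_sigma,
                 intercept = intercept, snp_rate = snp_rate,
                 snp_depletion = snp_depletion,
                 consensus_prob = consensus_prob, background = background,
                 pseudocount = pseudocount, seed = seed),
            class = "synthetic_spec")
}

.random_motifs <- function(spec) {
  lapply(seq_len(spec$n_motifs), function(j) {
    cons <- sample.int(4, spec$motif_length, replace = TRUE)
    probs <- matrix((1 - spec$consensus_prob) / 3,
                    spec$motif_length, 4)
    probs[cbind(seq_len(spec$motif_length), cons)] <- spec$consensus_prob
    motif_model(sprintf("M%02d", j), probs, background = spec$background,
                pseudocount = spec$pseudocount, source = "synthetic")
  })
}

#' Generate a synthetic benchmark dataset
#'
#' Draws a synthetic chromosome of `n_peaks` adjacent `width`-bp peak
#' windows with i.i.d. background bases, plants motif instances (sampled
#' position-wise from each motif's probability matrix at uniform offsets)
#' with the specified probability, recomputes the pipeline's own feature
#' matrix on the planted sequences, and sets each peak's enrichment score
#' to `exp(intercept + V w + Normal(0, sigma))` — so the generating model
#' matches the regression model and recovery is well-posed by
#' construction. SNPs are dropped per base at `snp_rate`, multiplied by
#' `snp_depletion` inside planted footprints.
#'
#' With a directory argument the five pipeline inputs are also written:
#' `genome.fa`, `peaks.tsv`, `motifs.meme`, `snps.bed` and `truth.json`.
#' Outputs are byte-identical for identical specs (seed included).
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory.
#' @return List of class `"synthetic_data"`: `peaks` (peak table),
#'   `peak_seqs`, `genome`, `motifs`, `snps`, `features` (the
#'   `"feature_matrix"`), and `truth` (weights, plants, intercept, spec).
#' @export
generate_synthetic <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_peaks; W <- spec$width; L <- spec$motif_length
  motifs <- .random_motifs(spec)
  glen <- n * W
  genome_v <- character(glen)
  plant_list <- vector("list", n)
  footprint <- logical(glen)

  draw_peak <- function(i) {
    base0 <- (i - 1L) * W
    idx_w <- base0 + seq_len(W)
    genome_v[idx_w] <<- sample(.BASES, W, replace = TRUE,
                               prob = spec$background)
    footprint[idx_w] <<- FALSE
    rows <- list()
    for (j in seq_len(spec$n_motifs)) {
      if (runif(1) >= spec$plant_prob) next
      off <- sample.int(W - L + 1L, 1L) - 1L
      probs <- motifs[[j]]$probs
      inst <- vapply(seq_len(L), function(p)
        sample(.BASES, 1, prob = probs[p, ]), character(1))
      idx <- base0 + off + seq_len(L)
      genome_v[idx] <<- inst
      footprint[idx] <<- TRUE
      rows[[length(rows) + 1]] <-
        data.frame(peak = i, motif_id = motifs[[j]]$id, offset = off,
                   genome_start = base0 + off, stringsAsFactors = FALSE)
    }
    plant_list[[i]] <<- if (length(rows)) do.call(rbind, rows) else NULL
  }
  for (i in seq_len(n)) draw_peak(i)

  # A peak in which every motif attains an identical raw score (e.g. all
  # planted instances hit their consensus exactly) has an all-zero shifted
  # feature row, which vectorization rejects; such peaks are redrawn.
  peak_seq_of <- function(i)
    paste(genome_v[((i - 1L) * W + 1L):(i * W)], collapse = "")
  degenerate <- function(idx) {
    mm <- scan_motifs(vapply(idx, peak_seq_of, character(1)), motifs)
    raw <- sweep(mm$score, 2, mm$max_score, "-")
    idx[apply(raw, 1, function(r) max(r) - min(r) < 1e-12)]
  }
  bad <- degenerate(seq_len(n))
  tries <- 0L
  while (length(bad) && tries < 50L) {
    for (i in bad) draw_peak(i)
    bad <- degenerate(bad)
    tries <- tries + 1L
  }
  if (length(bad))
    stop("could not draw non-degenerate peaks; use more motifs or a ",
         "lower plant probability", call. = FALSE)

  plants <- if (length(pl <- Filter(Negate(is.null), plant_list)))
    do.call(rbind, pl) else
    data.frame(peak = integer(0), motif_id = character(0),
               offset = integer(0), genome_start = integer(0))
  rownames(plants) <- NULL
  genome <- c(chrS = paste(genome_v, collapse = ""))
  ids <- sprintf("peak%04d", seq_len(n))
  peak_seqs <- data.frame(id = ids, chrom = "chrS",
                          win_start = as.integer((seq_len(n) - 1L) * W),
                          win_end = as.integer(seq_len(n) * W),
                          seq = substring(genome, (seq_len(n) - 1L) * W + 1,
                                          seq_len(n) * W),
                          score = NA_real_, qvalue = NA_real_,
                          center = as.integer((seq_len(n) - 1L) * W + W %/% 2),
                          stringsAsFactors = FALSE)
  fm <- vectorize_peaks(peak_seqs, motifs)
  noise <- rnorm(n, 0, spec$noise_sigma)
  y <- spec$intercept + drop(fm$V %*% spec$weights) + noise
  score <- exp(y)
  # Q-value anti-correlated with score (higher scores more significant),
  # spread over (0, 1) so Q-value filtering is exercisable.
  qvalue <- (rank(-score) - 0.5) / n
  peak_seqs$score <- score
  peak_seqs$qvalue <- qvalue
  fm$y <- stats::setNames(y, ids)
  peaks <- data.frame(chrom = "chrS", start = peak_seqs$win_start,
                      end = peak_seqs$win_end, score = score,
                      qvalue = qvalue, center = peak_seqs$center, id = ids,
                      stringsAsFactors = FALSE)
  rate <- ifelse(footprint, spec$snp_rate * spec$snp_depletion,
                 spec$snp_rate)
  snp_pos <- which(runif(glen) < rate) - 1L
  snps <- data.frame(chrom = rep("chrS", length(snp_pos)), pos = snp_pos,
                     stringsAsFactors = FALSE)
  truth <- list(weights = stats::setNames(
    spec$weights, vapply(motifs, function(m) m$id, character(1))),
    plants = plants, intercept = spec$intercept, spec = unclass(spec))
  out <- structure(list(peaks = peaks, peak_seqs = peak_seqs,
                        genome = genome, motifs = motifs, snps = snps,
                        features = fm, truth = truth),
                   class = "synthetic_data")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genome, file.path(dir, "genome.fa"))
    write_peak_table(peaks, file.path(dir, "peaks.tsv"))
    write_meme_motifs(motifs, file.path(dir, "motifs.meme"))
    bed <- data.frame(snps$chrom, snps$pos, snps$pos + 1L)
    write.table(bed, file.path(dir, "snps.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(weights = as.list(truth$weights),
                              plants = plants, intercept = spec$intercept,
                              seed = spec$seed),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
    out$files <- file.path(dir, c("genome.fa", "peaks.tsv", "motifs.meme",
                                  "snps.bed", "truth.json"))
  }
  out
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat("Synthetic benchmark:", nrow(x$peaks), "peaks x",
      length(x$motifs), "motifs;", nrow(x$truth$plants),
      "planted instances;", nrow(x$snps), "SNPs\n")
  invisible(x)
}

#' Compare a motif ranking against the generator's ground truth
#'
#' Recovery metrics for a fitted ranking on synthetic data: the fraction of
#' planted (nonzero-weight) motifs among the top-k ranks (k = number of
#' planted motifs), the fraction of planted motifs whose coefficient sign
#' matches the planted weight's sign, and the Spearman correlation between
#' planted |weight| and fitted |coefficient| over the planted motifs.
#'
#' @param truth Ground truth, either a `"synthetic_data"` object or its
#'   `truth` component.
#' @param ranking A `"motif_ranking"` from [normalize_and_rank()].
#' @return List with `top_k_overlap`, `sign_accuracy`,
#'   `rank_correlation`, `k`.
#' @export
truth_check <- function(truth, ranking) {
  if (inherits(truth, "synthetic_data")) truth <- truth$truth
  w <- truth$weights
  if (!all(ranking$motif_id %in% names(w)))
    stop("ranking contains motif ids absent from the ground truth",
         call. = FALSE)
  planted <- names(w)[w != 0]
  k <- length(planted)
  if (k == 0) stop("no planted motifs in the ground truth", call. = FALSE)
  topk <- utils::head(ranking$motif_id, k)
  cf <- stats::setNames(ranking$coefficient, ranking$motif_id)[planted]
  cf[is.na(cf)] <- 0
  list(top_k_overlap = length(intersect(topk, planted)) / k,
       sign_accuracy = mean(sign(cf) == sign(w[planted])),
       rank_correlation = suppressWarnings(
         cor(abs(w[planted]), abs(cf), method = "spearman")),
       k = k)
}
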