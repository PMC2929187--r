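## Regulatory-SNP candidate analysis: map motif matches onto genomic
## coordinates, intersect with known SNP positions, and test whether
## motif-covered bases carry fewer SNPs than peak bases at large — true
## binding sites are expected to be depleted of SNPs.

#' Genomic base positions covered by motif matches
#'
#' Takes every match of the selected motifs scoring at least
#' `alpha * max_score`, maps its window offsets back to genomic
#' coordinates via the peak windows, and returns the union of covered
#' positions (each base counted once, however many matches cover it).
#'
#' @param peak_seqs Peak-sequence data frame from [uniformize_peaks()]
#'   (columns `chrom`, `win_start`, `seq`, `id`).
#' @param motifs List of [motif_model()] objects.
#' @param motif_ids Motifs to map (default: all); an unknown id is an
#'   error.
#' @param alpha Match-score threshold fraction (default 0.8).
#' @param strands `"both"` or `"forward"`.
#' @return Data frame `chrom`, `pos` (0-based), unique.
#' @export
motif_positions <- function(peak_seqs, motifs, motif_ids = NULL, alpha = 0.8,
                            strands = c("both", "forward")) {
  strands <- match.arg(strands)
  hits <- .all_matches(peak_seqs, motifs, motif_ids, alpha, strands)
  chroms <- poss <- list()
  for (id in names(hits)) {
    h <- hits[[id]]
    if (!length(h$peak)) next
    L <- h$length
    start <- peak_seqs$win_start[h$peak] + h$offset
    chroms[[id]] <- rep(peak_seqs$chrom[h$peak], each = L)
    poss[[id]] <- as.integer(outer(0:(L - 1), start, "+"))
  }
  if (!length(poss))
    return(data.frame(chrom = character(0), pos = integer(0),
                      stringsAsFactors = FALSE))
  out <- unique(data.frame(chrom = unlist(chroms, use.names = FALSE),
                           pos = unlist(poss, use.names = FALSE),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Lower-tail hypergeometric test for SNP depletion
#'
#' Probability of observing at most `k` SNP-containing bases among `n`
#' motif-covered bases, when `K` of the `N` peak bases carry SNPs:
#' `p = sum_{i=0}^{k} C(K, i) C(N - K, n - i) / C(N, n)`, evaluated in log
#' space (stable for N in the millions). The lower tail tests depletion —
#' the working hypothesis that true binding sites tolerate fewer SNPs; the
#' upper tail (enrichment) is also available.
#'
#' @param k SNP-containing bases among the motif-covered ones.
#' @param n Motif-covered bases.
#' @param K SNP-containing bases among all peak bases.
#' @param N All peak bases.
#' @param tail `"lower"` (depletion, default) or `"upper"` (enrichment).
#' @return The tail probability.
#' @export
hypergeom_depletion <- function(k, n, K, N, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (k > n || n > N || K > N || k > K || k < 0)
    stop("need 0 <= k <= min(n, K) and n, K <= N", call. = FALSE)
  if (tail == "lower") phyper(k, K, N - K, n)
  else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.pos_key <- function(chrom, pos) paste0(chrom, ":", pos)

#' SNP depletion report for motif-mapped positions
#'
#' Counts SNPs among motif-covered bases (`k` of `n`) and among all peak
#' bases (`K` of `N`), reports both percentages (two decimals) and the
#' hypergeometric depletion p-value. With `count_mode = "distinct"`
#' (default) overlapping peak windows contribute each genomic base once;
#' `"length"` counts every window base with multiplicity (total sequence
#' length).
#'
#' @param positions Motif-covered positions ([motif_positions()]).
#' @param snps SNP set: data frame `chrom`, `pos` ([read_snps()]).
#' @param peak_seqs Peak-sequence data frame defining the universe of peak
#'   bases.
#' @param count_mode `"distinct"` or `"length"`.
#' @param tail Passed to [hypergeom_depletion()].
#' @return Object of class `"enrichment_result"`: `n`, `k`, `N`, `K`,
#'   `motif_pct`, `total_pct` (rounded to two decimals), `p_value`.
#' @export
enrichment_report <- function(positions, snps, peak_seqs,
                              count_mode = c("distinct", "length"),
                              tail = c("lower", "upper")) {
  count_mode <- match.arg(count_mode)
  tail <- match.arg(tail)
  if (!nrow(positions))
    stop("no motif-mapped positions; nothing to test", call. = FALSE)
  widths <- peak_seqs$win_end - peak_seqs$win_start
  win_chrom <- rep(peak_seqs$chrom, widths)
  win_pos <- unlist(lapply(seq_len(nrow(peak_seqs)), function(i)
    seq.int(peak_seqs$win_start[i], peak_seqs$win_end[i] - 1L)))
  win_key <- .pos_key(win_chrom, win_pos)
  if (count_mode == "distinct") win_key <- unique(win_key)
  snp_key <- unique(.pos_key(snps$chrom, snps$pos))
  pos_key <- unique(.pos_key(positions$chrom, positions$pos))
  N <- length(win_key)
  K <- sum(win_key %in% snp_key)
  n <- length(pos_key)
  k <- sum(pos_key %in% snp_key)
  enrichment_from_counts(k, n, K, N, tail = tail)
}

#' Build an enrichment result directly from counts
#'
#' @param k,n,K,N Counts as in [hypergeom_depletion()].
#' @param tail `"lower"` or `"upper"`.
#' @return An `"enrichment_result"` object.
#' @rdname enrichment_report
#' @export
enrichment_from_counts <- function(k, n, K, N, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  structure(list(n = n, k = k, N = N, K = K,
                 motif_pct = round(100 * k / n, 2),
                 total_pct = round(100 * K / N, 2),
                 p_value = hypergeom_depletion(k, n, K, N, tail = tail),
                 tail = tail),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("SNP", if (x$tail == "lower") "depletion" else "enrichment",
      "in motif-mapped positions\n")
  cat(sprintf("  motif-mapped: %.2f%% (%d SNP bases of %d bp)\n",
              x$motif_pct, x$k, x$n))
  cat(sprintf("  all peaks:    %.2f%% (%d SNP bases of %d bp)\n",
              x$total_pct, x$K, x$N))
  cat("  hypergeometric p-value:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
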