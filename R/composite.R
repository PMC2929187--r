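## Composite-motif identification: select high-coefficient motifs, encode
## peaks as binary presence vectors, cluster with K-means, and summarize
## per-cluster motif co-occurrence patterns.

#' Select motifs above a normalized-coefficient threshold
#'
#' Keeps the strengthening (positive-coefficient) motifs whose normalized
#' coefficient exceeds `tau`, preserving ranking order.
#'
#' @param ranking A `"motif_ranking"` from [normalize_and_rank()].
#' @param tau Threshold in `[0, 1]` (default 0.4).
#' @return Character vector of motif ids.
#' @export
select_motifs <- function(ranking, tau = 0.4) {
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]", call. = FALSE)
  ids <- ranking$motif_id[ranking$normalized_coefficient > tau]
  if (!length(ids))
    stop("no motif has a normalized coefficient above ", tau,
         "; lower tau", call. = FALSE)
  ids
}

.mean_silhouette <- function(d, cl) {
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
      mean(d[i, cl == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster binary motif-presence vectors with K-means
#'
#' Runs standard K-means (Euclidean metric on the 0/1 vectors, 10 random
#' restarts, best within-cluster sum of squares kept) on the peaks x
#' selected-motifs presence matrix. When `k` is `NULL` it is chosen by
#' mean silhouette width over `k_range`. Each cluster is summarized by its
#' motif signature — the per-motif presence frequency among its peaks.
#'
#' @param B Binary matrix, peaks x motifs (e.g. [presence_calls()]
#'   restricted to selected motifs).
#' @param k Number of clusters, or `NULL` to choose by silhouette.
#' @param seed Random seed (K-means restarts are stochastic).
#' @param n_start Number of random restarts (default 10).
#' @param k_range Candidate cluster counts when `k` is `NULL`.
#' @return Object of class `"composite_clusters"`: `assignment` (named
#'   integer vector), `clusters` (list with `cluster_id`, `peak_ids`,
#'   `size`, `signature`), `k`, `tot_withinss`.
#' @export
kmeans_composites <- function(B, k = NULL, seed = 17, n_start = 10,
                              k_range = 2:10) {
  B <- as.matrix(B)
  if (is.null(rownames(B))) rownames(B) <- sprintf("peak%d", seq_len(nrow(B)))
  n <- nrow(B)
  n_distinct <- nrow(unique(B))
  if (is.null(k)) {
    ks <- k_range[k_range >= 2 & k_range <= min(n - 1, n_distinct)]
    if (!length(ks)) {
      k <- 1L
    } else {
      d <- as.matrix(dist(B))
      sil <- vapply(ks, function(kk) {
        set.seed(seed)
        .mean_silhouette(d, kmeans(B, kk, nstart = n_start,
                                   iter.max = 100)$cluster)
      }, numeric(1))
      k <- ks[which.max(sil)]
    }
  }
  if (k > n) stop("k cannot exceed the number of peaks", call. = FALSE)
  if (k > n_distinct)
    stop("k cannot exceed the number of distinct presence patterns (",
         n_distinct, ")", call. = FALSE)
  set.seed(seed)
  km <- kmeans(B, k, nstart = n_start, iter.max = 100)
  clusters <- lapply(seq_len(k), function(g) {
    rows <- which(km$cluster == g)
    list(cluster_id = g, peak_ids = rownames(B)[rows], size = length(rows),
         signature = colMeans(B[rows, , drop = FALSE]))
  })
  structure(list(assignment = stats::setNames(km$cluster, rownames(B)),
                 clusters = clusters, k = k,
                 tot_withinss = km$tot.withinss, B = B),
            class = "composite_clusters")
}

#' @export
print.composite_clusters <- function(x, ...) {
  cat("Composite-motif clustering: k =", x$k, "clusters of sizes",
      paste(vapply(x$clusters, `[[`, integer(1), "size"), collapse = ", "),
      "\n")
  for (cl in x$clusters) {
    sig <- cl$signature
    top <- names(sig)[sig >= 0.5]
    cat(sprintf("  cluster %d (n=%d): %s\n", cl$cluster_id, cl$size,
                if (length(top)) paste(top, collapse = " + ") else "(none)"))
  }
  invisible(x)
}

#' Report co-occurring motif tuples per cluster
#'
#' Within each cluster, reports motif pairs whose joint presence frequency
#' reaches `min_pair_freq` — candidate composite motifs. Homotypic
#' composites (the same motif occurring at least twice in a peak) cannot be
#' read off a binary presence vector; they are detected from per-peak match
#' counts when `hit_counts` is supplied.
#'
#' @param cc A `"composite_clusters"` object.
#' @param min_pair_freq Minimum within-cluster joint presence frequency
#'   (default 0.8).
#' @param hit_counts Optional peaks x motifs matrix of qualifying match
#'   counts (see [motif_hit_counts()]) for homotypic detection.
#' @return Data frame `cluster_id`, `motif_a`, `motif_b`, `frequency`,
#'   `type` (`"heterotypic"`/`"homotypic"`), sorted by cluster then
#'   descending frequency.
#' @export
report_composites <- function(cc, min_pair_freq = 0.8, hit_counts = NULL) {
  stopifnot(inherits(cc, "composite_clusters"))
  B <- cc$B
  ids <- colnames(B)
  rows <- list()
  for (cl in cc$clusters) {
    sub <- B[cc$assignment == cl$cluster_id, , drop = FALSE]
    m <- ncol(sub)
    if (m >= 2) {
      for (a in 1:(m - 1)) for (b in (a + 1):m) {
        f <- mean(sub[, a] == 1 & sub[, b] == 1)
        if (f >= min_pair_freq)
          rows[[length(rows) + 1]] <- data.frame(
            cluster_id = cl$cluster_id, motif_a = ids[a], motif_b = ids[b],
            frequency = f, type = "heterotypic", stringsAsFactors = FALSE)
      }
    }
    if (!is.null(hit_counts)) {
      hc <- hit_counts[cl$peak_ids, , drop = FALSE]
      for (a in seq_len(m)) {
        f <- mean(hc[, ids[a]] >= 2)
        if (f >= min_pair_freq)
          rows[[length(rows) + 1]] <- data.frame(
            cluster_id = cl$cluster_id, motif_a = ids[a], motif_b = ids[a],
            frequency = f, type = "homotypic", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(cluster_id = integer(0), motif_a = character(0),
                      motif_b = character(0), frequency = numeric(0),
                      type = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster_id, -out$frequency, out$motif_a), ]
  rownames(out) <- NULL
  out
}

#' Count qualifying motif matches per peak
#'
#' Number of window offsets at which each motif scores at least
#' `alpha * max_score`, per peak (both strands pooled; an offset hit on
#' either strand counts once). Used for homotypic composite detection.
#'
#' @param peak_seqs Peak-sequence data frame ([uniformize_peaks()]).
#' @param motifs List of [motif_model()] objects.
#' @param alpha Match-score threshold fraction (default 0.8).
#' @param strands `"both"` or `"forward"`.
#' @return Integer matrix, peaks x motifs.
#' @export
motif_hit_counts <- function(peak_seqs, motifs, alpha = 0.8,
                             strands = c("both", "forward")) {
  strands <- match.arg(strands)
  hits <- .all_matches(peak_seqs, motifs, NULL, alpha, strands)
  n <- nrow(peak_seqs)
  out <- matrix(0L, n, length(hits),
                dimnames = list(peak_seqs$id, names(hits)))
  for (id in names(hits)) {
    tb <- tabulate(hits[[id]]$peak, nbins = n)
    out[, id] <- tb
  }
  out
}
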