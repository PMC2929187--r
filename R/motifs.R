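## PSSM log-odds scanning and peak vectorization.
##
## Each peak sequence is scored against each motif with a sliding log-odds
## scan; the raw feature is (best match score) - (maximum achievable
## score), so it is <= 0 with 0 exactly at a perfect-consensus match. Raw
## per-peak vectors are then shifted by their minimum and divided by their
## Euclidean norm.

.BASES <- c("A", "C", "G", "T")

#' Build a log-odds scoring matrix from a motif model
#'
#' Log-odds (base 2, "bits") of the pseudocount-smoothed letter
#' probabilities against the background:
#' `lom[p, a] = log2(((probs[p, a] + pc) / (1 + 4 pc)) / background[a])`.
#' With pseudocount 0, a zero probability yields `-Inf` (a hard mismatch).
#' `max_score` is the sum over positions of the best letter score — the
#' score of the motif's consensus, the best any sequence can achieve.
#'
#' @param motif A [motif_model()].
#' @return List of class `"log_odds"` with elements `motif_id`, `lom`
#'   (L x 4 matrix), `max_score` and `length`.
#' @export
build_log_odds <- function(motif) {
  stopifnot(inherits(motif, "motif_model"))
  if (any(motif$background <= 0))
    stop("background probabilities must be strictly positive", call. = FALSE)
  pc <- motif$pseudocount
  p <- (motif$probs + pc) / (1 + 4 * pc)
  lom <- log2(sweep(p, 2, motif$background, "/"))
  structure(list(motif_id = motif$id, lom = lom,
                 max_score = sum(apply(lom, 1, max)),
                 length = nrow(lom)),
            class = "log_odds")
}

.revcomp_lom <- function(lom) lom[rev(seq_len(nrow(lom))), 4:1, drop = FALSE]

#' Reverse-complement DNA strings
#'
#' @param seq Character vector of DNA strings (A/C/G/T/N).
#' @return Reverse complements.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(toupper(seq), NULL), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

# Encode sequences (equal length) as an integer matrix: A=1 C=2 G=3 T=4,
# N=5 (scores as background, i.e. log-odds contribution 0).
.encode_seqs <- function(seqs) {
  if (!length(seqs)) stop("no sequences", call. = FALSE)
  W <- unique(nchar(seqs))
  if (length(W) != 1)
    stop("all sequences must have the same length", call. = FALSE)
  m <- matrix(match(unlist(strsplit(toupper(seqs), NULL)),
                    c(.BASES, "N")),
              nrow = length(seqs), ncol = W, byrow = TRUE)
  if (anyNA(m))
    stop("sequences contain letters outside {A, C, G, T, N}", call. = FALSE)
  m
}

# All-offset window scores for one strand of one motif.
# S: n x W integer codes; lom: L x 4. Returns n x (W - L + 1).
.scan_scores <- function(S, lom) {
  L <- nrow(lom)
  W <- ncol(S)
  n_off <- W - L + 1L
  if (n_off < 1) stop("sequence shorter than motif", call. = FALSE)
  n <- nrow(S)
  sc <- matrix(0, n, n_off)
  for (p in seq_len(L)) {
    w5 <- c(lom[p, ], 0)  # N contributes 0
    sc <- sc + matrix(w5[S[, p:(p + n_off - 1), drop = FALSE]], n, n_off)
  }
  sc
}

#' Best sliding-window log-odds match of a motif in a sequence
#'
#' Slides the motif along the sequence (and along its reverse complement
#' when both strands are scanned) and returns the best windowed sum of
#' log-odds. Ties are broken toward the smallest offset, forward strand
#' first.
#'
#' @param seq A single DNA string.
#' @param lodds A `"log_odds"` object from [build_log_odds()].
#' @param strands `"both"` or `"forward"`.
#' @return List with `score`, `offset` (0-based) and `strand` (`"+"`/`"-"`).
#' @export
best_match_score <- function(seq, lodds, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (nchar(seq) < lodds$length)
    stop("sequence shorter than motif '", lodds$motif_id, "'", call. = FALSE)
  S <- .encode_seqs(seq)
  fwd <- .scan_scores(S, lodds$lom)[1, ]
  off <- which.max(fwd)
  best <- list(score = fwd[off], offset = off - 1L, strand = "+")
  if (strands == "both") {
    rev <- .scan_scores(S, .revcomp_lom(lodds$lom))[1, ]
    roff <- which.max(rev)
    if (rev[roff] > best$score)
      best <- list(score = rev[roff], offset = roff - 1L, strand = "-")
  }
  best
}

#' Scan every motif against every peak sequence
#'
#' Computes, for each (peak, motif) pair, the best sliding log-odds match
#' score with its offset and strand — the match map underlying feature
#' vectorization, presence calls and motif-position mapping.
#'
#' @param peak_seqs Data frame from [uniformize_peaks()] (columns `id`,
#'   `seq`, plus window coordinates), or a named character vector of
#'   equal-length sequences.
#' @param motifs List of [motif_model()] objects.
#' @param strands `"both"` (default; binding is strand-agnostic) or
#'   `"forward"`.
#' @return List of class `"match_map"`: matrices `score`, `offset`
#'   (0-based), `strand` (peaks x motifs), vectors `max_score` and
#'   `motif_len`, and the originating `peak_seqs`.
#' @export
scan_motifs <- function(peak_seqs, motifs, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (is.character(peak_seqs))
    peak_seqs <- data.frame(id = if (is.null(names(peak_seqs)))
      sprintf("seq%d", seq_along(peak_seqs)) else names(peak_seqs),
      seq = unname(peak_seqs), stringsAsFactors = FALSE)
  S <- .encode_seqs(peak_seqs$seq)
  n <- nrow(S)
  m <- length(motifs)
  ids <- vapply(motifs, function(x) x$id, character(1))
  score <- offset <- matrix(NA_real_, n, m,
                            dimnames = list(peak_seqs$id, ids))
  strand <- matrix("+", n, m, dimnames = list(peak_seqs$id, ids))
  max_score <- motif_len <- numeric(m)
  names(max_score) <- names(motif_len) <- ids
  for (j in seq_len(m)) {
    lo <- build_log_odds(motifs[[j]])
    max_score[j] <- lo$max_score
    motif_len[j] <- lo$length
    fwd <- .scan_scores(S, lo$lom)
    o <- max.col(fwd, ties.method = "first")
    s <- fwd[cbind(seq_len(n), o)]
    st <- rep("+", n)
    if (strands == "both") {
      rev <- .scan_scores(S, .revcomp_lom(lo$lom))
      ro <- max.col(rev, ties.method = "first")
      rs <- rev[cbind(seq_len(n), ro)]
      take <- rs > s
      s[take] <- rs[take]
      o[take] <- ro[take]
      st[take] <- "-"
    }
    score[, j] <- s
    offset[, j] <- o - 1L
    strand[, j] <- st
  }
  structure(list(score = score, offset = offset, strand = strand,
                 max_score = max_score, motif_len = motif_len,
                 strands = strands, peak_seqs = peak_seqs),
            class = "match_map")
}

#' Vectorize peaks in motif space
#'
#' The feature-construction step. For peak i and motif j the raw feature is
#' `raw[i, j] = best_match(i, j) - max_score(j)`, which is always `<= 0`
#' and equals 0 exactly when the peak contains a perfect-consensus match.
#' Each raw row is then shifted by subtracting its minimum (so entries are
#' nonnegative, the best-matching motif of a peak carrying the row maximum)
#' and divided by its Euclidean norm. The response `y` is the natural log
#' of the peak enrichment score.
#'
#' @param peak_seqs Data frame from [uniformize_peaks()] with a `score`
#'   column (omit scores by passing `score = NULL` rows as NA only if `y`
#'   is not needed downstream).
#' @param motifs List of [motif_model()] objects (at least 2; a single
#'   motif makes every shifted row identically zero).
#' @param strands Passed to [scan_motifs()].
#' @return List of class `"feature_matrix"`: `V` (normalized features,
#'   peaks x motifs), `raw`, `y` (NULL when scores are absent), and the
#'   underlying `match` map.
#' @export
vectorize_peaks <- function(peak_seqs, motifs, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (length(motifs) < 2)
    stop("vectorization needs at least 2 motifs: with a single motif every ",
         "shifted feature row is identically zero", call. = FALSE)
  mm <- scan_motifs(peak_seqs, motifs, strands)
  raw <- sweep(mm$score, 2, mm$max_score, "-")
  shifted <- raw - apply(raw, 1, min)
  norms <- sqrt(rowSums(shifted^2))
  if (any(norms == 0))
    stop("peak(s) with an all-zero shifted feature row (all motifs match ",
         "equally well): ", paste(utils::head(
           rownames(raw)[norms == 0], 5), collapse = ", "), call. = FALSE)
  V <- shifted / norms
  y <- NULL
  if (!is.null(mm$peak_seqs$score) && !all(is.na(mm$peak_seqs$score))) {
    if (any(mm$peak_seqs$score <= 0, na.rm = TRUE) ||
        any(is.na(mm$peak_seqs$score)))
      stop("peak scores must be positive (their natural log is the ",
           "regression target)", call. = FALSE)
    y <- log(mm$peak_seqs$score)
    names(y) <- mm$peak_seqs$id
  }
  structure(list(V = V, raw = raw, y = y, match = mm,
                 peak_ids = rownames(V), motif_ids = colnames(V)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$V), "peaks x", ncol(x$V), "motifs",
      if (is.null(x$y)) "(no response)" else "(with log-score response)",
      "\n")
  invisible(x)
}

#' Binary motif-presence calls
#'
#' A motif is called present in a peak when its best match score reaches a
#' fraction `alpha` of the motif's maximum achievable score. A motif with
#' `max_score` 0 (indistinguishable from background) is present everywhere.
#'
#' @param x A `"match_map"` or `"feature_matrix"`.
#' @param alpha Presence threshold in (0, 1] (default 0.8).
#' @return Binary integer matrix, peaks x motifs.
#' @export
presence_calls <- function(x, alpha = 0.8) {
  if (inherits(x, "feature_matrix")) x <- x$match
  stopifnot(inherits(x, "match_map"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  thr <- alpha * x$max_score
  B <- (sweep(x$score, 2, thr, ">=")) * 1L
  storage.mode(B) <- "integer"
  B
}

# All qualifying match offsets (score >= alpha * max_score) for the given
# motifs, per peak, over the requested strands. Internal engine shared by
# motif_positions() and match counting.
.all_matches <- function(peak_seqs, motifs, motif_ids = NULL, alpha = 0.8,
                         strands = c("both", "forward")) {
  strands <- match.arg(strands)
  ids <- vapply(motifs, function(x) x$id, character(1))
  if (is.null(motif_ids)) motif_ids <- ids
  missing <- setdiff(motif_ids, ids)
  if (length(missing))
    stop("motif id(s) absent from the motif set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  S <- .encode_seqs(peak_seqs$seq)
  n <- nrow(S)
  out <- vector("list", length(motif_ids))
  names(out) <- motif_ids
  for (id in motif_ids) {
    lo <- build_log_odds(motifs[[match(id, ids)]])
    thr <- alpha * lo$max_score
    sc <- .scan_scores(S, lo$lom)
    hit <- sc >= thr
    if (strands == "both") {
      rc <- .scan_scores(S, .revcomp_lom(lo$lom))
      hit <- hit | (rc >= thr)
    }
    idx <- which(hit, arr.ind = TRUE)
    out[[id]] <- list(peak = idx[, 1], offset = idx[, 2] - 1L,
                      length = lo$length)
  }
  out
}
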