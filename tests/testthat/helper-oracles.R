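# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the package's vectorized scanning / solver
# code paths: plain loops, closed forms, and log-space sums.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(len, prob = rep(0.25, 4)) {
  paste(sample(BASES, len, replace = TRUE, prob = prob), collapse = "")
}

# Random informative motif: one high-probability consensus letter per
# position, rest spread evenly. Per-position consensus probabilities are
# heterogeneous so that mismatch costs differ across positions and motifs
# (avoids widespread exact score ties between unrelated motifs).
rand_motif <- function(id, L = 6, consensus_prob = NULL, pseudocount = 0.01) {
  if (is.null(consensus_prob))
    consensus_prob <- runif(L, 0.6, 0.95)
  cons <- sample.int(4, L, replace = TRUE)
  probs <- matrix((1 - consensus_prob) / 3, L, 4)
  probs[cbind(seq_len(L), cons)] <- consensus_prob
  motif_model(id, probs, pseudocount = pseudocount)
}

# A motif whose consensus is an exact DNA string with probability 1.
consensus_motif <- function(id, consensus, pseudocount = 0) {
  L <- nchar(consensus)
  probs <- matrix(0, L, 4)
  probs[cbind(seq_len(L), match(strsplit(consensus, NULL)[[1]], BASES))] <- 1
  motif_model(id, probs, pseudocount = pseudocount)
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), NULL)[[1]]), collapse = "")
}

# Character-by-character log-odds of one motif (same smoothing formula,
# applied independently).
oracle_lom <- function(motif) {
  pc <- motif$pseudocount
  log2(((motif$probs + pc) / (1 + 4 * pc)) /
         matrix(motif$background, nrow(motif$probs), 4, byrow = TRUE))
}

# Exhaustive enumeration over offsets and strands of the best match score.
oracle_best_match <- function(seq, motif, strands = "both") {
  lom <- oracle_lom(motif)
  L <- nrow(lom)
  score_one <- function(s) {
    ch <- strsplit(s, NULL)[[1]]
    best <- -Inf
    for (o in 0:(nchar(s) - L)) {
      sc <- 0
      for (p in 1:L) {
        a <- match(ch[o + p], BASES)
        sc <- sc + if (is.na(a)) 0 else lom[p, a]
      }
      best <- max(best, sc)
    }
    best
  }
  best <- score_one(seq)
  if (strands == "both") best <- max(best, score_one(revcomp_str(seq)))
  best
}

# Naive triple-loop reimplementation of the full vectorization recipe.
oracle_vectorize <- function(seqs, motifs, strands = "both") {
  n <- length(seqs)
  m <- length(motifs)
  raw <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      lom <- oracle_lom(motifs[[j]])
      raw[i, j] <- oracle_best_match(seqs[i], motifs[[j]], strands) -
        sum(apply(lom, 1, max))
    }
  }
  V <- raw
  for (i in seq_len(n)) {
    sh <- raw[i, ] - min(raw[i, ])
    V[i, ] <- sh / sqrt(sum(sh^2))
  }
  list(raw = raw, V = V)
}

# Cyclic coordinate-descent solver for
#   sum((y - b - x w)^2) + lambda * sum(|w|)
# used as an independent cross-check of the lasso fits.
oracle_cd_lasso <- function(x, y, lambda, n_sweeps = 2000, tol = 1e-12) {
  p <- ncol(x)
  w <- rep(0, p)
  b <- mean(y)
  for (s in seq_len(n_sweeps)) {
    w_old <- w
    r <- y - b - drop(x %*% w)
    for (j in seq_len(p)) {
      r <- r + x[, j] * w[j]
      rho <- sum(x[, j] * r)
      xx <- sum(x[, j]^2)
      w[j] <- if (xx == 0) 0 else
        sign(rho) * max(0, abs(rho) - lambda / 2) / xx
      r <- r - x[, j] * w[j]
    }
    b <- b + mean(r)
    r <- y - b - drop(x %*% w)
    if (max(abs(w - w_old)) < tol) break
  }
  list(coef = w, intercept = b)
}

# Lower-tail hypergeometric probability as an explicit log-space
# combinatorial sum.
oracle_hyper_lower <- function(k, n, K, N) {
  i <- 0:k
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  exp(m) * sum(exp(lt - m))
}

# Tiny in-memory genome + peak-sequence frame for mapping tests.
toy_peak_seqs <- function(seqs, starts = NULL, chrom = "chr1",
                          scores = NULL) {
  W <- nchar(seqs[1])
  n <- length(seqs)
  if (is.null(starts)) starts <- (seq_len(n) - 1L) * W
  data.frame(id = sprintf("p%02d", seq_len(n)), chrom = chrom,
             win_start = as.integer(starts),
             win_end = as.integer(starts + W), seq = seqs,
             score = if (is.null(scores)) exp(seq_len(n)) else scores,
             qvalue = NA_real_, center = NA_integer_,
             stringsAsFactors = FALSE)
}

# Plant a consensus string into a background sequence at a given offset.
plant_in <- function(seq, consensus, offset) {
  paste0(substr(seq, 1, offset), consensus,
         substr(seq, offset + nchar(consensus) + 1, nchar(seq)))
}
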