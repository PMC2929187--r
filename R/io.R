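## Readers/writers for the external formats the pipeline touches:
## FASTA, peak tables, MEME minimal motif format, BED, and the pipeline's
## own tab-separated matrix outputs. All internal coordinates are 0-based
## half-open (BED convention).

#' Describe the column layout of a peak table
#'
#' Peak tables arrive as tab-separated files whose column layout varies
#' between peak callers. A dialect maps the fields the pipeline needs
#' (`chrom`, `start`, `end`, `score`, and optionally `qvalue` and `center`)
#' onto column names or 1-based column indices, and declares the coordinate
#' convention of the input.
#'
#' @param chrom,start,end,score Column name (character) or index (integer)
#'   of the mandatory fields.
#' @param qvalue,center Optional column name/index for the peak Q-value and
#'   the peak center position; `NULL` if the table lacks them.
#' @param one_based If `TRUE`, input coordinates are 1-based inclusive and
#'   are converted to 0-based half-open on read (and back on write).
#' @param header Does the file carry a header row?
#' @param sep Field separator.
#' @return A list of class `"peak_dialect"`.
#' @examples
#' peak_dialect(chrom = 1, start = 2, end = 3, score = 4, header = FALSE)
#' @export
peak_dialect <- function(chrom = "chrom", start = "start", end = "end",
                         score = "score", qvalue = NULL, center = NULL,
                         one_based = FALSE, header = TRUE, sep = "\t") {
  structure(list(chrom = chrom, start = start, end = end, score = score,
                 qvalue = qvalue, center = center, one_based = one_based,
                 header = header, sep = sep),
            class = "peak_dialect")
}

.dialect_col <- function(tab, key, field, row0 = 0L) {
  if (is.null(key)) return(NULL)
  if (is.character(key)) {
    if (!key %in% names(tab))
      stop("peak table is missing mandatory column '", key,
           "' (field '", field, "')", call. = FALSE)
    return(tab[[key]])
  }
  if (key > ncol(tab))
    stop("peak table has ", ncol(tab), " columns but field '", field,
         "' was mapped to column ", key, call. = FALSE)
  tab[[key]]
}

.parse_numeric <- function(x, field, header_offset) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "" & x != "NA" & x != ".")
  if (length(bad))
    stop("unparseable numeric value in column '", field, "' at row ",
         bad[1] + header_offset, ": '", x[bad[1]], "'", call. = FALSE)
  out
}

#' Read a peak table
#'
#' Reads a tab-separated table of ChIP-Seq peaks into a data frame of peak
#' records with 0-based half-open coordinates. Rows with a nonpositive
#' enrichment score are dropped (their count is reported with a message),
#' since the log of the score is later used as the regression target.
#'
#' @param path Path to the table.
#' @param dialect A [peak_dialect()] describing the column layout.
#' @return A data frame with columns `chrom`, `start`, `end`, `score`,
#'   `qvalue` (NA when absent), `center` (NA when absent) and `id`. Peak ids
#'   are taken as `chrom:start-end` when the table provides none. The number
#'   of dropped rows is attached as attribute `"n_dropped"`.
#' @export
read_peak_table <- function(path, dialect = peak_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.table(path, sep = dialect$sep, header = dialect$header,
                    stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE, comment.char = "")
  off <- if (dialect$header) 1L else 0L
  chrom <- as.character(.dialect_col(tab, dialect$chrom, "chrom"))
  start <- .parse_numeric(.dialect_col(tab, dialect$start, "start"), "start", off)
  end   <- .parse_numeric(.dialect_col(tab, dialect$end, "end"), "end", off)
  score <- .parse_numeric(.dialect_col(tab, dialect$score, "score"), "score", off)
  qv <- .dialect_col(tab, dialect$qvalue, "qvalue")
  qvalue <- if (is.null(qv)) rep(NA_real_, nrow(tab)) else .parse_numeric(qv, "qvalue", off)
  ct <- .dialect_col(tab, dialect$center, "center")
  center <- if (is.null(ct)) rep(NA_real_, nrow(tab)) else .parse_numeric(ct, "center", off)
  if (dialect$one_based) {
    start <- start - 1
    center <- center - 1
  }
  if (any(start >= end))
    stop("peak with start >= end at row ", which(start >= end)[1] + off, call. = FALSE)
  bad_q <- !is.na(qvalue) & (qvalue < 0 | qvalue > 1)
  if (any(bad_q))
    stop("Q-value outside [0, 1] at row ", which(bad_q)[1] + off, call. = FALSE)
  keep <- score > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_peak_table: dropped ", n_dropped,
            " peak(s) with nonpositive score")
  peaks <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end), score = score,
                      qvalue = qvalue, center = as.integer(center),
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  peaks$id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  rownames(peaks) <- NULL
  attr(peaks, "n_dropped") <- n_dropped
  peaks
}

#' Write a peak table
#'
#' Inverse of [read_peak_table()] for the pipeline's own outputs; writes
#' `chrom`, `start`, `end`, `score`, `qvalue`, `center`, `id` with a header,
#' converting back to 1-based inclusive coordinates when the dialect asks
#' for them.
#'
#' @param peaks Data frame as returned by [read_peak_table()].
#' @param path Output path.
#' @param one_based Write 1-based inclusive coordinates?
#' @export
write_peak_table <- function(peaks, path, one_based = FALSE) {
  out <- peaks[, intersect(c("chrom", "start", "end", "score", "qvalue",
                             "center", "id"), names(peaks)), drop = FALSE]
  if (one_based) {
    out$start <- out$start + 1L
    if ("center" %in% names(out)) out$center <- out$center + 1L
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a (multi-)FASTA file
#'
#' @param path Path to a FASTA file of DNA sequences.
#' @return A named character vector of upper-case sequences. Only the
#'   letters A, C, G, T and N are accepted; any other letter raises an
#'   error naming the offending records.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  x <- toupper(as.character(ss))
  names(x) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("non-DNA letters (other than N) in FASTA record(s): ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  x
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a BED3 file
#'
#' @param path Path to a tab-separated BED file (first three columns used).
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, as BED defines them).
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0) || any(out$start >= out$end))
    stop("malformed BED interval (need 0 <= start < end)", call. = FALSE)
  out
}

#' Read SNP positions from BED
#'
#' Expands each BED interval into its individual base positions and
#' deduplicates, yielding a set of (chrom, position) pairs. dbSNP-style
#' single-base records are the expected input.
#'
#' @param path Path to a BED file of SNP positions.
#' @return Data frame with columns `chrom`, `pos` (0-based), no duplicates.
#' @export
read_snps <- function(path) {
  bed <- read_bed(path)
  n <- bed$end - bed$start
  out <- data.frame(chrom = rep(bed$chrom, n),
                    pos = unlist(lapply(seq_len(nrow(bed)), function(i)
                      seq.int(bed$start[i], bed$end[i] - 1L))),
                    stringsAsFactors = FALSE)
  unique(out)
}

## ---- MEME minimal motif format ----

#' Construct a motif model
#'
#' A motif model is a letter-probability matrix over {A, C, G, T} plus a
#' background composition, i.e. a PSSM in probability form from which
#' log-odds scores are derived.
#'
#' @param id Motif identifier.
#' @param probs L x 4 numeric matrix of per-position letter probabilities;
#'   columns in A, C, G, T order. Each row must sum to 1 (tolerance 1e-6).
#' @param background Length-4 background letter probabilities, summing to 1.
#' @param pseudocount Nonnegative pseudocount used when forming log-odds.
#' @param source Free-text provenance tag (file name, cluster tag).
#' @return A list of class `"motif_model"`.
#' @export
motif_model <- function(id, probs, background = rep(0.25, 4),
                        pseudocount = 0.01, source = "") {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A, C, G, T)", call. = FALSE)
  if (nrow(probs) < 1) stop("motif must have at least one position", call. = FALSE)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("motif '", id, "': position probabilities must sum to 1", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-6)
    stop("background probabilities must sum to 1", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be nonnegative", call. = FALSE)
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(id = id, probs = probs, background = background,
                 pseudocount = pseudocount, source = source),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("Motif", x$id, "-", nrow(x$probs), "positions\n")
  cat("Consensus:", paste(c("A", "C", "G", "T")[max.col(x$probs)],
                          collapse = ""), "\n")
  invisible(x)
}

#' Read motifs in MEME minimal format
#'
#' Parses a MEME (minimal) motif file: one `MOTIF` block per motif, each
#' with a `letter-probability matrix:` header. The file-level background
#' letter frequencies are used when present, else a uniform background.
#' Matrix rows off from 1 by more than 1e-3 are rejected; smaller rounding
#' deviations are renormalized.
#'
#' @param path Path to the motif file.
#' @param pseudocount Pseudocount to attach to each parsed motif.
#' @return List of [motif_model()] objects, in file order.
#' @export
read_meme_motifs <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!length(lines) || !any(nzchar(lines)))
    stop("empty MEME motif file: ", path, call. = FALSE)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    i <- bg_at[1] + 1L
    toks <- character(0)
    while (i <= length(lines) && nzchar(lines[i]) &&
           !grepl("^MOTIF", lines[i])) {
      toks <- c(toks, strsplit(lines[i], "\\s+")[[1]])
      i <- i + 1L
    }
    vals <- suppressWarnings(as.numeric(toks))
    freq <- vals[!is.na(vals)]
    lets <- toupper(toks[is.na(suppressWarnings(as.numeric(toks)))])
    if (length(freq) >= 4 && all(c("A", "C", "G", "T") %in% lets)) {
      names(freq) <- lets[seq_along(freq)]
      background <- unname(freq[c("A", "C", "G", "T")])
    }
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at))
    stop("no MOTIF blocks found in ", path, call. = FALSE)
  motifs <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    id <- strsplit(lines[motif_at[k]], "\\s+")[[1]][2]
    lim <- if (k < length(motif_at)) motif_at[k + 1] - 1L else length(lines)
    block <- lines[motif_at[k]:lim]
    hdr <- grep("^letter-probability matrix:", block)
    if (!length(hdr))
      stop("motif '", id, "': missing letter-probability matrix", call. = FALSE)
    w <- suppressWarnings(as.integer(
      sub(".*\\bw=\\s*(\\d+).*", "\\1", block[hdr[1]])))
    rows <- block[(hdr[1] + 1):length(block)]
    rows <- rows[nzchar(rows) & grepl("^[0-9.eE+ \t-]+$", rows)]
    if (!is.na(w)) rows <- utils::head(rows, w)
    probs <- t(vapply(rows, function(r)
      as.numeric(strsplit(r, "\\s+")[[1]][1:4]), numeric(4)))
    rownames(probs) <- NULL
    if (any(is.na(probs)))
      stop("motif '", id, "': malformed probability row", call. = FALSE)
    rs <- rowSums(probs)
    if (any(abs(rs - 1) > 1e-3))
      stop("motif '", id, "': matrix row does not sum to 1 (row ",
           which(abs(rs - 1) > 1e-3)[1], ", sum ",
           format(rs[which(abs(rs - 1) > 1e-3)[1]]), ")", call. = FALSE)
    probs <- probs / rs
    motifs[[k]] <- motif_model(id, probs, background = background,
                               pseudocount = pseudocount, source = path)
  }
  motifs
}

#' Write motifs in MEME minimal format
#'
#' Inverse of [read_meme_motifs()]; probabilities are written with 8
#' decimals so a write/read round trip preserves them to 1e-6.
#'
#' @param motifs List of [motif_model()] objects.
#' @param path Output path.
#' @export
write_meme_motifs <- function(motifs, path) {
  if (!length(motifs)) stop("no motifs to write", call. = FALSE)
  bg <- motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(m$probs)), con)
    writeLines(apply(m$probs, 1, function(r)
      paste(sprintf("%.8f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write / read a numeric matrix as TSV with header row and column
#'
#' @param x Numeric matrix with row and column names.
#' @param path File path.
#' @return `read_matrix_tsv` returns the matrix with dimnames restored.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
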