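make_genome <- function(len = 5000, seed = 5) {
  set.seed(seed)
  c(chr1 = rand_dna(len))
}

test_that("uniformization produces the documented windows", {
  genome <- make_genome()
  # center mode: [center - W/2, center + W/2)
  pk <- data.frame(chrom = "chr1", start = 950L, end = 1050L, score = 10,
                   qvalue = NA_real_, center = 1000L, id = "p1")
  ps <- uniformize_peaks(pk, genome, width = 200, mode = "center")
  expect_equal(c(ps$win_start, ps$win_end), c(900L, 1100L))
  expect_equal(nchar(ps$seq), 200)
  expect_equal(ps$seq, substr(genome[["chr1"]], 901, 1100))

  # interval mode: symmetric enlargement, 75 bp per side
  pk$center <- NA_integer_
  pk$start <- 100L; pk$end <- 150L
  ps <- uniformize_peaks(pk, genome, width = 200, mode = "interval")
  expect_equal(c(ps$win_start, ps$win_end), c(25L, 225L))

  # symmetric trim of 400 bp per side
  pk$start <- 0L; pk$end <- 1000L
  ps <- uniformize_peaks(pk, genome, width = 200, mode = "interval")
  expect_equal(c(ps$win_start, ps$win_end), c(400L, 600L))

  # odd enlargement puts the extra base on the right
  pk$start <- 100L; pk$end <- 101L
  ps <- uniformize_peaks(pk, genome, width = 200, mode = "interval")
  expect_equal(ps$win_end - ps$win_start, 200L)
  expect_equal(100L - ps$win_start, 99L)   # 99 left, 100 right

  # boundary windows are shifted inward with a warning
  pk$start <- 0L; pk$end <- 10L
  expect_warning(ps <- uniformize_peaks(pk, genome, width = 200,
                                        mode = "interval"), "inward")
  expect_equal(c(ps$win_start, ps$win_end), c(0L, 200L))

  # center mode requires centers; unknown chromosome errors
  expect_error(uniformize_peaks(pk, genome, mode = "center"), "center")
  pk$chrom <- "chrX"
  expect_error(uniformize_peaks(pk, genome, mode = "interval"), "chrX")
})

test_that("every emitted sequence has exactly the requested width", {
  genome <- make_genome(len = 20000, seed = 6)
  set.seed(7)
  n <- 300
  len <- sample.int(4000, n, replace = TRUE)
  start <- sample.int(19000, n, replace = TRUE) - 1L
  pk <- data.frame(chrom = "chr1", start = start,
                   end = pmin(start + len, 20000L), score = runif(n) + 1,
                   qvalue = NA_real_, center = NA_integer_,
                   id = sprintf("p%03d", seq_len(n)))
  pk <- pk[pk$start < pk$end, ]
  ps <- suppressWarnings(uniformize_peaks(pk, genome, width = 200,
                                          mode = "interval"))
  expect_true(all(nchar(ps$seq) == 200))
  expect_true(all(ps$win_end - ps$win_start == 200))
  expect_true(all(ps$win_start >= 0 & ps$win_end <= 20000))
})

test_that("peak filtering modes behave and are monotone in qmax", {
  pk <- data.frame(chrom = "chr1", start = c(100L, 300L, 500L, 700L, 900L),
                   end = c(300L, 500L, 700L, 900L, 1100L),
                   score = 1:5, qvalue = c(0.01, 0.2, 0.04, 0.5, 0.05),
                   center = NA_integer_, id = paste0("p", 1:5))
  expect_identical(filter_peaks(pk, "none"), pk)
  kept <- filter_peaks(pk, "qvalue", qmax = 0.05)
  expect_equal(nrow(kept), 3)
  expect_equal(kept$id, c("p1", "p3", "p5"))
  # monotone: survivors at a smaller qmax are a subset
  for (q1 in c(0.01, 0.04, 0.2)) {
    k1 <- filter_peaks(pk, "qvalue", qmax = q1)$id
    k2 <- filter_peaks(pk, "qvalue", qmax = q1 + 0.1)$id
    expect_true(all(k1 %in% k2))
  }
  pk$qvalue[2] <- NA
  expect_error(filter_peaks(pk, "qvalue"), "p2")

  # promoter proximity: overlap with [tss - flank, tss + flank)
  pk2 <- data.frame(chrom = "chr1", start = c(100L, 5000L),
                    end = c(300L, 5200L), score = c(1, 2),
                    qvalue = NA_real_, center = NA_integer_,
                    id = c("near", "far"))
  tss <- data.frame(chrom = "chr1", start = 2000L, end = 2001L)
  kept <- filter_peaks(pk2, "promoter", tss = tss, flank = 2000)
  expect_equal(kept$id, "near")
  expect_error(filter_peaks(pk2, "promoter"), "TSS")
})

test_that("score clustering chunks ascending scores with the remainder rule", {
  set.seed(8)
  mk <- function(n) toy_peak_seqs(replicate(n, rand_dna(20)),
                                  scores = sample(n) + runif(n))
  cl <- cluster_by_score(mk(6), group_size = 2)
  expect_length(cl, 3)
  expect_equal(vapply(cl, nrow, integer(1)), rep(2L, 3))

  # 450 peaks, G = 200: remainder 50 < G/2 merges into the previous cluster
  cl <- cluster_by_score(mk(450), group_size = 200)
  expect_equal(vapply(cl, nrow, integer(1)), c(200L, 250L))
  # 300 peaks: remainder 100 >= G/2 kept
  cl <- cluster_by_score(mk(300), group_size = 200)
  expect_equal(vapply(cl, nrow, integer(1)), c(200L, 100L))
  # exactly one full group
  cl <- cluster_by_score(mk(200), group_size = 200)
  expect_length(cl, 1)

  # multiset preserved and scores globally non-decreasing
  ps <- mk(450)
  cl <- cluster_by_score(ps, group_size = 200)
  all_scores <- unlist(lapply(cl, `[[`, "score"))
  expect_equal(sort(all_scores), sort(ps$score))
  expect_true(!is.unsorted(all_scores))

  expect_length(cluster_by_score(ps[0, ], 200), 0)
})

test_that("cluster FASTA export round-trips and writes a manifest", {
  set.seed(9)
  ps <- toy_peak_seqs(replicate(6, rand_dna(30)), scores = 1:6)
  cl <- cluster_by_score(ps, group_size = 3)
  outdir <- withr::local_tempdir()
  paths <- export_cluster_fastas(cl, outdir)
  expect_length(paths, 2)
  back <- read_fasta(paths[1])
  expect_equal(unname(back), cl[[1]]$seq)
  expect_equal(names(back), cl[[1]]$id)
  manifest <- read.table(file.path(outdir, "manifest.tsv"), header = TRUE,
                         sep = "\t")
  expect_equal(manifest$rank, 1:2)
  expect_equal(manifest$n_peaks, c(3L, 3L))
})
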