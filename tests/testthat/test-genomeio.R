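test_that("FASTA reading normalizes case and maps non-ACGT to N", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 description", "acgT", ">s2", "AC-GT", "NNRA"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2L)
  expect_equal(seqs[[1]]$name, "s1")
  expect_equal(seqs[[1]]$seq, "ACGT")
  expect_equal(seqs[[1]]$length, 4L)
  expect_equal(seqs[[2]]$seq, "ACNGTNNNA")
  expect_equal(names(seqs), c("s1", "s2"))
})

test_that("FASTA errors on empty input and round-trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|malformed")
  g <- genome_sequence("chrT", strrep("ACGTN", 30L))
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, out, width = 13L)
  back <- read_fasta(out)
  expect_equal(back[[1]]$seq, g$seq)
})

test_that("BED round trip is the identity and bad lines are rejected", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t5\t10", f)
  iv <- read_bed(f)
  expect_equal(iv$start, 5L)
  expect_equal(iv$end, 10L)

  set.seed(7)
  n <- 100L
  st <- sample.int(1e6, n)
  df <- intervals(sample(c("chr1", "chr2"), n, TRUE), st,
                  st + sample.int(500, n))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(df, out)
  back <- read_bed(out)
  sorted <- df[order(df$chrom, df$start, df$end), ]
  rownames(sorted) <- NULL
  expect_equal(back, sorted)

  writeLines("chr1\t10\t10", f)
  expect_error(read_bed(f), "line 1")
  expect_error(intervals("chr1", 10, 10), "start < end")
})

test_that("interval/track conversion round-trips on merged sets", {
  expect_equal(track_from_intervals(intervals("c", 2, 5), 8L),
               c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(track_from_intervals(intervals(c("c", "c"), c(2, 4), c(5, 7)), 8L),
               c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 0L))
  expect_equal(track_from_intervals(empty_intervals(), 5L), rep(0L, 5))
  expect_error(track_from_intervals(intervals("c", 2, 9), 8L), "out of bounds")

  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:10, 1)
    st <- sort(sample.int(200, n))
    df <- intervals(rep("chr1", n), st, st + sample.int(30, n, TRUE))
    merged <- interval_ops(df, df, "merge")
    tr <- track_from_intervals(merged, 300L)
    expect_equal(intervals_from_track(tr, "chr1"), merged)
  }
})

test_that("interval set operations and coverage match per-base brute force", {
  rand_set <- function(n) {
    st <- sample.int(150, n)
    intervals(rep("chr1", n), st, st + sample.int(40, n, TRUE))
  }
  set.seed(11)
  for (i in 1:50) {
    a <- rand_set(sample(1:8, 1))
    b <- rand_set(sample(1:8, 1))
    L <- 250L
    ta <- track_from_intervals(a, L) == 1L
    tb <- track_from_intervals(b, L) == 1L
    inter <- interval_ops(a, b, "intersect")
    expect_equal(track_from_intervals(inter, L) == 1L, ta & tb)
    sub <- interval_ops(a, b, "subtract")
    expect_equal(track_from_intervals(sub, L) == 1L, ta & !tb)
    mer <- interval_ops(a, b, "merge")
    expect_equal(track_from_intervals(mer, L) == 1L, ta | tb)
    expect_equal(coverage_fraction(a, b), sum(ta & tb) / sum(ta))
  }
})

test_that("coverage handles containment and disjoint chromosomes", {
  a <- intervals("chr1", 0, 10)
  b <- intervals("chr1", 5, 15)
  expect_equal(interval_ops(a, b, "intersect"),
               data.frame(chrom = "chr1", start = 5L, end = 10L))
  expect_equal(coverage_fraction(a, b), 0.5)
  expect_equal(coverage_fraction(intervals("chr1", 3, 7), a), 1.0)
  expect_warning(cf <- coverage_fraction(a, intervals("chrX", 0, 100)),
                 "zero overlap")
  expect_equal(cf, 0)
})

test_that("overlap_counts reports both segment- and bp-level numbers", {
  a <- intervals(rep("chr1", 3), c(0, 20, 40), c(10, 30, 50))
  b <- intervals("chr1", 25, 45)
  oc <- overlap_counts(a, b)
  expect_equal(oc$segments_overlapping, 2L)
  expect_equal(oc$segments_total, 3L)
  expect_equal(oc$bp_overlap, 10L)
  expect_equal(oc$bp_total, 30L)
})

test_that("bedGraph output collapses runs", {
  f <- withr::local_tempfile(fileext = ".bg")
  write_bedgraph(c(0, 0, 1.5, 1.5, 0.25), "chr9", f)
  got <- read.table(f, sep = "\t")
  expect_equal(got$V2, c(0L, 2L, 4L))
  expect_equal(got$V3, c(2L, 4L, 5L))
  expect_equal(got$V4, c(0, 1.5, 0.25))
})
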