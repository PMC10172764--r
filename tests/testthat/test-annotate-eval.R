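test_that("confusion metrics match the closed forms and brute force", {
  # constructed counts: recall .89, precision ~.781, F1 ~.832
  pred <- c(rep(1, 89), rep(0, 11), rep(1, 25), rep(0, 875))
  truth <- c(rep(1L, 100), rep(0L, 900))
  cm <- confusion_metrics(pred, truth)
  expect_equal(unname(cm$counts), c(89L, 25L, 11L, 875L))
  expect_equal(cm$recall, 0.89)
  expect_equal(cm$precision, 89 / 114, tolerance = 1e-12)
  expect_equal(cm$f1, 2 * (89 / 114) * 0.89 / ((89 / 114) + 0.89))

  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  set.seed(17)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    p <- runif(n)
    y <- rbinom(n, 1, 0.3)
    th <- runif(1)
    cm <- confusion_metrics(p, y, th)
    tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
    for (j in seq_len(n)) {
      if (p[j] >= th && y[j] == 1) tp <- tp + 1L
      else if (p[j] >= th) fp <- fp + 1L
      else if (y[j] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_equal(unname(cm$counts), c(tp, fp, fn, tn))
  }
  expect_true(is.na(confusion_metrics(rep(0, 5), rep(0L, 5))$precision))
})

test_that("rank-based AUC matches trapezoidal integration and pROC", {
  expect_equal(roc_auc(c(.1, .2, .8, .9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 100), rbinom(100, 1, .5)), 0.5)
  trap_auc <- function(s, y) {
    ths <- sort(unique(c(-Inf, s, Inf)), decreasing = TRUE)
    tpr <- sapply(ths, function(t) sum(s >= t & y == 1) / sum(y == 1))
    fpr <- sapply(ths, function(t) sum(s >= t & y == 0) / sum(y == 0))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(23)
  for (i in 1:30) {
    n <- sample(20:100, 1)
    s <- round(runif(n), 2)   # force ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(roc_auc(s, y), trap_auc(s, y), tolerance = 1e-12)
    pr <- pROC::roc(response = y, predictor = s, levels = c(0, 1),
                    direction = "<", quiet = TRUE)
    expect_equal(roc_auc(s, y), as.numeric(pr$auc), tolerance = 1e-12)
  }
})

make_annot <- function() {
  # one + strand gene at [10000, 12000), one - strand gene at [20000, 22000)
  genes <- intervals(c("chr1", "chr1"), c(10000, 20000), c(12000, 22000),
                     strand = c("+", "-"))
  tss <- data.frame(chrom = "chr1", pos = c(10000L, 21999L),
                    strand = c("+", "-"))
  exons <- intervals(rep("chr1", 4), c(10000, 11500, 20000, 21500),
                     c(10300, 11800, 20300, 21800))
  utr5 <- intervals(c("chr1", "chr1"), c(10000, 21900), c(10100, 22000))
  utr3 <- intervals(c("chr1", "chr1"), c(11900, 20000), c(12000, 20100))
  feature_annotation(tss, genes, exons, utr5, utr3)
}

test_that("feature classification follows the precedence order", {
  an <- make_annot()
  expect_equal(classify_feature("chr1", 9400, 9600, an), "Promoter")
  expect_equal(classify_feature("chr1", 7100, 7200, an), "Promoter")
  expect_equal(classify_feature("chr1", 22100, 22200, an), "Promoter")  # - strand
  expect_equal(classify_feature("chr1", 10020, 10060, an), "5'UTR")
  expect_equal(classify_feature("chr1", 11550, 11650, an), "Exon")
  expect_equal(classify_feature("chr1", 11000, 11100, an), "Intron")
  expect_equal(classify_feature("chr1", 11920, 11960, an), "3'UTR")
  expect_equal(classify_feature("chr1", 12100, 12200, an), "Downstream")
  expect_equal(classify_feature("chr1", 50000, 50100, an), "DistalIntergenic")
  expect_warning(cls <- classify_feature("chrUn", 100, 200, an),
                 "not annotated")
  expect_equal(cls, "DistalIntergenic")
  # every interval lands in exactly one of the seven classes
  set.seed(3)
  for (i in 1:50) {
    s <- sample.int(60000, 1)
    cl <- classify_feature("chr1", s, s + 50, an)
    expect_true(cl %in% feature_classes())
  }
})

test_that("overlap recovery reproduces printed-table percentages", {
  # segment-level >= 1 bp intersection semantics
  expect_equal(contingency_ratio(26751, 26751 + 2040, digits = 2), 92.91)
  expect_equal(contingency_ratio(1650, 1650 + 81, digits = 2), 95.32)
  exp_ <- intervals(rep("chr1", 4), c(0, 100, 200, 300),
                    c(50, 150, 250, 350))
  prd <- intervals(rep("chr1", 2), c(40, 205), c(60, 215))
  out <- overlap_recovery(exp_, prd)
  expect_equal(out$shared, 2L)
  expect_equal(out$experimental_only, 2L)
  expect_equal(out$percent, 50)
  # containment -> 100%
  all_in <- overlap_recovery(intervals("chr1", 10, 20),
                             intervals("chr1", 0, 100))
  expect_equal(all_in$percent, 100)
})

test_that("enrichment tables conserve 100% and difference columns", {
  et <- enrichment_table(c(A = 50, B = 50), c(A = 10, B = 90))
  expect_equal(et$observed_pct, c(50, 50))
  expect_equal(et$expected_pct, c(10, 90))
  expect_equal(et$difference, c(40, -40))
  expect_equal(sum(et$observed_pct), 100)
  expect_equal(sum(et$expected_pct), 100)
  same <- enrichment_table(c(A = 30, B = 70), c(A = 300, B = 700))
  expect_equal(same$difference, c(0, 0))
})

test_that("repeat score summaries equal brute-force aggregation", {
  vals <- c(rep(2, 10), rep(4, 10), seq(0, 1, length.out = 20))
  reps <- intervals(rep("chr1", 3), c(0, 10, 20), c(10, 20, 40),
                    name = c("(CG)n", "(CG)n", "(CA)n"))
  rs <- repeat_scores(vals, reps)
  cg <- rs[rs$family == "(CG)n", ]
  expect_equal(cg$bases_in_repeats, 20L)
  expect_equal(cg$mean_base_score, 3)
  expect_equal(cg$max_base_score, 4)
  ca <- rs[rs$family == "(CA)n", ]
  expect_equal(ca$mean_base_score, mean(seq(0, 1, length.out = 20)))
  expect_true(all(rs$max_base_score >= rs$mean_base_score))
  set.seed(31)
  for (i in 1:20) {
    v <- runif(500)
    st <- sample.int(450, 5)
    rp <- intervals(rep("chr1", 5), st, st + sample.int(40, 5, TRUE),
                    name = sample(c("f1", "f2"), 5, TRUE))
    rs <- repeat_scores(v, rp)
    for (fam in rs$family) {
      idx <- unique(unlist(lapply(which(rp$name == fam), function(j)
        (rp$start[j] + 1):rp$end[j])))
      expect_equal(rs$mean_base_score[rs$family == fam], mean(v[idx]))
      expect_equal(rs$max_base_score[rs$family == fam], max(v[idx]))
    }
  }
  expect_warning(repeat_scores(vals, intervals("chr1", 100, 110,
                                               name = "ghost")),
                 "no scored bases")
})

test_that("junction windows are 11 nt, clipped at edges, count-conserving", {
  g <- genome_sequence("c", random_dna(200))
  segs <- intervals(rep("c", 3), c(100, 2, 150), c(120, 14, 197))
  expect_warning(jw <- junction_windows(segs, g), "clipped")
  # segment (100,120): start window [95,106), end window [114,125)
  w1 <- jw[jw$start == 95, ]
  expect_equal(w1$end, 106L)
  expect_equal(w1$side, "start")
  expect_equal(w1$seq, substr(g$seq, 96, 106))
  expect_equal(nchar(jw$seq), rep(11L, nrow(jw)))
  # 3 segments -> 6 windows minus 2 dropped (start at 2, end at 197)
  expect_equal(nrow(jw), 4L)
  fa <- withr::local_tempfile(fileext = ".fa")
  suppressWarnings(junction_windows(segs, g, fasta = fa))
  expect_equal(sum(startsWith(readLines(fa), ">")), 4L)
})

test_that("haplotype scores add trait directions and are antisymmetric", {
  expect_equal(haplotype_score(c(1L, 1L, -1L, 0L)), 1L)
  expect_equal(haplotype_score(rep(0L, 6)), 0L)
  set.seed(41)
  for (i in 1:50) {
    d <- sample(c(-1L, 0L, 1L), sample(1:10, 1), replace = TRUE)
    expect_equal(haplotype_score(-d), -haplotype_score(d))
    expect_lte(abs(haplotype_score(d)), length(d))
  }
  expect_error(haplotype_score(c(1L, 2L)))
})

test_that("contingency ratios reproduce printed values at printed precision", {
  expect_equal(contingency_ratio(655, 108517), 0.6)
  expect_equal(contingency_ratio(1093, 1160), 94.2)
  expect_equal(contingency_ratio(0, 100), 0)
  # half-up rounding, and agreement with plain division before rounding
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.125, 2), 0.13)
  set.seed(43)
  for (i in 1:100) {
    n <- sample.int(1e5, 1); d <- n + sample.int(1e5, 1)
    expect_equal(contingency_ratio(n, d, digits = 6),
                 round_half_up(100 * n / d, 6), tolerance = 1e-12)
  }
})
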