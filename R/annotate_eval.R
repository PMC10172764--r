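#' Nucleotide-level confusion counts and metrics
#'
#' @param pred A `prediction_track` or probability vector.
#' @param truth Per-nucleotide 0/1 vector.
#' @param threshold Probability threshold for calling a base Z.
#' @return List with `counts` (TP, FP, FN, TN) and `precision`, `recall`,
#'   `f1` (harmonic mean of precision and recall). A metric whose
#'   denominator is zero is `NA`.
#' @export
confusion_metrics <- function(pred, truth, threshold = 0.5) {
  p <- if (inherits(pred, "prediction_track")) pred$p else as.numeric(pred)
  stopifnot(length(p) == length(truth))
  call <- p >= threshold
  y <- truth == 1L
  tp <- sum(call & y); fp <- sum(call & !y)
  fn <- sum(!call & y); tn <- sum(!call & !y)
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
       precision = prec, recall = rec, f1 = f1)
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' Ties receive midranks, so tied scores contribute 1/2.
#'
#' @param pred A `prediction_track` or score vector.
#' @param truth Per-element 0/1 vector.
#' @return AUC in `[0, 1]`; `NA` when one class is absent.
#' @export
roc_auc <- function(pred, truth) {
  s <- if (inherits(pred, "prediction_track")) pred$p else as.numeric(pred)
  stopifnot(length(s) == length(truth))
  y <- truth == 1L
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(s)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Gene-model annotation for feature classification
#'
#' @param tss Data frame with `chrom`, `pos` (0-based TSS) and `strand`.
#' @param genes Interval data frame of gene bodies (with `strand`).
#' @param exons,utr5,utr3 Interval data frames.
#' @param promoter_bp Promoter window upstream of the TSS (default 3000).
#' @param downstream_bp Downstream window past the gene end (default 300).
#' @return An object of class `feature_annotation`.
#' @export
feature_annotation <- function(tss, genes, exons,
                               utr5 = NULL, utr3 = NULL,
                               promoter_bp = 3000L, downstream_bp = 300L) {
  stopifnot(promoter_bp > 0L, downstream_bp > 0L,
            all(c("chrom", "pos", "strand") %in% names(tss)))
  structure(list(tss = tss, genes = genes, exons = exons,
                 utr5 = if (is.null(utr5)) empty_intervals() else utr5,
                 utr3 = if (is.null(utr3)) empty_intervals() else utr3,
                 promoter_bp = as.integer(promoter_bp),
                 downstream_bp = as.integer(downstream_bp)),
            class = "feature_annotation")
}

#' The seven genomic feature classes
#' @return Character vector of class labels, in precedence order.
#' @export
feature_classes <- function() {
  c("Promoter", "5'UTR", "Exon", "Intron", "3'UTR", "Downstream",
    "DistalIntergenic")
}

.point_in <- function(chrom, pos, df) {
  any(df$chrom == chrom & df$start <= pos & pos < df$end)
}

#' Classify an interval into a genomic feature class
#'
#' The interval midpoint is assigned to exactly one of the seven classes
#' with precedence Promoter > 5'UTR > Exon > Intron > 3'UTR > Downstream >
#' DistalIntergenic. The promoter window spans `promoter_bp` upstream of a
#' TSS (strand-aware); the downstream window spans `downstream_bp` past the
#' gene end.
#'
#' @param chrom,start,end The interval (0-based half-open).
#' @param annot A [feature_annotation()].
#' @return One class label (see [feature_classes()]).
#' @export
classify_feature <- function(chrom, start, end, annot) {
  stopifnot(inherits(annot, "feature_annotation"))
  if (!chrom %in% c(annot$tss$chrom, annot$genes$chrom)) {
    warning("chromosome '", chrom, "' not annotated; DistalIntergenic")
    return("DistalIntergenic")
  }
  mid <- (start + end) %/% 2L
  tss <- annot$tss[annot$tss$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(tss))) {
    pr <- if (tss$strand[i] == "-")
      c(tss$pos[i] + 1L, tss$pos[i] + annot$promoter_bp + 1L)
    else c(tss$pos[i] - annot$promoter_bp, tss$pos[i])
    if (mid >= pr[1L] && mid < pr[2L]) return("Promoter")
  }
  if (.point_in(chrom, mid, annot$utr5)) return("5'UTR")
  if (.point_in(chrom, mid, annot$exons)) return("Exon")
  if (.point_in(chrom, mid, annot$genes)) {
    if (.point_in(chrom, mid, annot$utr3)) return("3'UTR")
    return("Intron")
  }
  if (.point_in(chrom, mid, annot$utr3)) return("3'UTR")
  g <- annot$genes[annot$genes$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    dw <- if (!is.null(g$strand) && g$strand[i] == "-")
      c(g$start[i] - annot$downstream_bp, g$start[i])
    else c(g$end[i], g$end[i] + annot$downstream_bp)
    if (mid >= dw[1L] && mid < dw[2L]) return("Downstream")
  }
  "DistalIntergenic"
}

#' Per-class recovery of experimental segments by predictions
#'
#' Segment-level counting: an experimental segment is "shared" iff it
#' intersects at least one predicted segment by >= 1 bp. The recovery
#' percentage per class is `100 * shared / (shared + experimental_only)`.
#'
#' @param experimental,predicted Interval data frames.
#' @param annot Optional [feature_annotation()]; when supplied the table is
#'   broken down by feature class of the experimental segment, otherwise a
#'   single `All` row is returned.
#' @param digits Decimals for the printed percentage (half-up rounding).
#' @return Data frame with `class`, `shared`, `experimental_only`,
#'   `percent`.
#' @export
overlap_recovery <- function(experimental, predicted, annot = NULL,
                             digits = 2L) {
  validate_intervals(experimental)
  validate_intervals(predicted)
  shared_flag <- logical(nrow(experimental))
  for (ch in unique(experimental$chrom)) {
    sel <- experimental$chrom == ch
    ia <- .as_iranges(experimental, ch)
    ib <- IRanges::reduce(.as_iranges(predicted, ch))
    shared_flag[sel] <- IRanges::countOverlaps(ia, ib) > 0L
  }
  cls <- if (is.null(annot)) rep("All", nrow(experimental))
  else vapply(seq_len(nrow(experimental)), function(i)
    classify_feature(experimental$chrom[i], experimental$start[i],
                     experimental$end[i], annot), character(1))
  lv <- if (is.null(annot)) "All" else feature_classes()
  out <- do.call(rbind, lapply(lv, function(cl) {
    sh <- sum(shared_flag & cls == cl)
    ex <- sum(!shared_flag & cls == cl)
    data.frame(class = cl, shared = sh, experimental_only = ex,
               percent = if (sh + ex > 0)
                 round_half_up(100 * sh / (sh + ex), digits) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Observed vs expected class composition
#'
#' @param hits Named counts per class (the foreground).
#' @param background Named counts per class (the genome-wide expectation);
#'   names must cover those of `hits`.
#' @return Data frame with `class`, `observed_pct`, `expected_pct`,
#'   `difference` (percentage points). Each percentage column sums to 100.
#' @export
enrichment_table <- function(hits, background) {
  classes <- union(names(hits), names(background))
  h <- setNames(rep(0, length(classes)), classes)
  h[names(hits)] <- hits
  b <- setNames(rep(0, length(classes)), classes)
  b[names(background)] <- background
  stopifnot(sum(h) > 0, sum(b) > 0)
  obs <- 100 * h / sum(h)
  exp_ <- 100 * b / sum(b)
  data.frame(class = classes, observed_pct = unname(obs),
             expected_pct = unname(exp_),
             difference = unname(obs - exp_), stringsAsFactors = FALSE)
}

#' Per-repeat-family base-score summary
#'
#' @param values Per-nucleotide score vector (e.g. `base_score` from
#'   [predict_track()]).
#' @param repeats Interval data frame with a `name` column giving the repeat
#'   family; all on the scored sequence.
#' @return Data frame with `family`, `bases_in_repeats`, `mean_base_score`,
#'   `max_base_score`, sorted by mean descending. Families with no covered
#'   bases are dropped with a warning.
#' @export
repeat_scores <- function(values, repeats) {
  validate_intervals(repeats)
  stopifnot(!is.null(repeats$name))
  fams <- unique(repeats$name)
  rows <- lapply(fams, function(fam) {
    r <- repeats[repeats$name == fam, , drop = FALSE]
    idx <- unlist(lapply(seq_len(nrow(r)), function(i)
      (r$start[i] + 1L):r$end[i]))
    idx <- unique(idx[idx >= 1L & idx <= length(values)])
    if (!length(idx)) {
      warning("repeat family '", fam, "' covers no scored bases; dropped")
      return(NULL)
    }
    data.frame(family = fam, bases_in_repeats = length(idx),
               mean_base_score = mean(values[idx]),
               max_base_score = max(values[idx]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(-out$mean_base_score), , drop = FALSE]
}

#' Extract B-Z junction windows around segment boundaries
#'
#' For each segment, two windows of `2 * flank + 1` nt: one centered on the
#' first base (start boundary), one on the last base (end boundary).
#' Windows running off the contig are dropped with a warning. The FASTA
#' headers record the convention: `<chrom>:<center0>:<side>`.
#'
#' @param segments Interval data frame.
#' @param genome A `genome_sequence` (or named list of them).
#' @param flank Flank on each side of the boundary base (default 5, so
#'   11-nt windows).
#' @param fasta Optional path; when given the windows are written as FASTA
#'   for motif discovery (e.g. MEME).
#' @return Data frame with `chrom`, `start`, `end`, `side`
#'   (`"start"`/`"end"`), `seq`.
#' @export
junction_windows <- function(segments, genome, flank = 5L, fasta = NULL) {
  validate_intervals(segments)
  if (inherits(genome, "genome_sequence"))
    genome <- setNames(list(genome), genome$name)
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(segments))) {
    ch <- segments$chrom[i]
    g <- genome[[ch]]
    if (is.null(g)) stop("no sequence for chromosome '", ch, "'")
    for (side in c("start", "end")) {
      center <- if (side == "start") segments$start[i]
                else segments$end[i] - 1L
      ws <- center - flank
      we <- center + flank + 1L
      if (ws < 0L || we > g$length) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, start = ws, end = we, side = side,
                   seq = substr(g$seq, ws + 1L, we), stringsAsFactors = FALSE)
    }
  }
  if (dropped) warning(dropped, " junction window(s) clipped at contig edges; dropped")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               side = character(0), seq = character(0),
               stringsAsFactors = FALSE)
  if (!is.null(fasta) && nrow(out)) {
    hdr <- sprintf("%s:%d:%s", out$chrom, out$start + flank, out$side)
    writeLines(paste0(">", hdr, "\n", out$seq), fasta)
  }
  out
}

#' Positional base frequencies of junction windows
#'
#' @param windows Output of [junction_windows()] (optionally filtered by
#'   `side`).
#' @return 4 x width matrix of base frequencies (rows A, C, G, T).
#' @export
junction_base_frequencies <- function(windows) {
  stopifnot(nrow(windows) > 0L)
  width <- nchar(windows$seq[1L])
  m <- matrix(0, 4L, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in windows$seq) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (j in seq_len(width))
      if (b[j] %in% rownames(m)) m[b[j], j] <- m[b[j], j] + 1L
  }
  sweep(m, 2L, pmax(colSums(m), 1L), "/")
}

#' Score a haplotype by trait directions
#'
#' Each allele contributes `+1` if it increases the trait value, `-1` if it
#' decreases it, and `0` when no quantitative trait measure is available.
#'
#' @param directions Integer vector over `{-1, 0, 1}`, one per SNP allele.
#' @return The integer sum.
#' @export
haplotype_score <- function(directions) {
  stopifnot(all(directions %in% c(-1L, 0L, 1L)))
  as.integer(sum(directions))
}

#' Percentage ratio with printed-precision rounding
#'
#' @param numerator,denominator Counts.
#' @param digits Decimals to round to (half-up, as printed tables round).
#' @param scale `100` for percent (default), `1` for a plain ratio.
#' @return The rounded ratio.
#' @export
contingency_ratio <- function(numerator, denominator, digits = 1L,
                              scale = 100) {
  stopifnot(denominator > 0, numerator >= 0)
  round_half_up(scale * numerator / denominator, digits)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Printed tables round 0.5 up, unlike R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimals.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
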