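#' Read a FASTA file into genome sequences
#'
#' Sequences are uppercased and any character outside `A`, `C`, `G`, `T` is
#' mapped to `N`. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named list of `genome_sequence` objects (fields `name`, `seq`,
#'   `length`), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    s <- gsub("[^ACGT]", "N", s)
    out[[i]] <- genome_sequence(nms[i], s)
  }
  names(out) <- nms
  out
}

#' Construct a genome sequence
#'
#' @param name Sequence identifier.
#' @param seq Character scalar over the alphabet `ACGTN`.
#' @return A `genome_sequence` object.
#' @export
genome_sequence <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence '", name, "' contains characters outside ACGTN")
  structure(list(name = name, seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", x$name, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Write genome sequences to FASTA
#'
#' @param seqs A `genome_sequence` or list thereof.
#' @param path Output file.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "genome_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$name), con)
    starts <- seq(1L, s$length, by = width)
    writeLines(substring(s$seq, starts, pmin(starts + width - 1L, s$length)),
               con)
  }
  invisible(path)
}

#' Construct an interval table
#'
#' Intervals are BED-style: 0-based, half-open `[start, end)`.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer vectors; `0 <= start < end`.
#' @param score Optional numeric score.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (default; Z-flipons are
#'   strandless because the Z helix involves both strands).
#' @param name Optional feature names.
#' @return A data frame with columns `chrom`, `start`, `end` and any of
#'   `name`, `score`, `strand` supplied.
#' @export
intervals <- function(chrom, start, end, score = NULL, strand = NULL,
                      name = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(head(bad, 5L), collapse = ", "),
         ": need 0 <= start < end")
  invisible(df)
}

empty_intervals <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Read a BED file (BED3+) as an interval table
#'
#' @param path Path to a tab-separated BED3/BED6 file.
#' @return Interval data frame (0-based half-open), with `name`, `score`,
#'   `strand` columns when present in the file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               colClasses = "character", quote = ""),
    error = function(e) {
      # an empty BED file is a legal empty interval set
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop("malformed BED file '", path, "': ", conditionMessage(e))
    })
  if (is.null(raw)) return(empty_intervals())
  if (ncol(raw) < 3L) stop("BED file '", path, "' has fewer than 3 columns")
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  if (anyNA(start) || anyNA(end))
    stop("non-integer coordinates in BED file '", path, "' at line ",
         which(is.na(start) | is.na(end))[1L])
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop("invalid interval (start >= end or start < 0) in '", path,
         "' at line ", bad[1L])
  df <- data.frame(chrom = raw[[1L]], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (ncol(raw) >= 4L) df$name <- raw[[4L]]
  if (ncol(raw) >= 5L) {
    sc <- suppressWarnings(as.numeric(raw[[5L]]))
    df$score <- sc
  }
  if (ncol(raw) >= 6L) df$strand <- raw[[6L]]
  df
}

#' Write an interval table to BED
#'
#' Intervals are sorted by `(chrom, start)` on write.
#'
#' @param df Interval data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$name) || !is.null(df$score) || !is.null(df$strand)) {
    cols <- c(cols, list(if (is.null(df$name)) "." else df$name))
    if (!is.null(df$score) || !is.null(df$strand))
      cols <- c(cols, list(if (is.null(df$score)) 0 else df$score))
    if (!is.null(df$strand)) cols <- c(cols, list(df$strand))
  }
  out <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-nucleotide score vector as bedGraph
#'
#' Consecutive equal values are collapsed into one record.
#'
#' @param values Numeric vector, one value per nucleotide.
#' @param chrom Sequence name.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, chrom, path) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  r <- rle(values)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  write.table(data.frame(chrom, start, end, r$values),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# intervals for one chromosome -> IRanges (1-based closed, internal only)
.as_iranges <- function(df, chrom) {
  d <- df[df$chrom == chrom, , drop = FALSE]
  IRanges::IRanges(start = d$start + 1L, end = d$end)
}

.from_iranges <- function(ir, chrom) {
  if (length(ir) == 0L) return(empty_intervals())
  data.frame(chrom = chrom, start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir), stringsAsFactors = FALSE)
}

#' Per-nucleotide label vector from intervals
#'
#' @param df Interval data frame (all on the same sequence).
#' @param seq_length Sequence length in bp.
#' @return Integer vector of length `seq_length`; 1 where covered by at least
#'   one interval, 0 elsewhere.
#' @export
track_from_intervals <- function(df, seq_length) {
  validate_intervals(df)
  if (nrow(df) && (min(df$start) < 0L || max(df$end) > seq_length))
    stop("interval out of bounds for sequence of length ", seq_length)
  labels <- integer(seq_length)
  for (i in seq_len(nrow(df)))
    labels[(df$start[i] + 1L):df$end[i]] <- 1L
  labels
}

#' Merged intervals from a binary label vector
#'
#' Inverse of [track_from_intervals()] up to interval merging.
#'
#' @param labels Binary (0/1) vector.
#' @param chrom Sequence name for the output intervals.
#' @return Interval data frame of maximal runs of 1s.
#' @export
intervals_from_track <- function(labels, chrom = "chr1") {
  stopifnot(all(labels %in% c(0L, 1L)))
  r <- rle(as.integer(labels))
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values == 1L
  if (!any(keep)) return(empty_intervals())
  data.frame(chrom = chrom, start = start[keep], end = end[keep],
             stringsAsFactors = FALSE)
}

#' Set operations on interval tables
#'
#' bp-level semantics per chromosome; results are merged (disjoint, sorted).
#' Chromosomes present in `b` but not in `a` contribute nothing; chromosomes
#' of `a` absent from `b` are treated as zero overlap (a warning is issued for
#' `intersect`/`subtract` only when `b` is entirely disjoint in names).
#'
#' @param a,b Interval data frames.
#' @param mode One of `"intersect"`, `"subtract"`, `"merge"`. `"merge"`
#'   merges the union of `a` and `b`.
#' @return Interval data frame.
#' @export
interval_ops <- function(a, b, mode = c("intersect", "subtract", "merge")) {
  mode <- match.arg(mode)
  validate_intervals(a)
  validate_intervals(b)
  if (mode == "merge") {
    ab <- rbind(a[c("chrom", "start", "end")], b[c("chrom", "start", "end")])
    chroms <- sort(unique(ab$chrom))
    out <- lapply(chroms, function(ch)
      .from_iranges(IRanges::reduce(.as_iranges(ab, ch)), ch))
    return(do.call(rbind, c(list(empty_intervals()), out)))
  }
  if (nrow(a) && nrow(b) && !any(unique(a$chrom) %in% unique(b$chrom)))
    warning("no chromosome of 'a' present in 'b'; treating as zero overlap")
  chroms <- sort(unique(a$chrom))
  out <- lapply(chroms, function(ch) {
    ia <- IRanges::reduce(.as_iranges(a, ch))
    ib <- IRanges::reduce(.as_iranges(b, ch))
    res <- switch(mode,
                  intersect = IRanges::intersect(ia, ib),
                  subtract = IRanges::setdiff(ia, ib))
    .from_iranges(res, ch)
  })
  do.call(rbind, c(list(empty_intervals()), out))
}

#' Fraction of `a` covered by `b`, in bp
#'
#' @param a,b Interval data frames.
#' @return `(bp of a covered by b) / (total bp of a)`; `NA` if `a` is empty.
#' @export
coverage_fraction <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  am <- interval_ops(a, a, "merge")
  total <- sum(am$end - am$start)
  if (total == 0L) return(NA_real_)
  ov <- interval_ops(am, b, "intersect")
  sum(ov$end - ov$start) / total
}

#' Segment- and bp-level overlap counts between two interval sets
#'
#' @param a,b Interval data frames.
#' @return List with `segments_overlapping` (segments of `a` intersecting
#'   `b` by >= 1 bp), `segments_total`, `bp_overlap`, `bp_total`,
#'   `coverage_fraction`.
#' @export
overlap_counts <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  n_hit <- 0L
  for (ch in unique(a$chrom)) {
    ia <- .as_iranges(a, ch)
    ib <- IRanges::reduce(.as_iranges(b, ch))
    n_hit <- n_hit + sum(IRanges::countOverlaps(ia, ib) > 0L)
  }
  am <- interval_ops(a, a, "merge")
  ov <- suppressWarnings(interval_ops(am, b, "intersect"))
  list(segments_overlapping = n_hit,
       segments_total = nrow(a),
       bp_overlap = sum(ov$end - ov$start),
       bp_total = sum(am$end - am$start),
       coverage_fraction = if (nrow(am)) sum(ov$end - ov$start) /
         sum(am$end - am$start) else NA_real_)
}

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over `ACGTN`.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}
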