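#' k-mer vocabulary
#'
#' Content k-mers are numbered 1..4^k in lexicographic order (A < C < G < T),
#' followed by two specials: `UNK` (any k-mer containing `N`) and `PAD`
#' (window padding). For the default `k = 6` the vocabulary has 4096 content
#' tokens and ids `UNK = 4097`, `PAD = 4098`.
#'
#' @param k k-mer length.
#' @return List with `k`, `size`, `unk_id`, `pad_id`, and `kmers` (the
#'   lexicographic k-mer strings).
#' @export
kmer_vocab <- function(k = 6L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 10L)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  kmers <- do.call(paste0, rev(grid))
  kmers <- sort(kmers)
  list(k = k, size = 4L^k + 2L, unk_id = 4L^k + 1L, pad_id = 4L^k + 2L,
       kmers = kmers)
}

#' Write / read a k-mer vocabulary file
#'
#' Plain text, one `kmer<TAB>id` line per token in id order, specials last.
#'
#' @param vocab A [kmer_vocab()].
#' @param path File path.
#' @return `path` / the vocabulary, invisibly.
#' @export
write_vocab <- function(vocab, path) {
  df <- data.frame(token = c(vocab$kmers, "UNK", "PAD"),
                   id = seq_len(vocab$size))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  k <- nchar(df[[1L]][1L])
  v <- kmer_vocab(k)
  if (!identical(c(v$kmers, "UNK", "PAD"), df[[1L]]))
    stop("vocabulary file does not match lexicographic ", k, "-mer order")
  v
}

# integer codes A=0 C=1 G=2 T=3, N = NA, for one sequence string
.base_codes <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1L]],
             c("A", "C", "G", "T"))
  m - 1L
}

#' Tokenize a sequence into overlapping k-mers
#'
#' Sliding window, stride 1: token `i` covers `seq[i, i+k)` so each
#' nucleotide is represented by the k-mer starting at it. k-mers containing
#' `N` map to `UNK`.
#'
#' @param x A `genome_sequence` or DNA string.
#' @param k k-mer length.
#' @return A `token_sequence`: list with `tokens` (integer ids), `k`,
#'   `origin` (chrom, 0-based start) and `seq_length`.
#' @export
tokenize <- function(x, k = 6L) {
  if (inherits(x, "genome_sequence")) { seq <- x$seq; chrom <- x$name }
  else { seq <- as.character(x); chrom <- "chr1" }
  n <- nchar(seq)
  k <- as.integer(k)
  if (n < k) stop("sequence length ", n, " < k = ", k)
  code <- .base_codes(seq)
  nt <- n - k + 1L
  ids <- integer(nt)
  bad <- logical(nt)
  pw <- as.integer(4^((k - 1L):0L))
  for (j in seq_len(k)) {
    cj <- code[j:(j + nt - 1L)]
    nas <- is.na(cj)
    bad <- bad | nas
    cj[nas] <- 0L
    ids <- ids + cj * pw[j]
  }
  ids <- ids + 1L
  ids[bad] <- as.integer(4^k + 1)   # UNK
  structure(list(tokens = ids, k = k,
                 origin = list(chrom = chrom, start = 0L),
                 seq_length = n),
            class = "token_sequence")
}

#' Reconstruct the sequence from overlapping tokens
#'
#' Only defined for `N`-free sequences (no `UNK` tokens).
#'
#' @param ts A `token_sequence`.
#' @return The DNA string.
#' @export
detokenize <- function(ts) {
  v <- kmer_vocab(ts$k)
  if (any(ts$tokens >= v$unk_id)) stop("cannot detokenize UNK/PAD tokens")
  km <- v$kmers[ts$tokens]
  paste0(paste(substr(km, 1L, 1L), collapse = ""),
         substr(km[length(km)], 2L, ts$k))
}

#' Project nucleotide labels onto tokens
#'
#' Token `i` inherits the label of nucleotide `i` (the k-mer's first base);
#' with `method = "majority"` it takes the majority vote over the k covered
#' bases (ties to 1).
#'
#' @param labels Per-nucleotide 0/1 vector.
#' @param k k-mer length.
#' @param method `"first"` (default) or `"majority"`.
#' @return Per-token 0/1 vector of length `length(labels) - k + 1`.
#' @export
project_labels <- function(labels, k = 6L, method = c("first", "majority")) {
  method <- match.arg(method)
  n <- length(labels)
  if (n < k) stop("label track shorter than k")
  nt <- n - k + 1L
  if (method == "first") return(as.integer(labels[seq_len(nt)]))
  cs <- c(0L, cumsum(as.integer(labels)))
  cov <- cs[(k + 1L):(n + 1L)] - cs[1L:nt]
  as.integer(cov * 2L >= k)
}

#' Lift per-token probabilities back to nucleotides
#'
#' Nucleotide `i` receives the probability of token `i`; the trailing
#' `k - 1` nucleotides inherit the final token's probability.
#'
#' @param token_probs Per-token probability vector.
#' @param k k-mer length.
#' @param seq_length Sequence length in bp.
#' @return Per-nucleotide probability vector of length `seq_length`.
#' @export
lift_predictions <- function(token_probs, k = 6L, seq_length) {
  nt <- seq_length - k + 1L
  if (length(token_probs) != nt)
    stop("expected ", nt, " token probabilities, got ", length(token_probs))
  c(token_probs, rep(token_probs[nt], k - 1L))
}

#' Chunk a token sequence into fixed-length windows
#'
#' Windows tile the token stream; the final short window is padded with
#' `PAD`, which is masked from loss and prediction downstream.
#'
#' @param ts A `token_sequence`.
#' @param window Window length in tokens.
#' @param stride Step between window starts; `stride == window` (default)
#'   tiles without overlap, smaller strides overlap (overlapping nucleotide
#'   probabilities are averaged at prediction time).
#' @return List of windows, each a list with `tokens` (length `window`),
#'   `valid` (logical mask, `FALSE` at PAD), `token_start` (0-based offset
#'   into the token stream) and `chrom`.
#' @export
make_windows <- function(ts, window = 512L, stride = window) {
  stopifnot(inherits(ts, "token_sequence"), window >= 1L, stride >= 1L,
            stride <= window)
  v <- kmer_vocab(ts$k)
  n <- length(ts$tokens)
  starts <- seq.int(0L, max(0L, n - 1L), by = stride)
  # drop windows that start beyond the stream except the first
  starts <- starts[starts < n]
  lapply(starts, function(s) {
    take <- (s + 1L):min(s + window, n)
    toks <- ts$tokens[take]
    pad <- window - length(take)
    list(tokens = c(toks, rep(v$pad_id, pad)),
         valid = c(rep(TRUE, length(take)), rep(FALSE, pad)),
         token_start = s, chrom = ts$origin$chrom)
  })
}

#' Encode one position as a gradient-boosting record
#'
#' The classical fixed-width encoding: the 261-nt (256 + k - 1) window whose
#' 256 overlapping 6-mers, read as categorical ids, describe the central
#' nucleotide; the label is the Z status of that central base.
#'
#' @param x A `genome_sequence` or DNA string.
#' @param center 0-based position of the target nucleotide.
#' @param labels Optional per-nucleotide 0/1 vector for the label.
#' @param k k-mer length.
#' @param n_features Number of k-mer features (window is
#'   `n_features + k - 1` nt).
#' @return List with `features` (integer vector of `n_features` ids),
#'   `label` (0/1 or `NA`), `center`; or `NULL` with a warning when the
#'   window does not fit.
#' @export
encode_boost <- function(x, center, labels = NULL, k = 6L,
                         n_features = 256L) {
  if (inherits(x, "genome_sequence")) seq <- x$seq else seq <- as.character(x)
  n <- nchar(seq)
  win <- n_features + k - 1L
  start <- center - n_features %/% 2L + 1L   # 0-based window start
  if (start < 0L || start + win > n) {
    warning("boost window out of bounds at center ", center, "; skipped")
    return(NULL)
  }
  sub <- substr(seq, start + 1L, start + win)
  ids <- tokenize(sub, k)$tokens
  lab <- if (is.null(labels)) NA_integer_ else as.integer(labels[center + 1L])
  list(features = ids, label = lab, center = center)
}
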