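#' Z-propensity score of a sequence
#'
#' `sum(log(1 + p))` over every nucleotide, where `p` is the model's
#' predicted probability of Z-DNA formation. Adding 1 inside the log keeps
#' zero probabilities finite; the natural log is used (ratios of scores are
#' base-invariant).
#'
#' @param x A `prediction_track`, a probability vector, or a
#'   `genome_sequence`/string (scored with `ensemble`).
#' @param ensemble A `z_ensemble`, required when `x` is a sequence.
#' @return The scalar score.
#' @export
z_score <- function(x, ensemble = NULL) {
  p <- if (inherits(x, "prediction_track")) x$p
       else if (is.numeric(x)) x
       else predict_track(ensemble, x)$p
  if (!length(p)) stop("empty sequence")
  stopifnot(all(p >= 0 & p <= 1))
  sum(log1p(p))
}

#' In-silico saturation mutagenesis map
#'
#' Every position of the region is substituted with the three alternative
#' bases; each variant sequence is re-tokenized and re-scored over the same
#' fixed scoring window, and the effect is the ratio
#' `score(variant) / score(reference)`. Ratios above 1 mean the substitution
#' increases the predicted propensity to form Z-DNA; below 1, decreases.
#'
#' @param genome A `genome_sequence`.
#' @param region_start,region_end 0-based half-open region to mutate.
#' @param ensemble A `z_ensemble`.
#' @param window_policy `"tiles"` (default) scores over the 512-token tiling
#'   windows covering the region, fixed across all variants; `"region"`
#'   scores over the region only.
#' @param flank bp of context kept on each side of the region when
#'   `window_policy = "tiles"` is wider than the sequence.
#' @return An object of class `mutagenesis_map`: list with `region`,
#'   `ref_seq`, `ref_score`, `effect` (length x 4 matrix over A/C/G/T;
#'   reference base column fixed at 1) and `delta` (score differences).
#'   When `ref_score == 0` the ratios are `NA` with a warning.
#' @export
mutagenesis_map <- function(genome, region_start, region_end, ensemble,
                            window_policy = c("tiles", "region"),
                            flank = 250L) {
  window_policy <- match.arg(window_policy)
  stopifnot(inherits(genome, "genome_sequence"),
            region_start >= 0L, region_end <= genome$length,
            region_start < region_end)
  cfg <- ensemble$config
  if (window_policy == "tiles") {
    wbp <- cfg$window
    win_start <- (region_start %/% wbp) * wbp
    win_end <- min(genome$length, ((region_end - 1L) %/% wbp + 1L) * wbp)
  } else {
    win_start <- max(0L, region_start - flank)
    win_end <- min(genome$length, region_end + flank)
  }
  score_window <- function(seq_str) {
    sub <- substr(seq_str, win_start + 1L, win_end)
    z_score(genome_sequence("w", sub), ensemble)
  }
  ref_score <- score_window(genome$seq)
  len <- region_end - region_start
  bases <- c("A", "C", "G", "T")
  ref_bases <- strsplit(substr(genome$seq, region_start + 1L, region_end),
                        "", fixed = TRUE)[[1L]]
  effect <- matrix(NA_real_, len, 4L, dimnames = list(NULL, bases))
  delta <- matrix(NA_real_, len, 4L, dimnames = list(NULL, bases))
  zero_ref <- ref_score == 0
  if (zero_ref)
    warning("reference score is 0; effect ratios undefined (NA)")
  for (i in seq_len(len)) {
    pos <- region_start + i          # 1-based string position
    for (b in bases) {
      if (b == ref_bases[i]) {
        effect[i, b] <- 1; delta[i, b] <- 0
        next
      }
      var_seq <- genome$seq
      substr(var_seq, pos, pos) <- b
      s <- score_window(var_seq)
      delta[i, b] <- s - ref_score
      effect[i, b] <- if (zero_ref) NA_real_ else s / ref_score
    }
  }
  structure(list(region = intervals(genome$name, region_start, region_end),
                 ref_seq = paste(ref_bases, collapse = ""),
                 ref_score = ref_score, effect = effect, delta = delta,
                 window = c(win_start, win_end)),
            class = "mutagenesis_map")
}

#' @export
print.mutagenesis_map <- function(x, ...) {
  cat("<mutagenesis_map> ", x$region$chrom, ":", x$region$start, "-",
      x$region$end, " ref_score ", formatC(x$ref_score, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Write / read a mutagenesis map as TSV
#'
#' Columns: 0-based `pos`, `ref`, then the effect ratio and score difference
#' for each alternative base.
#'
#' @param map A `mutagenesis_map`.
#' @param path Output file.
#' @return `path` / a list with `effect` and `delta` matrices.
#' @export
write_mutagenesis_tsv <- function(map, path) {
  bases <- colnames(map$effect)
  df <- data.frame(pos = map$region$start + seq_len(nrow(map$effect)) - 1L,
                   ref = strsplit(map$ref_seq, "", fixed = TRUE)[[1L]])
  for (b in bases) df[[paste0("ratio_", b)]] <- map$effect[, b]
  for (b in bases) df[[paste0("delta_", b)]] <- map$delta[, b]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutagenesis_tsv
#' @export
read_mutagenesis_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  eff <- as.matrix(df[paste0("ratio_", bases)])
  del <- as.matrix(df[paste0("delta_", bases)])
  colnames(eff) <- bases; colnames(del) <- bases
  list(effect = eff, delta = del, pos = df$pos, ref = df$ref)
}

#' Render a mutagenesis map as a heatmap PNG (plus TSV twin)
#'
#' Diverging palette centered at effect = 1: red above (substitution
#' increases Z-propensity), blue below (loss of Z-DNA formation).
#'
#' @param map A `mutagenesis_map`.
#' @param png_path Optional PNG output.
#' @param tsv_path Optional TSV output.
#' @return Invisibly, a list with the matrix extrema annotations
#'   (`min`, `max`).
#' @export
render_heatmap <- function(map, png_path = NULL, tsv_path = NULL) {
  if (!is.null(tsv_path)) write_mutagenesis_tsv(map, tsv_path)
  ext <- list(min = min(map$effect, na.rm = TRUE),
              max = max(map$effect, na.rm = TRUE))
  if (!is.null(png_path)) {
    m <- map$effect
    lim <- max(abs(m - 1), na.rm = TRUE)
    if (lim == 0) lim <- 1e-6
    breaks <- seq(1 - lim, 1 + lim, length.out = 101L)
    pal <- colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100L)
    png(png_path, width = max(480L, 8L * nrow(m)), height = 320L)
    image(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m, col = pal,
          breaks = breaks, xlab = "position", ylab = "",
          main = sprintf("effect ratio (min %.3f, max %.3f)",
                         ext$min, ext$max), yaxt = "n")
    axis(2, at = seq_len(ncol(m)), labels = colnames(m))
    dev.off()
  }
  invisible(ext)
}
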