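#' Specification for a synthetic Z-flipon genome
#'
#' Emulates the structure of experimentally mapped Z-DNA training data:
#' short Z-prone segments (tens of bp) of alternating purine-pyrimidine
#' repeats embedded sparsely in random background, with an adenosine-rich
#' d(TAAA) motif planted at segment flanks at a configurable rate.
#'
#' @param contig_length Contig length, bp.
#' @param n_z_segments Number of planted Z segments.
#' @param repeat_family_mix Named weights over the planted repeat families
#'   `cg` ((CG)n), `ca` ((CA)n / (TG)n), `cggg` ((CGGG)n) and `mixed`
#'   (random interleavings of CG and CA steps). Must sum to 1.
#' @param segment_length_range Even min/max planted segment length, bp.
#' @param junction_motif_rate Probability that a segment's 5' flank carries
#'   the TAAA junction motif (mirrored as TTTA at the 3' flank).
#' @param background_gc Background GC fraction (i.i.d. bases).
#' @param min_gap Minimum spacing between planted segments, bp.
#' @param seed RNG seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(contig_length = 100000L, n_z_segments = 200L,
                       repeat_family_mix = c(cg = 0.4, ca = 0.3,
                                             cggg = 0.1, mixed = 0.2),
                       segment_length_range = c(12L, 60L),
                       junction_motif_rate = 0.5, background_gc = 0.41,
                       min_gap = 50L, seed = 1L) {
  stopifnot(abs(sum(repeat_family_mix) - 1) < 1e-9,
            all(repeat_family_mix >= 0),
            all(c("cg", "ca", "cggg", "mixed") %in%
                  names(repeat_family_mix)),
            segment_length_range[1L] >= 12L,
            segment_length_range[1L] %% 2L == 0L,
            segment_length_range[2L] %% 2L == 0L,
            segment_length_range[2L] >= segment_length_range[1L],
            junction_motif_rate >= 0, junction_motif_rate <= 1,
            background_gc > 0, background_gc < 1, min_gap >= 0L)
  structure(list(contig_length = as.integer(contig_length),
                 n_z_segments = as.integer(n_z_segments),
                 repeat_family_mix = repeat_family_mix,
                 segment_length_range = as.integer(segment_length_range),
                 junction_motif_rate = junction_motif_rate,
                 background_gc = background_gc,
                 min_gap = as.integer(min_gap), seed = as.integer(seed)),
            class = "synth_spec")
}

.repeat_unit <- function(family, len) {
  pat <- switch(family,
                cg = "CG",
                ca = if (runif(1) < 0.5) "CA" else "TG",
                cggg = "CGGG",
                mixed = NULL)
  if (is.null(pat)) {  # random interleaving of CG and CA dinucleotide steps
    steps <- sample(c("CG", "CA"), len %/% 2L, replace = TRUE)
    return(paste(steps, collapse = ""))
  }
  substr(strrep(pat, ceiling(len / nchar(pat))), 1L, len)
}

#' Generate a synthetic genome with energetics-derived ground truth
#'
#' Plants non-overlapping repeat segments into i.i.d. background and labels
#' the final contig with the energetics oracle ([energy_label_track()]), so
#' both the planted repeats and any background sequence that happens to be
#' Z-prone carry consistent truth labels.
#'
#' @param spec A [synth_spec()].
#' @param model The [energy_model()] used as labeling oracle.
#' @return List with `genome` (a `genome_sequence`), `planted` (interval
#'   data frame of planted repeats with `name` = family), `truth`
#'   (per-nucleotide 0/1 oracle labels), `truth_intervals`, and
#'   `oracle_score` (per-nucleotide energy score track).
#' @export
synth_genome <- function(spec = synth_spec(), model = energy_model()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  gc <- spec$background_gc
  bases <- sample(c("A", "C", "G", "T"), spec$contig_length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  lens <- 2L * sample(seq(spec$segment_length_range[1L] %/% 2L,
                          spec$segment_length_range[2L] %/% 2L),
                      spec$n_z_segments, replace = TRUE)
  fams <- sample(names(spec$repeat_family_mix), spec$n_z_segments,
                 replace = TRUE, prob = spec$repeat_family_mix)
  # place segments left to right with random gaps; error out if they cannot fit
  flank <- 5L
  need <- sum(lens) + (spec$n_z_segments + 1L) * (spec$min_gap + flank)
  if (need > spec$contig_length)
    stop("requested segments do not fit: need >= ", need, " bp, contig is ",
         spec$contig_length, " bp")
  slack <- spec$contig_length - sum(lens) -
    (spec$n_z_segments + 1L) * (spec$min_gap + flank)
  cuts <- sort(sample.int(slack + 1L, spec$n_z_segments, replace = TRUE)) - 1L
  starts <- integer(spec$n_z_segments)
  pos <- 0L
  for (i in seq_len(spec$n_z_segments)) {
    extra <- cuts[i] - if (i > 1L) cuts[i - 1L] else 0L
    pos <- pos + spec$min_gap + flank + extra
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  for (i in seq_len(spec$n_z_segments)) {
    unit <- strsplit(.repeat_unit(fams[i], lens[i]), "", fixed = TRUE)[[1L]]
    bases[(starts[i] + 1L):(starts[i] + lens[i])] <- unit
    if (runif(1) < spec$junction_motif_rate) {
      # TAAA ending at the 5' junction; TTTA starting at the 3' junction
      bases[(starts[i] - 3L):starts[i]] <- c("T", "A", "A", "A")
      e <- starts[i] + lens[i]
      bases[(e + 1L):(e + 4L)] <- c("T", "T", "T", "A")
    }
  }
  g <- genome_sequence("synth1", paste(bases, collapse = ""))
  planted <- intervals(rep(g$name, spec$n_z_segments), starts,
                       starts + lens, name = fams)
  truth <- energy_label_track(g, model)
  list(genome = g, planted = planted, truth = truth,
       truth_intervals = intervals_from_track(truth, g$name),
       oracle_score = energy_score_track(g, model))
}

#' Generate a consistent annotation fixture
#'
#' Builds a small gene model (TSS, gene bodies, exons, UTRs), a repeat-family
#' BED over the planted segments, and a SNP table with trait directions --
#' the inputs the downstream feature / enrichment / haplotype analytics
#' consume. All intervals are internally consistent (exons inside genes,
#' UTRs at gene ends).
#'
#' @param synth Output of [synth_genome()].
#' @param n_genes Number of genes to scatter over the contig.
#' @param n_snps Number of SNPs in the table.
#' @param seed RNG seed.
#' @return List with `annotation` (a [feature_annotation()]), `genes`,
#'   `exons`, `utr5`, `utr3`, `tss`, `repeats` (planted repeats with family
#'   names) and `snps` (data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `direction` in -1/0/+1).
#' @export
synth_annotation <- function(synth, n_genes = 20L, n_snps = 50L, seed = 1L) {
  set.seed(seed)
  g <- synth$genome
  L <- g$length
  glen <- 2000L
  gap <- max(500L, (L - n_genes * glen) %/% (n_genes + 1L))
  gstart <- cumsum(rep(gap + glen, n_genes)) - glen
  gstart <- gstart[gstart + glen <= L]
  n <- length(gstart)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- intervals(rep(g$name, n), gstart, gstart + glen, strand = strand)
  tss <- data.frame(chrom = g$name,
                    pos = ifelse(strand == "+", gstart, gstart + glen - 1L),
                    strand = strand, stringsAsFactors = FALSE)
  # 3 exons per gene at fixed offsets; UTRs at the transcript ends
  ex <- do.call(rbind, lapply(seq_len(n), function(i) {
    off <- c(0L, 800L, 1600L)
    intervals(rep(g$name, 3L), gstart[i] + off, gstart[i] + off + 300L)
  }))
  utr5 <- intervals(rep(g$name, n),
                    ifelse(strand == "+", gstart, gstart + glen - 100L),
                    ifelse(strand == "+", gstart + 100L, gstart + glen))
  utr3 <- intervals(rep(g$name, n),
                    ifelse(strand == "+", gstart + glen - 100L, gstart),
                    ifelse(strand == "+", gstart + glen, gstart + 100L))
  annot <- feature_annotation(tss, genes, ex, utr5, utr3)
  pos <- sort(sample.int(L, n_snps)) - 1L
  ref <- substring(g$seq, pos + 1L, pos + 1L)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  snps <- data.frame(chrom = g$name, pos = pos, ref = ref, alt = alt,
                     direction = sample(c(-1L, 0L, 1L), n_snps,
                                        replace = TRUE),
                     stringsAsFactors = FALSE, row.names = NULL)
  list(annotation = annot, genes = genes, exons = ex, utr5 = utr5,
       utr3 = utr3, tss = tss, repeats = synth$planted, snps = snps)
}
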