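#' Thermodynamic model of the B-to-Z transition
#'
#' The model assigns each dinucleotide step a cost (kcal/mol) for flipping
#' from B- into Z-DNA, plus a fixed penalty per B-Z junction (two junctions
#' flank every Z helix). Alternating purine-pyrimidine steps are cheap --
#' d(CG) cheapest, then d(CA)/d(TG), then the out-of-alternation d(GG)/d(CC)
#' -- and every other step pays a single configurable penalty so that
#' imperfect repeats are disfavoured but not forbidden.
#'
#' The cost table is closed under reverse complement: the two strands of a
#' Z helix are equivalent, so `cost(xy) == cost(revcomp(xy))`.
#'
#' @param cg Cost of a d(CG) step, kcal/mol per dinucleotide.
#' @param ca Cost of d(CA) (and its complement d(TG)).
#' @param gg Cost of d(GG) (and d(CC)).
#' @param other Cost of any dinucleotide not listed above.
#' @param junction Cost per B-Z junction, kcal/mol; every Z segment pays two.
#' @param min_helix_bp Minimum Z-helix length, bp (even).
#' @param max_helix_bp Longest single segment the caller will emit, bp.
#' @param z_cutoff Threshold on the mean dinucleotide cost (junctions
#'   excluded), kcal/mol per dinucleotide, for calling a segment Z-prone.
#'   The default admits pure d(CG)n and d(CA)n repeats and d(CG)-rich mixes,
#'   and rejects random sequence; it is a tunable, not a measured constant.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(cg = 0.6, ca = 1.34, gg = 2.4, other = 4.0,
                         junction = 5.0, min_helix_bp = 12L,
                         max_helix_bp = 200L, z_cutoff = 1.5) {
  stopifnot(cg > 0, ca > 0, gg > 0, other > 0, junction > 0,
            min_helix_bp >= 2L, min_helix_bp %% 2L == 0L,
            max_helix_bp >= min_helix_bp, z_cutoff > 0)
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  cost <- setNames(rep(other, 16L), dinucs)
  cost["CG"] <- cg                     # revcomp(CG) == CG
  cost["CA"] <- ca; cost["TG"] <- ca   # d(CA) == d(TG)
  cost["GG"] <- gg; cost["CC"] <- gg
  structure(list(dinucleotide_cost = cost, junction_cost = junction,
                 min_helix_bp = as.integer(min_helix_bp),
                 max_helix_bp = as.integer(max_helix_bp),
                 z_cutoff = z_cutoff),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> junction", x$junction_cost, "kcal/mol x2;",
      "cutoff", x$z_cutoff, "kcal/mol/dinuc;",
      "helix", x$min_helix_bp, "-", x$max_helix_bp, "bp\n")
  named <- x$dinucleotide_cost[c("CG", "CA", "GG")]
  cat("  d(CG)/d(CA)/d(GG):", paste(named, collapse = " / "),
      "; other:", x$dinucleotide_cost[["AA"]], "\n")
  invisible(x)
}

# vector of dinucleotide costs along a sequence: cost[i] for seq[i, i+2)
.dinuc_costs <- function(seq, model) {
  n <- nchar(seq)
  if (n < 2L) return(numeric(0))
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  keys <- paste0(b[-n], b[-1L])
  cost <- unname(model$dinucleotide_cost[keys])
  cost[is.na(cost)] <- Inf   # any dinucleotide containing N
  cost
}

#' Free-energy cost of flipping a segment into Z-DNA
#'
#' The segment is tiled by non-overlapping dinucleotides starting at offset
#' `phase` (0 or 1); the total is the sum of their costs plus two junction
#' penalties. With `phase = 1` the first and last base fall outside the
#' dinucleotide register and contribute nothing.
#'
#' @param seq DNA string of even length, no `N`.
#' @param phase Tiling offset, 0 or 1 (the syn-anti register is not
#'   observable from sequence, so both are legal).
#' @param model An [energy_model()].
#' @return Energy in kcal/mol.
#' @export
segment_energy <- function(seq, phase = 0L, model = energy_model()) {
  n <- nchar(seq)
  if (n < 2L || n %% 2L != 0L)
    stop("segment length must be even and >= 2, got ", n)
  if (grepl("N", seq, fixed = TRUE)) stop("segment contains N")
  stopifnot(phase %in% c(0L, 1L))
  idx <- seq.int(1L + phase, n - 1L, by = 2L)
  costs <- .dinuc_costs(seq, model)
  sum(costs[idx]) + 2 * model$junction_cost
}

#' Minimal-energy Z-prone segments of a sequence
#'
#' Enumerates every even-length window between `min_helix_bp` and
#' `max_helix_bp` (both dinucleotide tiling parities, tiling anchored at the
#' window start) via cumulative sums, keeps windows whose mean dinucleotide
#' cost is at most `z_cutoff`, and selects non-overlapping segments
#' best-first: lowest mean cost wins, ties resolved to the longer then the
#' leftmost window. The exhaustive enumeration guarantees the reported
#' minimal mean cost equals a brute-force scan over all admissible windows.
#'
#' @param x A `genome_sequence` or DNA string.
#' @param model An [energy_model()].
#' @return Data frame with columns `chrom`, `start`, `end`,
#'   `energy_per_dinuc` (mean step cost, junctions excluded), `energy_total`
#'   (step costs plus two junctions) and `phase` (parity of the first base,
#'   `start %% 2`), sorted by `start`. Empty when nothing qualifies.
#' @export
best_z_segments <- function(x, model = energy_model()) {
  if (inherits(x, "genome_sequence")) { seq <- x$seq; chrom <- x$name }
  else { seq <- as.character(x); chrom <- "chr1" }
  n <- nchar(seq)
  if (n < model$min_helix_bp) return(.empty_segments())
  costs <- .dinuc_costs(seq, model)
  costs[!is.finite(costs)] <- 1e9     # N-containing steps never qualify
  m_min <- model$min_helix_bp %/% 2L
  m_max <- model$max_helix_bp %/% 2L
  cand_start <- integer(0); cand_m <- integer(0); cand_mean <- numeric(0)
  for (q in 0:1) {
    pos <- seq.int(1L + q, n - 1L, by = 2L)   # chain of tiling positions
    if (length(pos) < m_min) next
    d <- costs[pos]
    cs <- c(0, cumsum(d))
    J <- length(d)
    for (m in m_min:min(m_max, J)) {
      mu <- (cs[(m + 1L):(J + 1L)] - cs[1L:(J - m + 1L)]) / m
      hit <- which(mu <= model$z_cutoff + 1e-9)
      if (length(hit)) {
        cand_start <- c(cand_start, pos[hit] - 1L)   # 0-based bp start
        cand_m <- c(cand_m, rep.int(m, length(hit)))
        cand_mean <- c(cand_mean, mu[hit])
      }
    }
  }
  if (!length(cand_start)) return(.empty_segments())
  # quantize the sort key so cumulative-sum noise cannot break exact ties
  ord <- order(round(cand_mean, 9L), -cand_m, cand_start)
  claimed <- logical(n)
  keep <- integer(0)
  for (i in ord) {
    s <- cand_start[i] + 1L; e <- cand_start[i] + 2L * cand_m[i]
    if (!any(claimed[s:e])) { claimed[s:e] <- TRUE; keep <- c(keep, i) }
  }
  st <- cand_start[keep]
  en <- cand_start[keep] + 2L * cand_m[keep]
  tot <- cand_mean[keep] * cand_m[keep] + 2 * model$junction_cost
  out <- data.frame(chrom = chrom, start = st, end = en,
                    energy_per_dinuc = cand_mean[keep], energy_total = tot,
                    phase = st %% 2L, stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

.empty_segments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             energy_per_dinuc = numeric(0), energy_total = numeric(0),
             phase = integer(0), stringsAsFactors = FALSE)
}

#' Oracle label track from the energetics model
#'
#' @param x A `genome_sequence` or DNA string.
#' @param model An [energy_model()].
#' @return Integer 0/1 vector, one per nucleotide; 1 inside
#'   [best_z_segments()] calls.
#' @export
energy_label_track <- function(x, model = energy_model()) {
  len <- if (inherits(x, "genome_sequence")) x$length else nchar(x)
  seg <- best_z_segments(x, model)
  track_from_intervals(seg, len)
}

#' Per-nucleotide energy score track
#'
#' Bases inside a called Z segment carry that segment's mean dinucleotide
#' cost; all other bases carry the out-of-alternation cost, so lower values
#' mean more Z-prone everywhere on one scale.
#'
#' @inheritParams energy_label_track
#' @return Numeric vector, one value per nucleotide (kcal/mol/dinucleotide).
#' @export
energy_score_track <- function(x, model = energy_model()) {
  len <- if (inherits(x, "genome_sequence")) x$length else nchar(x)
  seg <- best_z_segments(x, model)
  v <- rep(model$dinucleotide_cost[["AA"]], len)
  for (i in seq_len(nrow(seg)))
    v[(seg$start[i] + 1L):seg$end[i]] <- seg$energy_per_dinuc[i]
  v
}
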