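# Shared fixtures: a small synthetic genome and a matching trained ensemble.
# Sized so the whole suite trains in seconds; the full desk-scale run lives
# in test-acceptance.R.

tiny_spec <- function(seed = 101L) {
  synth_spec(contig_length = 12000L, n_z_segments = 50L,
             segment_length_range = c(12L, 40L), seed = seed)
}

tiny_config <- function(seed = 101L) {
  segmenter_config(window = 64L, d_model = 16L, n_layers = 2L,
                   n_heads = 2L, d_ff = 32L, seed = seed)
}

# built once per test run
.tiny <- local({
  sy <- synth_genome(tiny_spec())
  ens <- suppressMessages(
    train_segmenter(sy$genome, sy$truth, tiny_config(), quiet = TRUE))
  list(sy = sy, ens = ens)
})

tiny_synth <- function() .tiny$sy
tiny_ensemble <- function() .tiny$ens

# independent brute-force helpers used as oracles -------------------------

# mean dinucleotide cost of seq[s..e] (1-based, inclusive), tiling from s
brute_mean_cost <- function(seq, s, e, cost_table) {
  total <- 0; m <- 0L
  i <- s
  while (i + 1L <= e) {
    di <- substr(seq, i, i + 1L)
    cost <- if (grepl("N", di)) Inf else cost_table[[di]]
    total <- total + cost
    m <- m + 1L
    i <- i + 2L
  }
  total / m
}

# exhaustive minimum mean cost over all even windows in [min_bp, max_bp]
brute_min_mean <- function(seq, model) {
  n <- nchar(seq)
  ct <- as.list(model$dinucleotide_cost)
  best <- Inf
  for (s in 1:n) {
    hi <- min(model$max_helix_bp, n - s + 1L)
    if (hi < model$min_helix_bp) next
    for (len in seq(model$min_helix_bp, hi, by = 2L)) {
      mu <- brute_mean_cost(seq, s, s + len - 1L, ct)
      if (mu < best) best <- mu
    }
  }
  best
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# dinucleotide-step sequences biased toward Z-prone alternation
random_z_biased <- function(n_steps) {
  paste(sample(c("CG", "CA", "TG", "GG", "AT", "AA"), n_steps,
               replace = TRUE, prob = c(.3, .2, .1, .2, .1, .1)),
        collapse = "")
}
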