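---
title: "Locating Z-flipons: energetics, a 6-mer transformer segmenter, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating Z-flipons: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Z-flipons are genomic segments that can flip from the right-handed B-DNA
double helix into the left-handed Z conformation under the torsional stress
generated by transcription. The flip is sequence-dependent: alternating
purine–pyrimidine repeats such as d(CG)n and d(CA)n pay the lowest energetic
price because purines can adopt the *syn* glycosidic conformation that the
Z helix alternates with *anti*. Each Z helix is bounded by two B–Z
junctions, each carrying an extruded base and a large fixed energy cost, so
short dispersed repeats are penalized relative to longer perfect ones.

`zflipon` predicts these segments from sequence by two independent routes
and provides the downstream analytics used to interpret them: saturation
mutagenesis maps, attention maps, genomic-feature classification, repeat
scoring, junction-motif extraction and haplotype scoring.

## The thermodynamic model

`energy_model()` assigns every dinucleotide step a B→Z flipping cost in
kcal/mol: d(CG) = 0.6, d(CA) = d(TG) = 1.34, d(GG) = d(CC) = 2.4, and a
single configurable out-of-alternation cost (default 4.0) for every other
step, plus 5 kcal/mol per B–Z junction with two junctions per segment. The
table is closed under reverse complement because the two strands of a Z
helix are equivalent.

Two published phrasings required a decision:

* **Junction penalty.** The in-vitro literature quotes the junction cost
  "per dinucleotide"; we charge 5 kcal/mol *per junction*, twice per
  segment, and expose the value as a parameter so other readings are one
  argument away.
* **Phase.** The syn–anti register of a candidate segment is not observable
  from sequence. `segment_energy()` therefore accepts a tiling phase (0
  or 1); the segment caller anchors the tiling at each candidate window
  start and enumerates both parities of start position, which covers both
  registers.

`best_z_segments()` enumerates every even-length window between
`min_helix_bp` (12, the shortest stable Z helix we admit) and
`max_helix_bp` (200) on both parities using cumulative sums, keeps windows
whose *mean step cost* (junctions excluded) is at most `z_cutoff`, and
selects non-overlapping segments best-first: lowest mean first, ties to the
longer and then the leftmost window. We deliberately chose exhaustive
enumeration over seed-and-extend heuristics: a window whose cheap ends
flank an expensive core can qualify while containing no qualifying
fixed-size seed, so heuristics can miss the global minimum that our tests
verify against brute-force enumeration. Sort keys are quantized at 1e-9 so
floating-point noise in cumulative sums cannot break exact ties between a
repeat and its sub-windows.

`z_cutoff` defaults to 1.5 kcal/mol per dinucleotide. This is a tunable,
not a measured constant: it admits d(CG)n (0.6), d(CA)n (1.34) and — at
exactly the boundary — d(CGGG)n (mean 1.5), and rejects random sequence,
matching the qualitative ranking in which even-numbered alternating repeats
score highest. The reported `energy_per_dinuc` excludes the junction terms
so that segments of different lengths are comparable; `energy_total` adds
them back.

A consequence of minimal-core selection worth knowing: for repeats at the
cutoff boundary (d(CGGG)n) and for mixed repeats, the caller labels the
minimal-energy core rather than the full planted repeat, so oracle labels
can be a few steps narrower than a planted cassette. This is intended — the
truth track is defined as what the energetics model calls, not as the
generator's plan.

## Tokenization

Each nucleotide position is represented by the 6-mer starting at it
(sliding window, stride 1), giving a vocabulary of 4^6 = 4096 content
tokens plus `UNK` (any 6-mer containing N) and `PAD`. Token *i* inherits
the label of nucleotide *i* (its first base); predictions are lifted back
by giving nucleotide *i* the probability of token *i*, with the trailing
five nucleotides inheriting the final token's value — the simplest
consistent extension, since those positions start no token. A
majority-vote labeling over the covered bases is available as an option.
`UNK` tokens are excluded from the loss and predicted as probability 0,
because the experimental training data exclude unmappable regions. Windows
are 512 tokens, tiled without overlap by default; overlapping strides
average the overlapped probabilities.

## The segmenter

The classifier is a from-scratch pre-LayerNorm transformer encoder: token
plus learned positional embeddings, multi-head self-attention with PAD keys
masked, a GELU feed-forward block, a final LayerNorm and a per-token
sigmoid head. Gradients are hand-derived and verified against central
finite differences in the test suite (agreement at 1e-6 over random
coordinates of a 2-layer model). We author the network rather than binding
a deep-learning framework so the package trains anywhere R runs.

Training follows the published fine-tuning protocol where the protocol is
scale-free: 5 stratified folds assigned at region level (no window is seen
by the member evaluated on it — a bookkeeping the tests assert), all
positive windows plus twice as many sampled negatives, 3 epochs, one-cycle
learning-rate schedule with 30% warmup, binary cross-entropy on non-PAD,
non-UNK tokens, and a 5-member ensemble in which held-out scoring uses
exactly the member that excluded the window's fold, while novel sequence
averages all members.

Two protocol values do not transfer to desk scale and were re-chosen, with
the genome-scale values still available through `segmenter_config()`:

* **Peak learning rate 1e-3** rather than the 1e-5 used when fine-tuning a
  pretrained genome language model — we train from random initialization.
* **Batch size 1** rather than 24. A desk-scale corpus is a few hundred
  windows; at batch 24 an epoch yields only ~7 optimizer steps and the
  model cannot leave its initialization in 3 epochs. One 512-token window
  already averages the token gradient over hundreds of positions, so
  single-window steps are stable; with ~450 steps the one-cycle schedule
  behaves as intended.
* **Backbone width**: 2 layers and 4 heads as designed, but 32-dimensional
  embeddings (vs the 128 a GPU-scale run would use); at 32 the five-member
  ensemble trains on the 100 kb benchmark in about six minutes on one CPU
  core, and the task loss is already near its floor.

`base_score` is the sum of the five members' probabilities at a base
(range 0–5). The published per-base aggregate it mirrors tops out near
4.45 without a printed definition; the member-sum is the simplest statistic
with that range and is configurable by post-processing since the per-member
tracks are exposed.

### Attention maps

For interpretability we report, per layer and head, the column sums of the
attention matrix — how much attention each token *receives* — and a
combined map: the mean over all layers and heads, min-max normalized per
window, thresholded at 0.2 for display masks. A constant combined map
normalizes to all zeros rather than dividing by zero. The exact aggregation
behind published attention visualizations is tool-specific; column-sum plus
min-max is declared here, not inferred.

## Saturation mutagenesis

The Z-propensity score of a window is `sum(log(1 + p))` over its
nucleotides; adding 1 keeps zero probabilities finite, and the natural log
is used (ratios are base-invariant). Every position of a target region is
substituted with the three alternative bases, each variant re-tokenized and
re-scored over the *same* fixed scoring window (default: the 512-bp tiles
covering the region), and the effect reported as the variant/reference
score ratio — above 1 means the substitution favours Z formation. Score
differences are also emitted since ratios lose the magnitude of the
reference. A reference score of exactly zero would make ratios undefined;
that case yields NA with a warning rather than an arbitrary number.

## The synthetic benchmark

`synth_genome()` emulates the statistical shape of the experimental
training data: 200 Z segments of 12–60 bp planted in a 100 kb i.i.d.
background at GC 0.41 (the genome-wide value), at least 50 bp apart, drawn
from families (CG)n (weight 0.4), (CA)n/(TG)n (0.3), (CGGG)n (0.1) and
mixed CG/CA interleavings (0.2), with a d(TAAA) motif written into the 5′
flank (and its complement into the 3′ flank) of half the segments,
mirroring the adenosine-rich junction motif seen genome-wide. Truth labels
come from the energetics oracle applied to the finished contig, so
background sequence that happens to be Z-prone is labeled consistently
rather than silently mislabeled.

What passing on this benchmark does and does not show: the generator has
i.i.d. background (no isochores, no repeat families other than the planted
ones, no chromatin context), labels are exactly sequence-determined, and
class balance is controlled. Success here demonstrates that the training
protocol, windowing, label projection and ensembling are implemented
correctly and that the model can learn a sequence-determined segmentation —
it does not certify performance on experimental Z-DNA maps, where labels
are noisy and context-dependent.

At these study conditions the five-member ensemble reaches held-out
nucleotide F1 ≈ 0.89 and AUROC ≈ 0.96 in about six minutes on one CPU
(the acceptance script recomputes both from scratch). Problem sizes in the
unit-test fixture are smaller (12 kb, 50 segments, 64-token windows,
16-dim embeddings) so the full suite stays fast.

## Downstream analytics

* **Metrics** are nucleotide-level: precision, recall, F1 (harmonic mean)
  from confusion counts at a threshold, and a rank-based (Mann–Whitney,
  midrank ties) ROC AUC, cross-checked in tests against trapezoidal
  integration and an independent implementation.
* **Feature classes** follow the seven-class scheme (Promoter ≤ 3 kb,
  5′UTR, Exon, Intron, 3′UTR, Downstream ≤ 300 bp, Distal Intergenic)
  assigned to the interval midpoint with promoter-first precedence; the
  published tables do not state a precedence, so ours is explicit and
  configurable by editing the annotation.
* **Overlap recovery** uses segment-level ≥ 1 bp intersection
  (`shared / (shared + experimental_only)`), which reproduces the printed
  recovery percentages; bp-level counts are emitted alongside because
  genome-wide coverage figures are bp-based.
* **Junction windows** are 11 nt: the boundary base ± 5, start-side
  centered on a segment's first base and end-side on its last, clipped
  windows dropped with a warning; FASTA export feeds motif discovery tools.
* **Haplotype scores** sum +1/−1 per allele by trait direction, 0 where no
  quantitative trait measure exists.
* **Percentages** reproduce printed values with half-up rounding at the
  table's precision (R's default banker's rounding would differ at .5).

## Numerical and degenerate-input choices

* All coordinates are 0-based half-open; 1-based appears only in display.
* N bases are legal, always labeled 0, never tokenized into content
  k-mers, and poison any dinucleotide step (infinite cost).
* Attention uses a scalar-max softmax stabilization with a per-row
  fallback on underflow; PAD keys get −1e9 logits.
* Empty interval sets, empty FASTA, start ≥ end BED lines, fewer regions
  than folds, a fold with no positives, and zero reference scores all
  raise typed errors or NA-with-warning rather than propagating nonsense.
* One master seed fans out deterministically to background sampling,
  segment placement, fold assignment, negative sampling, weight
  initialization and data order; identical seeds give byte-identical
  outputs.

## Known limitations

* The energetics model is a simplified scorer: no supercoiling-density
  dependence, no statistical-mechanics partition function, no
  G4-quadruplex or Z-RNA loop energetics, and a single out-of-alternation
  cost. It ranks sequences; it does not predict transition probabilities.
* The desk-scale transformer is small and trained from scratch; it will
  not match a pretrained genome language model fine-tuned on experimental
  data, and the package makes no claim that it does.
* Window-tiling predictions depend on window placement (any contextual
  model's do); overlapping-stride averaging reduces but does not remove
  the effect.

## A minimal session

```{r example}
library(zflipon)

sy  <- synth_genome(synth_spec(seed = 1))
ens <- train_segmenter(sy$genome, sy$truth, segmenter_config(seed = 2))
pr  <- predict_track(ens, sy$genome, members = "heldout")
confusion_metrics(pr, sy$truth)
roc_auc(pr, sy$truth)

seg <- call_segments(predict_track(ens, sy$genome), threshold = 0.5,
                     min_len = 12)
jw  <- junction_windows(seg, sy$genome, fasta = "junctions.fa")
```
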