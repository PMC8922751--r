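---
title: "From convolution kernels to sequence motifs: the N-adjusted transformation"
author: "convmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From convolution kernels to sequence motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convmotif)
```

## The problem

Whether a gene is transcribed is partly encoded in the sequence around its
transcription start site (TSS). `convmotif` trains a deliberately small
classifier — a single convolutional layer followed by max-pooling, dropout
and two dense layers — to predict binary expression status (expressed vs
low expressed, from an FPKM threshold of 1) from 1000-nt windows centered
on the TSS, and then reads the sequence features the model learned
directly out of its first-layer kernels. The single-layer design is the
point: with one convolutional layer, each first-layer filter is a
position-specific detector over the raw one-hot sequence, so the trained
kernel weights themselves can be reinterpreted as a motif.

## The N-adjusted kernel transformation

Input windows are one-hot encoded over five channels, A, T, C, G and N —
the fifth channel carries cryptic nucleotides (masked repeats, assembly
gaps) present in any real genome. N positions carry essentially no
information about expression, so whatever weight the N channel of a
trained kernel acquires reflects initialisation and optimisation bias
rather than sequence preference. The transformation uses that channel as a
per-position bias control. For a 5 x L kernel `O` (rows A, T, C, G, N) and
each column `j`:

1. `a[i, j] = max(0, O[i, j] - O[N, j])` for the four nucleotides;
2. if any `a[., j] > 0`, the column of the position weight matrix is
   `R[i, j] = a[i, j] / sum_i a[i, j]`;
3. if all four adjusted weights are zero — no nucleotide outscores the
   bias control — the column is set to `(0.25, 0.25, 0.25, 0.25)`,
   declaring no preference.

Two consequences are worth stating because the tests rely on them. The
transform is invariant to adding any constant to a whole kernel column
(only differences against the N entry matter), and it is monotone: raising
a nucleotide's weight never lowers its probability. Alongside the
transformation, `n_effect_ranks()` reports, per column, where the N weight
ranks among the five channels (0 = smallest, 4 = largest); columns where N
ranks high are columns where ignoring the cryptic channel would have
distorted the motif. Ties give N the lowest rank among the tied values,
deliberately under-stating N's influence.

```{r transform-example}
O <- matrix(c(0.5, 0.3, -0.2, 0.1, 0.1,   # a column with real preference
              -1,  -2,  -3,  -1,  0), 5, 2)
n_adjusted_transform(kernel_matrix(O))
n_effect_ranks(kernel_matrix(O))
```

## The model and its training

The architecture is fixed — convolution (valid, no padding) with F filters
of width L over the 5-channel input, activation, non-overlapping
max-pooling of width P (so a 1000-nt window with L = 14, P = 10 gives a
987-long convolution output and 98 pooled positions per filter), dropout,
a dense hidden layer, and a 2-unit softmax trained with cross-entropy and
Adam (learning rate 1e-3). A hyperparameter grid of 7 filter counts x 6
kernel widths x 5 pool widths (210 configurations) is evaluated by mean
fivefold cross-validation accuracy; splits hold out a stratified 20% test
set once and draw a fresh stratified validation set per fold (4000 genes
at full scale, scaled to a quarter of the non-test genes on smaller data).

Three training choices deserve explanation because the obvious defaults
fail, and they were adopted after diagnosing those failures on synthetic
data:

* **Leaky activations (slope 0.01).** With hard ReLU units, training on a
  hard two-class problem spends its first epochs on a chance-level
  plateau; during that plateau the quickest way to reduce cross-entropy is
  to shrink the logits toward zero, and the optimiser achieves this by
  driving the dense pre-activations negative. With a hard ReLU that state
  is absorbing: once every hidden unit is inactive for every input, all
  upstream gradients are exactly zero and the network can never leave
  chance level. A small leak keeps gradient flowing through inactive
  units, which removes the absorbing state.
* **Early stopping with a floor.** Validation accuracy is the stopping
  criterion (patience 10), but never before 15 epochs: the pre-takeoff
  plateau would otherwise trigger stopping on almost every run.
* **Multi-start training.** Escaping the plateau depends on whether some
  filter happens to start near enough to the discriminative motif to
  receive coherent gradient. `cnn_fit()` therefore restarts from a fresh
  initialisation (up to `max_restarts`, default 4) whenever a run finishes
  with chance-level validation accuracy, and keeps the restart with the
  best validation accuracy — the usual multi-start remedy for
  initialisation-sensitive non-convex fits.

The output layer and dense weights use Glorot initialisation and the
convolution He initialisation; batch size defaults to 32. All randomness
(initialisation, shuffling, dropout) runs through R's RNG, so fits are
exactly reproducible under a seed.

## Interpretation beyond the kernels

For per-position evidence, `attribution()` implements the rescale rule on
the conv/pool/dense stack against an all-zeros one-hot reference (no
letter present anywhere). The attributed score is the expressed-minus-low
logit difference, which keeps the stack piecewise-linear; max-pooling
routes each pooled delta to the actually pooled position. Because the
zero-input reference makes the reference convolution output constant per
filter, per-window attributions sum *exactly* to the difference in score
between the window and the reference (summation-to-delta), which the tests
assert at 1e-4 relative tolerance. The choice of the all-zeros reference
is ours and is exposed in the interface (`reference = "input"` gives the
identity check; `method = "gradient_input"` gives a gradient-times-input
fallback without the summation guarantee). Reporting splits the
class-averaged map into the TSS ± 10 nt block and the rest, since the
extreme values right at the start site otherwise dominate the display.

## Motif calling, scanning and validation

Transformed kernels from the five cross-validation models are matched
against a reference motif library with `pwm_similarity()` — the maximum
Pearson correlation between flattened overlapping sub-matrices over all
ungapped offsets with at least 4 overlapping columns (default match
threshold 0.8). A motif matched in at least two of the five models is a
*common* motif; matched in exactly one, *specific*. Unmatched motifs are
de-duplicated greedily in input order at the same similarity threshold to
give a non-redundant novel set. `write_meme()` exports any motif set in
MEME minimal format (cells quantised to six decimals with
largest-remainder rounding so every written column sums to exactly
1.000000 and round-trips within 1e-6) for external alignment tools.

`scan_motifs()` scans windows on the forward strand only, scoring log-odds
against the background with pseudo-count 1e-3; N contributes 0 bits, so
N-padded window edges neither create nor destroy hits. P-values are exact:
the null score distribution is computed by dynamic programming over
per-column integerised scores (1000 bins), which the tests verify against
full enumeration of all 4^w background words for short motifs.
Benjamini-Hochberg q-values are computed per motif across all (window,
offset) tests and hits are kept at q <= 0.1.

`svm_evaluate()` closes the loop: motif-occurrence counts per gene feed an
rbf-kernel SVM (cost 1, gamma 1/(n_features x var)) that re-predicts
expression status and reports accuracy, precision, recall and F1 with
expressed as the positive class, reusing the classifier's test partition.
`svm_compare()` runs two motif sets (e.g. kernel-transformed vs an
external library) through the identical split so the four metrics are
directly comparable; it does not decide a winner.

## The synthetic benchmark: what it emulates and what it does not

Real expression-labelled promoter data requires a genome assembly and an
RNA-seq series, so the package ships a generator whose output is the
self-contained test bed for every stage: two balanced classes of windows over
{A, C, G, T, N}, i.i.d. background letters (uniform by default), a
configurable fraction of cryptic N positions (default 1%, roughly the
masked fraction of promoter regions in a repeat-masked genome assembly;
planted motif positions are exempt), and class-conditionally planted PWM
motifs with per-window insertion probabilities, uniform or Gaussian
placement, forward strand only, never straddling the window edge. A
matching synthetic FPKM table (expressed genes > 1 at every timepoint, low
genes <= 1, an optional conflict fraction with mixed status) exercises the
labelling and trimming rules. Per-gene random sub-streams derived from one
global seed make every record reproducible independently of generation
order.

The canonical benchmark (`planted_tss_benchmark()`) plants one sharp
TATA-box-like width-10 motif (consensus CTATAAATAG, consensus probability
0.95 per column) at a near-fixed TSS-relative position (Gaussian start
offset 465 ± 5 nt, i.e. just upstream of the TSS at offset 500, the way
core promoter elements such as the TATA box occupy essentially fixed
positions) in 90% of expressed and 5% of low-expressed windows. Positional
concentration is not cosmetic: a single weak-rate motif placed uniformly
over all ~990 offsets of a 1000-nt window is unlearnable at a few thousand
training sequences by *any* classifier operating on locally pooled
positional features — a cross-validated lasso probe on the pooled features
of random filters sits at exactly chance — and positionally structured
occurrence is also what real promoter motifs show.

Two quantitative limits of these conditions are worth making explicit.
With presence rates 0.9 vs 0.05, class and motif presence are not
deterministic, so no classifier can exceed an accuracy of
0.5·0.9 + 0.5·0.95 = 0.925 or an AUROC of about 0.9275 (the tie mass
between with-motif and without-motif windows of opposite classes is
irreducible). The cross-validated model reaches mean accuracy ≈ 0.88 and
AUROC ≈ 0.91 — close to the empirical ceiling of a PWM-scan oracle that
knows the planted motif (~0.91) — and recovers the planted PWM among its
transformed kernels at similarity ≥ 0.8 in all five folds. What passing
these tests shows is that the pipeline detects and faithfully extracts a
planted, positionally coherent signal; it does not show that the
generator's i.i.d. background reproduces the composition, repeat
structure, or multi-motif grammar of real promoters, and performance
numbers on it do not transfer to real genomes.

## Numerical choices and degenerate inputs

* Pooling floors away a partial final block (`floor(conv_len / pool)`),
  matching the valid-convolution / non-overlapping-pooling arithmetic used
  throughout.
* `pwm_similarity()` skips offsets where either overlapping sub-matrix is
  constant (correlation undefined); if every offset is degenerate it
  returns 0 with a flag rather than NA.
* The scanner clamps the integerised N score into each column's achievable
  range so N-containing windows always index the null distribution;
  p-values for such windows are exact up to one discretisation bin.
* `label_stage()` uses a strict threshold (FPKM exactly 1 is low, per the
  labelling rule's wording), trims missing values with a recorded reason,
  and partitions genes into expressed / low / trimmed with no overlap.
* One-class evaluation sets yield accuracy with `auroc_defined = FALSE`
  instead of an error; AUROC uses midranks, so all-tied scores give 0.5.
* Zero-column feature matrices (no motif ever hit) fall back to a single
  all-zero feature and are flagged `degenerate` rather than crashing the
  SVM.
* TSS coordinates are 1-based on input; internally the window covers
  transcription offsets [-500, 500) so the TSS base itself is the first
  downstream base, at 0-based offset 500. Positions beyond a contig edge
  are N-padded. Soft-masked (lower-case) letters are uppercased; IUPAC
  ambiguity codes map to N.

## Known limitations

* The stage-to-timepoint assignment of a real FPKM series is a required
  configuration input; the package does not infer it.
* The in-core motif matcher is a correlation-based stand-in for dedicated
  alignment tools; `write_meme()` exists precisely so transformed motifs
  can be re-aligned externally, and match thresholds are exposed rather
  than hard-coded.
* Training a 24-filter model on ~2,000 windows takes a couple of minutes
  on one CPU; grid searches at that scale multiply this by 210 and are
  meant for real datasets or patient users — the tests exercise the grid
  machinery on miniature data.
* The attribution implementation covers this package's own architecture
  only; it is not a general-purpose attribution engine.
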