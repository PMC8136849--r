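---
title: "Frame pooling for length-agnostic mean ribosome load prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame pooling for length-agnostic mean ribosome load prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(framepoolr)
```

## The problem

The 5' untranslated region (5'UTR) of an mRNA controls how efficiently
ribosomes initiate translation. Massively parallel reporter assays (MPRAs)
measure a mean ribosome load (MRL) — the average number of ribosomes bound,
read off a polysome profile — for hundreds of thousands of random 5'UTRs,
and convolutional networks regress MRL on sequence very accurately. But a
convolutional stack followed by a flatten-and-dense head is locked to the
training length: human 5'UTRs range from a handful of nucleotides to
thousands, so a fixed-length model must truncate most of them.

The obstacle to simply replacing the dense head with global pooling is the
reading frame. An upstream AUG is far more disruptive when it is
*out-of-frame* with the canonical coding sequence than when it merely
extends the protein N-terminally, and frame is defined by distance to the
canonical start codon *modulo 3* — exactly the information global pooling
destroys.

## Frame pooling

`framepoolr` centres on a pooling operation that keeps that one bit of
structure and nothing else. With the 5'UTR written 5'→3' and its 3' end
abutting the canonical start, position `i` (0-based) of a length-`L`
sequence has frame `(L - i) mod 3` (`frame_index()`); a codon starting at
`i` is in-frame iff this is 0. The feature map of the last convolutional
layer is reversed along the position axis — anchoring indices at the 3'
end, so the operation is independent of `L` — sliced into the three
frame classes, and each slice is reduced by masked global max *and* average
pooling. The six blocks are concatenated as
`[max f0 | max f1 | max f2 | avg f0 | avg f1 | avg f2]`. For a 300-position,
128-filter map this yields three 100×128 slices and a 768-vector.

Max pooling answers "is this motif present in this frame anywhere?";
average pooling answers "how much of it, per position?". Because the
pooled width is `6F` for every `L`, the same weights serve any sequence
of at least 3 nt.

Two numeric conventions matter and are fixed here:

* **Masking is exclusion, not down-weighting.** Batches of mixed lengths
  are padded with all-zero rows at the 5' end; padded rows are excluded
  from max pooling entirely and from the average's numerator *and*
  denominator. Convolution biases make padded positions nonzero after the
  first layer, so anything softer breaks the padding-invariance guarantee.
  We additionally re-zero padded rows after every convolutional layer, which
  makes predictions *bitwise* identical under any amount of 5' padding
  (adding a zero term to a dot product is exact in floating point).
* **Empty frames pool to 0** (both statistics). Only sequences shorter
  than 3 nt can produce one; the convention matches the padding value and
  keeps the operation total.

A deliberately naive per-position loop implementation
(`frame_pool_oracle()`) ships alongside the vectorised `frame_pool()` and
the two are held equal on a thousand random masked instances in the test
suite.

## Architecture and training

The main preset (`preset_config("framepool")`) is three same-padded
convolutions (128 filters, kernel 7, ReLU), identity residual additions
wherever channel counts match (so between the second and third layers but
not across the 4→128 input layer, where a projection would add weights),
frame pooling, a 64-unit ReLU dense layer with dropout 0.2 on its outputs,
and a linear scalar head: 282,625 weights in total, receptive field 19 nt.
The residual additions are applied post-activation; the alternative
(pre-activation) placement is weight-count-neutral and we observed no
reason to prefer it. Frame-unaware baselines replace frame pooling with
plain masked global pooling (`global_pool`), optionally with dilations
(1, 2, 4) or an extra dilation-8 layer (receptive fields 43 and 91), and
k-mer random forests (framed features: per-frame counts, `3·4^k` long)
complete the comparison set.

There is no deep-learning framework dependency: the engine is
double-precision base R. Convolutions are evaluated as one BLAS GEMM per
layer on an im2col layout, with backpropagation (including input
gradients, verified against central finite differences) written out
explicitly. Initialisation is Glorot-uniform from an explicit seed; biases
start at zero.

Training follows the MPRA protocol: Adam with default parameters
(learning rate 0.001, β₁ 0.9, β₂ 0.999), mean-squared-error loss,
mini-batches of 128 padded to the longest sequence in the batch. Two modes
are supported: early stopping that returns the weights of the epoch with
the lowest validation MSE after `patience` non-improving epochs
("improvement" is strictly lower loss — the simplest reproducible rule),
and fixed-epoch training without a validation set. Two-library training
(`train_combined()`) shares the trunk and adds a per-library affine
`(scale, bias)` on the scalar output — 4 extra weights for two libraries —
shuffling both libraries together within each epoch; library 0's scale
initialises at 1 and bias at 0. Length bucketing is available as an
efficiency toggle; padding invariance makes it output-neutral.

## The leaky-scanning simulator

Real MPRA data cannot ship with a package, so `framepoolr` generates its
own study conditions with an explicit generative model of the biology the
method targets (`simulate_mpra()`). A scanning ribosome moves 5'→3'. At
every AUG/CUG/GUG it initiates with probability

&nbsp;&nbsp;`p = plogis(a · context + b) · strength(codon)`

where `context` is a position-weight-matrix score of the −6..+5 Kozak
window. The default PWM puts all its weight on the two positions that
dominate initiation in vivo — A/G at −3, G at +4 — and the codon strengths
order AUG (1.0) ≫ CUG (0.3) > GUG (0.15). Initiating at a uORF (a uTIS
with an in-frame stop before the canonical start) reinitiates downstream
with probability 0.5 or drops off at mean load `mu_uorf = 1`; initiating
at a non-uORF uTIS is absorbing and yields `mu_main = 6` in-frame (an
N-terminal extension behaves like canonical initiation) or `mu_oof = 2`
out-of-frame; mass that reaches the canonical start yields `mu_main`.
`oracle_mrl()` returns the exact expectation of this process; datasets add
Gaussian noise (σ = 0.3, a small fraction of the ≈1.1 MRL standard
deviation at 50 nt, giving a correlation ceiling near 0.96) and an
optional per-library affine. Candidate uTIS are processed strictly in
scanning order with no re-scoring after absorption.

Defaults were chosen once, for realism of *structure* rather than
calibration: the simulator reproduces the qualitative phenomena the
architecture exploits (frame-dependent uAUG penalties, Kozak-strength
leakiness, uORF reinitiation) but not secondary structure, IRES elements,
length effects, nucleotide-composition biases of real libraries, or
measurement error correlated with expression. Passing the recovery tests
therefore shows the *method* can learn frame-dependent regulation from
sequence, not that the trained toy weights transfer to real 5'UTRs.

Because the oracle is an exact, pluggable predictor (`oracle_predictor()`
implements the same `mrl_predict()` interface as a trained model,
including simulated frameshifts and library affines), every downstream
pipeline — variant scoring, TIS benchmarking, saturation mutagenesis — can
be tested against hand-computed expectations without trained weights.

## Problem sizes

The shipped experiments use sizes chosen to make every property sharply
testable on a desktop: the simulator-recovery experiment trains the full
282,625-weight preset and its global-pooling counterpart for three epochs
on 20,000 simulated 50-nt sequences (σ = 0.3) and evaluates on 2,000
held-out sequences; the k-mer random forests (100 trees) use 8,000
training sequences; property suites use reduced-width models of the same
topology (8–32 filters), which exercise identical code paths.

## Variant effects

`run_vcf_pipeline()` mirrors the standard genomics contract: BED (0-based
half-open, name = transcript id) defines spliced 5'UTR exons, FASTA the
reference, VCF (1-based, multi-allelics split) the variants. Exons are
concatenated in genomic order and reverse-complemented for minus-strand
transcripts; variants are injected right-to-left in spliced coordinates so
indels never displace one another; REF alleles are verified against the
genome. Variants spanning an exon boundary are rejected rather than
truncated (partial application is biologically ill-defined), as are
overlapping variants within one transcript (injection order would silently
change results). Each transcript×variant pair is scored as
`log2(MRL_alt / MRL_ref)`, plus the same score after appending one and two
*masked* zero positions to the 3' end of both sequences. The shift
displaces every real position's frame — zero-padding, not real bases, so a
predictor that honours the mask sees only the frame change — and exposes
variants whose unshifted effect vanishes because they act within the
canonical frame (in-frame uAUG creation lengthens the protein instead of
disrupting it; under the oracle its unshifted score is exactly 0 while the
shifted scores drop to `log2(2.4/6)`).

## TIS strength scoring

`predicted_tis_effect()` embeds a start-codon context (−6..+5 window for
AUG, −3..+4 for alternative codons) out-of-frame in random backgrounds
sized to the model's receptive field and averages
`predict(active)/predict(AGG-deactivated)` over 100 seeded backgrounds.
Three underdetermined choices are fixed and documented: the codon sits in
the +1 frame for every context (any fixed out-of-frame choice removes a
confounder); backgrounds are uniform over A/C/G/U (the assays used random
flanks of unstated composition); and the average is taken over plain fold
changes, the literal reading of "difference in terms of fold change",
with log-scale (geometric) averaging exposed as an option. Contexts whose
window contains an unintended AUG — in active or deactivated form — are
excluded, since the selected start codon would be ambiguous.
`tis_benchmark()` correlates the scores with measured strengths; strong
contexts repress, so meaningful correlations are negative.

## Interpretation and evaluation utilities

Contribution scores are exact input gradients (`raw_gradient`) or
gradient×input (zero off the one-hot support); both come from the same
backward pass that trains the network and are tested against central
finite differences at 10⁻³ relative tolerance. Saturation mutagenesis
scores all `3L` single-base substitutions and summarises positions by the
mean *absolute* log2 fold change, treating up- and down-regulation
uniformly. `bootstrap_compare()` implements paired model comparison:
correlation differences over joint resamples, an interval of
±`multiplier`·SD (SDs, not SEs — more replicates should not manufacture
significance), with 3.54 as the default multiplier used for
multiple-testing-corrected comparisons; the multiplier is a direct
parameter because its derivation from (α, number of tests) does not
reconcile cleanly, and honouring the published constant is less surprising
than silently recomputing a different one. Preprocessing formulas for
endogenous data (TE = RPF/RNA with a minimum-read filter, TPM filtering
then replicate averaging, per-tissue medians, polysome-fraction MRL as the
abundance-weighted mean ribosome number) are pure functions with explicit
exclusion flags.

## Known limitations

* The receptive field bounds the uORF span the convolutional stack can
  see as a unit (19 nt for the main preset); longer uORFs are seen as a
  disjoint uTIS and stop.
* Pooling discards the 5'→3' *order* of uTIS, which leaky scanning in
  principle cares about; the simulator's sequential absorption is exactly
  the mechanism such a model cannot fully replicate.
* The engine is CPU-bound R + BLAS: adequate for the shipped problem
  sizes, not for multi-hundred-thousand-sequence assays.
* The max-pool subgradient at exactly tied activations (common at ReLU
  zeros) follows the first-argmax convention; gradient checks avoid
  degenerate, exactly-periodic inputs for this reason.
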