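# framepoolr

Predicting mean ribosome load (MRL) from 5'UTR sequences of **any length**
with frame-aware pooling — together with the machinery a translation
researcher needs around such a model: a leaky-scanning simulator with an
exactly solvable oracle, a VCF/BED/FASTA variant-effect pipeline with
simulated-frameshift scores, upstream start-codon (uTIS) strength scoring,
gradient-based interpretation, and bootstrap model comparison.

## The idea

MRL — the average number of ribosomes loaded on an mRNA, measured by
polysome profiling in massively parallel reporter assays — is predictable
from 5'UTR sequence with convolutional networks, but a flattening dense
head pins the model to one sequence length. Replacing it with global
pooling frees the length but destroys the single most important piece of
positional structure in translation: the **reading frame**. An upstream
AUG at distance *d* from the canonical start codon is benign when
`d mod 3 == 0` (it merely extends the protein) and disruptive otherwise.

Frame pooling keeps exactly that bit. For a position `i` in a UTR of
length `L` the frame is `(L - i) mod 3`, anchored at the 3' end where the
UTR meets the start codon. The last convolutional feature map is reversed
along the position axis, sliced into the three frame classes, and each
slice is reduced by masked global **max** and **average** pooling:

```
conv output (L x F) --reverse--> slice by index mod 3
  -> [max f0 | max f1 | max f2 | avg f0 | avg f1 | avg f2]   (6F, any L)
```

The main preset is three kernel-7, 128-filter convolutions with identity
residual additions, frame pooling (768-vector), a 64-unit dense layer with
dropout 0.2 and a linear head — 282,625 weights, receptive field 19 nt.
Batches mix lengths freely: sequences are zero-padded at the 5' end and
masked, and predictions are bitwise invariant to the padding.

There is no deep-learning framework underneath: the package implements
the convolutions (as per-layer BLAS GEMMs), backpropagation, Adam and the
masked pooling in double-precision R, including exact input gradients for
interpretation.

## Worked example

Architecture arithmetic is exact and checkable by hand:

```r
count_parameters(preset_config("framepool"))
#> [1] 282625
receptive_field(preset_config("dilated"))   # kernel 7, dilations (1,2,4)
#> [1] 43
```

The simulator generates MPRA-like data from an explicit leaky-scanning
model; the full preset trained on 20,000 simulated 50-nt sequences
recovers it well (held-out n = 2,000):

```r
train <- simulate_mpra(20000, 50, seed = 701)
test  <- simulate_mpra(2000, 50, seed = 702)
fit <- train_mrl(train, build_model("framepool", seed = 42),
                 max_epochs = 4, patience = NULL, val_count = 2000,
                 seed = 42, verbose = TRUE)
#> epoch 1: train 1.9789 val 1.3079
#> epoch 2: train 1.0523 val 0.4701
#> epoch 3: train 0.5705 val 0.2970
#> epoch 4: train 0.5251 val 0.2888
cor(predict_mrl(test, fit)$mrl_pred, test$mrl)
#> [1] 0.8941426
```

(The same run with conventional global pooling reaches r = 0.76, and a
framed 4-mer random forest beats an unframed one 0.78 to 0.67 — frame
information is what the architecture is buying.)

Variant effects, with the simulator oracle plugged in as the predictor
(initiation probability fixed at 0.9 so every score is hand-computable;
`write_toy_fixtures()` generates the genome/BED/VCF):

```r
fx <- write_toy_fixtures(tempfile())
orc <- oracle_predictor(scanning_params(init_slope = 0,
                                        init_intercept = qlogis(0.9)))
run_vcf_pipeline(fx$vcf, fx$bed, fx$fasta, orc)
#>   transcript_id      variant_id mrl_ref mrl_alt log2fc log2fc_shift1 log2fc_shift2
#> 1           TX1       tx1_multi       6     6.0  0.000         0.000         0.000
#> 2           TX1       tx1_multi       6     6.0  0.000         0.000         0.000
#> 3           TX1     tx1_oof_aug       6     2.4 -1.322        -1.322         0.000
#> 4           TX2 tx2_inframe_aug       6     6.0  0.000        -1.322        -1.322
#> 5           TX3   tx3_minus_aug       6     2.4 -1.322        -1.322         0.000
```

Reading the table: `tx1_oof_aug` creates an out-of-frame uAUG, so MRL
drops from 6 to `0.9*2 + 0.1*6 = 2.4` (log2 fold change −1.322); shifting
the frame by 2 places it in-frame and the penalty vanishes.
`tx2_inframe_aug` creates an **in-frame** uAUG — invisible in the
unshifted score but strongly negative after the simulated frameshift,
which is exactly how such protein-lengthening variants are flagged. `TX3`
is the same UTR encoded on the minus strand and scores identically.

A thin command-line wrapper over the same functions ships in
`inst/cli/framepoolr.R` (`simulate`, `train`, `predict`, `score-variants`,
`tis-benchmark`, `interpret`, `compare`, `make-fixtures`).

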