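---
title: "Methods: fused sequence and graph channels for affinity regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused sequence and graph channels for affinity regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

dtafuse regresses a real-valued binding affinity — pKd for Davis-style
data, a KIBA score, or any other dataset-native scale — from a pair of
strings: a compound SMILES and a protein amino-acid sequence. The model
represents the drug twice (as a character sequence and as a molecular
graph), the protein once (as a character sequence), and learns the
drug-protein interaction explicitly through cross-attention rather than by
concatenating independent embeddings.

## Input encodings

**Label encoding.** Each modality has a fixed token dictionary (64 SMILES
characters; 22 protein characters = the 20 standard amino acids plus X and
U), with codes assigned in insertion order from 1; 0 is the padding code.
Sequences are truncated to `drug_max_len` / `protein_max_len` (defaults
100 and 1000, conventional for this task family; these only control
truncation) and right-padded. Dictionaries are plain data: they can be
exported and re-imported as two-column TSV, and user-supplied dictionaries
are accepted anywhere a default one is used.

**Molecular graphs.** SMILES are parsed with OpenBabel (via ChemmineR)
into heavy-atom graphs: one node per non-hydrogen atom, one undirected
edge per bond, no bond labels (the graph layers use only adjacency). Each
atom carries 10 descriptors: symbol (one-hot, 44 symbols + other), atomic
number, hybridization (one-hot over SP/SP2/SP3/SP3D/SP3D2/other), heavy
degree, chirality (one-hot), formal charge, aromaticity, bonded hydrogens,
explicit and implicit valence. Aromaticity is decided by a Hückel-style
test on perceived rings of size 5-6 (every ring atom contributes either a
ring double bond or, for N/O/S, a lone pair; 4n+2 pi electrons);
hybridization and hydrogen counts follow standard valence rules applied to
the kekulized bond orders. Ring systems with exocyclic carbonyls are a
known gray zone where published toolkits disagree; the test suite pins the
cases where the models agree.

## Architecture

**Sequence channels (drug and protein).** Embedding (dimension `embed_dim`,
padding row frozen at zero) followed by `length(filters)` blocks of
same-padded 1D convolution (stride 1) + ReLU + squeeze-and-excitation. The
SE gate squeezes a feature map to per-channel means, passes them through a
bottleneck of reduction ratio `r` (`sigmoid(W2 relu(W1 z))`, no biases) and
rescales each channel; with zero gating weights the block halves its input
exactly, a property the tests assert. Pad positions are re-zeroed after
every block and excluded from the squeeze mean, so padding can never leak
into gates, pooled vectors, or attention — appending padding to a sequence
leaves every output unchanged to 1e-6.

The channel-attention equations pool the feature map globally, while the
interaction module consumes position-resolved maps. The single consistent
reading, and the one implemented, is that the encoder exposes the
length-resolved map and global max pooling happens only at the fusion
stage.

**Graph channel.** A stack of `gin_depth` graph isomorphism network
layers: aggregation `(1 + eps) * own + sum(neighbours)` (eps learnable,
initialized 0), a two-layer perceptron, node-level batch normalization
(statistics over all nodes in the batch per channel), ReLU. The graph-level
vector concatenates per-layer sum readouts — the canonical injective
readout, which also satisfies the final-layer projection form — and
projects them through linear + ReLU + dropout. The last layer's
post-activation node features `F` feed both the attention module and
attribution. Dropout is applied to the graph vector (after projection), not
per node.

**Interaction.** Two cross-multi-head attention blocks share the protein
keys: queries come from the drug SMILES features (block 1) and the atom
features `F` (block 2). Each block applies a ReLU projection into width
`la`, per-head linear maps, and scaled dot-products with the printed scale
`sqrt(d_in / h)` (the conventional `sqrt(d_head)` is available via
`scale_by = "head"`). The per-head attention maps are averaged and
decoupled into position weights: row sums give one drug weight per SMILES
position and one per atom (the two drug representations differ in length,
so a single shared weight vector cannot type-check; branch-specific weights
are the implemented resolution), and column sums of the row-concatenated
maps give the protein weight. Because softmax rows sum to one, the drug
weights are identically 1 — the drug representations pass to pooling
unattenuated — while the protein weight genuinely concentrates on attended
columns. Normalizing the sums into means was considered and rejected: it
rescales every fused segment by 1/length, which empirically starves the
sequence channels of gradient relative to the unscaled graph vector and
stalls learning at desk scale (any *fixed* rescaling, by contrast, is
absorbed by the regression head). The value-weighted attention outputs cannot be consumed by this
row/column decoupling (their shape has no protein axis), so the fitted
model does not parameterize value/output projections — the standalone
`multi_head_cross_attention()` operation implements the full Q/K/V form.

**Fusion and head.** Each weighted representation is global-max pooled over
its valid positions and the three pooled vectors are concatenated into the
interaction vector; the outer average pool of that vector has window one
and is the identity. The graph-level GIN vector is concatenated alongside
the interaction vector before the regression head — it is defined as the
drug-graph representation feeding prediction, and would otherwise be
disconnected. The head is a stack of affine layers (defaults 1024/1024/512,
each + ReLU + dropout) ending in one linear output.

## Training

Adam on the mean squared error at the configured learning rate, batch size
and epoch count; per-epoch training MSE (from the training passes) and
validation MSE (evaluation mode) are logged, and the returned checkpoint is
the one with the best validation MSE. The regression target is centred on
the training-set mean (the offset is stored in the model and restored at
prediction time), and the output layer is initialized at a twentieth of
the usual He scale, so optimization starts at the mean-prediction
baseline; without these, a randomly initialized network spends
thousands of optimizer steps just travelling to the label scale. All
randomness — initialization, batch order, dropout — derives from one seed,
and two runs with the same seed produce identical loss curves.

Dataset presets fix the published hyperparameter columns (embedding 128,
filters 16/32/48 or 32/64/96, GIN depth 5 within the designed 3-7 range, 8
heads, head widths 1024/1024/512, dropout 0.2, learning rate 1e-4, 600
epochs, batch 512/1024). The `synthetic` preset is the desk-scale
configuration the package's own tests run: the same architecture at small
widths (embedding 16, filters 8/16/16, GIN depth 3 x 32, 2 heads, head
64/32, learning rate 1e-3, batch 32, sequence lengths 60/120), sized so
the planted-signal experiments below complete in minutes on one CPU.

Five-fold cross-validation over the non-test portion is available
(`kfold_affinity()`) alongside the default fixed seeded split; the split is
by interaction record, with the fractions 4/6-1/6-1/6 that reproduce the
conventional benchmark partition to within one record by largest-remainder
rounding. Cold-drug or cold-target splitting is deliberately not the
default, matching the record-level protocol of the benchmark tables.

## Metrics

Mean squared error, concordance index (pairwise, over ordered pairs with
distinct labels; tied predictions credit 0.5), the rm-squared
external-validity index, and Pearson correlation. rm-squared is computed
as `r2 * (1 - sqrt(r2 - r02))` with `r2` the squared correlation of the
intercept fit and `r02` the through-origin coefficient of determination;
a transcription of the index sometimes renders the correction linearly
(`1 - r2 - r02`), which goes negative for perfect fits — that form is kept
behind `variant = "printed"` for auditability but is not the metric. The
concordance index is verified against a brute-force O(n^2) oracle, its
invariance under strictly increasing transforms is asserted, and the mean
over 1000 random shuffles at n = 200 is required to sit in [0.49, 0.51].

## Synthetic data: what it emulates and what it does not

`synthetic_spec()` generates triplets with a *planted interaction*: drugs
are concatenations of 2-4 chain-safe SMILES fragments, with an amide
fragment (`C(=O)NC`) inserted into half of them; proteins are uniform
random 100-mers over the 20 amino acids, with an 8-residue motif written
into half; affinity = 5 + 2 x 1[pharmacophore AND motif] + N(0, 0.3). The
indicator is recomputed from the emitted strings, so it stays truthful on
accidental occurrences, and the heavy-atom indices of the planted fragment
are recorded — attribution can therefore be scored against a known ground
truth, which no real affinity dataset provides. Defaults (n = 2000, effect
2, noise 0.3, balanced planting) were chosen once as a realistic
desk-scale signal-to-noise regime: the effect is ~6.7 noise SDs, but only
a quarter of records carry it, and the model must learn a conjunction, not
a main effect.

One consequence of the two-valued generative signal deserves emphasis: the
concordance index of *any* predictor is bounded. Pairs from the same
affinity cluster differ only by independent noise, which no function of
the inputs can rank, so the expected CI is at most
`1 - 0.5 * (p^2 + (1 - p)^2)` at co-occurrence rate `p` — about 0.69 at
the balanced defaults (p = 0.25), and never above 0.75 for any p. A model
that predicts the learnable component perfectly (test MSE at the noise
floor, Pearson above 0.9) therefore sits near CI 0.69 on this data; on
real, continuously distributed affinities the same model family is not
subject to this ceiling. The test suite asserts the attainable properties
(MSE near the noise floor, high Pearson, attribution localization) and
records the CI it reaches.

What the generator does *not* emulate: real binding chemistry (affinity is
a substring indicator, not physics), realistic protein sequence statistics
(no homology structure), dataset bias such as the censoring floor of
Davis-style Kd panels, or drug-likeness of the molecules. Passing the
signal-recovery tests therefore demonstrates that the architecture,
gradients and training loop work end-to-end and that attribution localizes
a known cause — not that benchmark-level accuracy on real data is
reproduced, which requires the full datasets and long GPU training and is
out of scope here.

## Attribution

Grad-AAM: the gradient of the (single-pair, evaluation-mode) prediction is
backpropagated to the last GIN layer's node features; channel weights are
the node-averaged gradients, the raw map is the ReLU of the
gradient-weighted feature combination, and scores are min-max normalized
to [0, 1]. A constant raw map normalizes to all-zeros with a warning
rather than dividing by zero. Atoms at or above 0.5 normalized score (a
configurable threshold; the selection rule is not fixed by the method's
definition) constitute the top-contributing set used by `overlap_rate()`,
the mean per-molecule fraction of reference site atoms recovered.
Atom-level counting is used; functional-group-level counting would be a
straightforward extension.

## Numerical choices

* All forward/backward passes are hand-written matrix code; every layer's
  gradient is checked against central finite differences in the test suite
  (relative tolerance 1e-3 at step 1e-6).
* Softmax rows are computed with max-subtraction; fully masked query rows
  are an error, masked keys get exactly zero mass.
* Batch normalization uses population statistics of the current batch in
  training (momentum 0.1 running updates) and running statistics in
  evaluation; a single-node batch falls back to running statistics.
* Global max pooling breaks ties by first index (R's `which.max`), making
  evaluation bit-reproducible.
* Convolution uses same-padding with the left offset `floor((k-1)/2)`.
* The padding embedding row is pinned to zero by zeroing its gradient.

## Known limitations

* Attention is looped per sample and per head in R; throughput is adequate
  for desk-scale experiments (thousands of records) but far from a GPU
  implementation — full benchmark training is explicitly out of scope.
* OpenBabel's SMILES chemistry differs from RDKit's in aromaticity corner
  cases (exocyclic-carbonyl rings); descriptors are deterministic but not
  bit-identical to an RDKit featurizer.
* Proteins are sequences only; no structural or pocket information enters
  the model.
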