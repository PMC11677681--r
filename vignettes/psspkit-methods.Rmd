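---
title: "Models and methods in psspkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in psspkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

psspkit is a desk-scale implementation of a protein secondary structure
prediction (PSSP) framework built around two ideas: a *highly targeted
autoencoder* that learns a compact per-residue encoding shaped by
secondary-structure segments, and a *multi-task* predictor that shares
parameters between the structure task and a binary solvent-accessibility
task through a multi-gate mixture of experts. This vignette explains the
models, the choices made where the design was genuinely open, and what the
synthetic data used throughout the tests does and does not establish.

## Alphabets, labels and records

Residues are letters of a fixed 21-letter alphabet: the 20 standard amino
acids plus `X`, onto which every non-standard letter (B, J, O, U, Z,
anything else) is normalized. Secondary structure uses the eight DSSP
states H, G, I, E, B, T, S, L, reduced to three states by H,G,I → H (helix),
E,B → E (strand) and T,S,L → C (coil). A corpus is a tibble with one row per
chain (`id`, `sequence`, optional `ss8` labels, optional per-residue `rsa`
fractions); all per-residue tracks must match the sequence length exactly.
Internally positions are 1-based inclusive, the native R convention; the
segment table returned by `extract_segments()` carries `start`, `end`,
`length` per maximal single-category run.

## Evaluation metrics

`q_accuracy()` is the percentage of correctly labeled residues; over a test
set it pools counts (total correct over total residues) rather than
averaging per-sequence values, so long chains weigh more — the convention
implied by defining the score through a single global residue total.

`sov()` implements the segment-overlap score. For every category, each
observed segment `s1` is compared with the same-category predicted segments
`s2` that overlap it; each pair contributes
`(minov + delta)/maxov * l(s1)` where `minov` is the overlap length,
`maxov` the extent of the union, and
`delta = min(maxov - minov, minov, floor(l(s1)/2), floor(l(s2)/2))`.
The normalizer adds `l(s1)` once per overlapping pair plus the lengths of
observed segments with no same-category overlap. Two reading-level choices
are fixed here: `l/2` uses integer floor (the convention of the metric's
reference definition), and categories absent from the observed labeling
contribute nothing (sums over empty sets). Both pooled and per-pair
behaviour are tested against an independent brute-force transcription that
manipulates explicit residue position sets, exhaustively for all label
pairs up to length 8 over two categories and on random 8-category pairs.

Boundary residues are sequence ends (type 1), interior residues whose two
flanks disagree (type 2), and interior residues that differ from their
agreeing flanks (type 3); types 2 and 3 apply only where both neighbours
exist, so a length-2 sequence has exactly two type-1 boundary residues.
`boundary_accuracy()` is `q_accuracy()` restricted to the boundary mask of
the observed labeling.

## The association analysis

The multi-task design rests on the association between secondary structure
and relative solvent accessibility (RSA = ASA normalized by the residue
type's maximum, clipped to [0, 1]). RSA is binarized at 0.15 — inclusive on
the buried side — and tallied into a 2 × 8 contingency table against the
8-state category. Cramer's V is computed with expected counts
`E_ij = sum_i sum_j / n` and `V = sqrt(chi^2 / (n * min(m-1, n-1)))`;
margins are always recomputed from the cells, and zero-margin rows or
columns are dropped from the chi-square sum with a warning (a rare category
can be entirely absent from a small corpus). The package ships a published
reference tally of about 6.03 million residues as a plain CSV; on it V
evaluates to 0.2264 — a moderate association, which is exactly the regime
where *soft* parameter sharing (MMoE) is preferable to hard sharing.
The shipped maximum-ASA and 7-descriptor physicochemical tables (sheet and
helix propensity, isoelectric point, hydrophobicity, van der Waals volume,
polarizability, graph shape index) are standard literature scales stored as
replaceable CSVs; no computation in the package depends on their specific
numeric values, only on the lookup contract.

## The highly targeted autoencoder

The encoder chains `A` residual dynamic-convolution blocks (default
`A = 2`, the smallest depth that exercises chaining). A block holds `B`
candidate filters (default 3). The input batch is globally average-pooled
over valid positions, passed through a kernel-1 convolution to `B` logits
and a softmax, giving per-sample attention weights; the effective filter is
the weighted sum of the candidates. The implementation convolves the batch
with each candidate once and mixes the results — by linearity identical to
building per-sample combined filters, and far friendlier to BLAS. The
block output is `LeakyReLU(BN(Conv_comb(X)) + BN(Conv_1x1(X)))` with the
1×1-projected residual applied regardless of channel counts, matching the
block equation literally. The final block has 4 output channels: the
*highly targeted encoding*. A small bottleneck is the point — the encoding
must be cheap to fuse with other features and forces structure-relevant
compression.

The decoder is a BiLSTM (default 2 layers, 20 hidden units per direction;
the two numbers are exposed separately because reasonable readings of the
source material disagree on which is which) followed by a position-wise
linear layer to 21 residue classes. Training masks one maximal
single-category secondary-structure segment per sequence per epoch, chosen
uniformly at random; masked one-hot rows become all-zero (there is no
mask letter in the alphabet; a dedicated 22nd mask channel is available via
`mask_mode = "token"`). Masking alters input features only, never labels.
By default the reconstruction cross-entropy covers all non-padded
positions; `loss_scope = "masked"` restricts it to masked positions.
Inference always encodes unmasked input, so no residue is ignored.

## The multi-task predictor

Enabled feature channels — one-hot (21), PSSM (20), HMM (30),
physicochemical (7), HTA encoding (4) — are concatenated per residue; every
channel is individually toggleable, which is how feature-ablation
experiments are run. The hybrid tensor passes through one residual
convolution per scale (defaults 1, 5, 9, reflecting the empirical 1–11
segment-length pattern; 32 channels per scale), each
`LeakyReLU(BN(Conv_s(X)) + BN(Conv_1x1(X)))`. Language-model embedding
channels (default width 1280), which already encode inter-residue context,
join by concatenation *after* the multi-scale module.

The MMoE block has, per task, a 1×1-conv residual path and a gating network
(Conv → BN → LeakyReLU → softmax across the `E` experts, independently at
each position), and `E` shared experts of `beta` Conv+BN(+LeakyReLU) pairs
(defaults `E = 3`, `beta = 2`, width `CH = 64`). The fused feature for task
`j` is `LeakyReLU(Res_j + sum_k omega_jk ⊙ EX_k)` with the position-wise
gate weights broadcast down the channel rows. Each task then owns a tower:
a TCN of `M = 3` residual blocks (two causal dilated convolutions per
block, dilation `2^(i-1)`, kernel 3) and a BiGRU whose bidirectional pass
supplements the TCN's strictly causal features, then a softmax head —
8-state (or 3-state) structure for the main task, 2-state buried/exposed
for the auxiliary task at threshold 0.15. The auxiliary head is a
*classification* head because the association analysis that motivates
multi-task learning is itself binary. Tower parameters are per-task
(towers sit above the gates by construction).

## Optimization protocol

Both models train with AdamW (weight decay 0.05), batch size 32, sequences
padded to the batch maximum with a validity mask, initial learning rate
5e-4 halved every five epochs, and early stopping with patience 3. The
monitored quantity is the validation metric natural to each model — Q
accuracy of the structure task for the predictor, masked-position
reconstruction accuracy for the autoencoder — with the best-epoch weights
retained. The loss is `0.8 * CE(structure) + 0.2 * CE(rsa)`, both
cross-entropies averaged over non-padded positions. All randomness
(initialization, shuffling, mask draws) flows from one seed (default 42),
and fixed seeds reproduce loss histories bit for bit.

## Numerical and padding choices

The networks run on an in-package reverse-mode autodiff engine over plain R
arrays in channel-major `(C, L, N)` layout; gradients of every composite
block are tested against central finite differences. Numerical choices not
dictated by the architecture: LeakyReLU negative slope 0.01; BatchNorm
statistics computed over valid positions only (momentum 0.1, eps 1e-5);
softmax computed with max subtraction; cross-entropy clamps probabilities
at 1e-12. Padded positions are excluded from BN statistics, losses and
metrics, re-zeroed after every layer, and bidirectional recurrences reverse
each sample within its own valid length — together these make
evaluation-mode outputs identical whether a record is batched alone or
padded inside a larger batch, which is asserted by test.

## The synthetic-data generator

The generator emulates the statistical structure the framework assumes,
not protein physics. Sequences are concatenations of segments whose
categories follow a first-order Markov chain with zero self-transition
(so segments are maximal by construction); defaults make H, E, T, L
frequent and the pi-helix I rare, mirroring the strong category imbalance
of real corpora. Per-category segment lengths are truncated-geometric with
means between 1.2 (isolated bridges) and 6 (alpha helices), concentrating
mass on 1–11 residues. Residues are emitted from per-category
distributions; each residue's buried/exposed state is drawn from a
per-category exposure probability, and continuous RSA values are placed
uniformly within the sampled bin's interval — sufficient because every
analysis in scope binarizes at 0.15.

`calibrate_association()` works in closed form: for a 2 × 8 table built
from per-residue category weights `w_c` and exposure probabilities `q_c`,
the population value is
`V = sqrt( sum_c w_c (q_c - qbar)^2 / (qbar(1 - qbar)) )`, so spreading the
`q_c` along a fixed standardized contrast with amplitude
`V * sqrt(qbar(1-qbar))` hits any feasible target exactly in expectation;
the default configuration targets 0.23, the strength of the reference
tally. Generated corpora return complete bookkeeping tallies so that
downstream analyses (contingency table, segment histogram) can be compared
with the generator exactly.

What passing tests on this generator shows: the models optimize their
losses, the metrics and analyses are correct, the pipeline is
deterministic and padding-clean. What it does not show: prediction quality
on real proteins — the generator's sequence–structure coupling is local
and far simpler than evolutionary signal, and profile/embedding channels
carry no real information here.

## Problem sizes used by the checks

The learnability checks run, by choice, at sizes a laptop CPU handles in
minutes: the predictor check uses 500 sequences of length 30–50 with
deterministic category-specific emissions (H→A, E→V, T→P, S→S, others→G),
a model with 8 channels per scale, `CH = 16`, `M = 2`, BiGRU width 12, and
the full stated protocol (scales {1,5,9}, `E = 3`, weights 0.8/0.2, AdamW,
batch 32, seed 42), and must beat the majority-class Q8 baseline by 15
points within 20 epochs. The autoencoder check uses 200 sequences, `B = 3`,
encoding width 4, the masked-only loss scope and learning rate 2e-3 (with
the default protocol and corpus sizes above, the number of optimizer steps
is far too small for the reconstruction signal at masked positions to
emerge; the masked scope concentrates the loss on exactly the quantity the
check measures), and must beat the residue-frequency baseline on masked
positions. The association check generates at least 10^6 residues and
requires the measured V within ±0.02 of the calibrated 0.2264.

## Known limitations

* Training is pure R on BLAS; it is deliberately sized for corpora of
  hundreds of sequences, not the tens of thousands used by benchmark-scale
  studies.
* The profile readers parse the standard PSI-BLAST ASCII PSSM and HH-suite
  `.hhm` layouts but do not run the underlying search tools.
* Language-model embeddings are a pluggable numeric channel; no embedding
  model ships with the package.
* The generator's RSA model is binary-first; continuous RSA values are
  placeholders within the correct bin, not biophysical accessibilities.
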