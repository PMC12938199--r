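---
title: "Predicting protein-protein interactions from grayscale feature maps"
author: "ppigray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interactions from grayscale feature maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppigray)
```

## The model

`ppigray` predicts whether two proteins interact from nothing but their
amino-acid sequences and coding gene sequences (plus a PSI-BLAST PSSM per
protein). Each protein is described by 576 features in four families:

* **V1 — amphiphilic pseudo amino acid composition (80).** The 20 residue
  frequencies $f_m = n_m/L$ together with $2\lambda$ sequence-order
  correlation factors: for each rank $d \le \lambda$,
  $\tau_{2d-1} = \frac{1}{L-d}\sum_i \varphi^1_i \varphi^1_{i+d}$ on the
  normalized hydrophobicity trace of the sequence and the analogous
  $\tau_{2d}$ on the hydrophilicity trace. All components are jointly
  normalized by $1 + \omega\sum_k \tau_k$, so V1 sums to one. Defaults
  $\omega = 0.5$, $\lambda = 30$; both hydropathy properties are min-max
  scaled to $[0,1]$ across the 20 residues before use, and the scale table
  is injectable (`hydropathy_scale(path)`).
* **V2 — segmented interval-distance statistics (320).** The sequence is
  cut into four consecutive segments of length $\lfloor L/4\rfloor$ (the
  last absorbs the remainder). Within a segment, each residue type's
  occurrence positions define its interval-distance sequence (gaps between
  consecutive occurrences; the distance to the segment end when it occurs
  once; zero when absent), summarized by mean, min, max and the frequency
  $q/s$ — $4 \times 20 \times 4 = 320$ features capturing the local
  positional distribution of each residue type.
* **V3 — PSSM evolutionary descriptors (80).** On the sigmoid-normalized
  PSSM, the 20 column means $\bar a_w$, plus the $\theta$-interval
  deviation product factors
  $Z^\theta_w = \frac{1}{L-\theta}\sum_i (a^*_{i,w}-\bar a_w)(a^*_{i+\theta,w}-\bar a_w)$
  for $\theta \in \{1,2,3\}$, quantifying co-evolution of positions
  $\theta$ apart.
* **V4 — gene-sequence features (96).** Overlapping 1/2/3-mer frequencies
  of the CDS (84), per-nucleotide positional means and population
  variances (8), and the mean/variance of a unit-circle mapping (4) in
  which the $r$-th nucleotide maps to angle
  $\text{offset}(e) + \frac{\pi}{2}\, b^r_e/(b_e+1)$ — quadrants I-IV for
  A, C, G, T — so every point encodes type, rank and abundance at once.

The 576 features are arranged into a fixed 36 × 16 matrix (V2 rows 1-20,
one residue per row; V1 rows 21-25; V3 rows 26-30 with the column means
first; V4 rows 31-36 ending in $f_{TTT}$). A protein pair is the
horizontal concatenation of its two matrices — a 36 × 32 "grayscale map"
— classified by a small convolutional network: three 6 × 6 stride-1
convolutions (shared channel count, ReLU), 3 × 3 stride-1 max pooling
after the second and third, then a fully connected softmax pair
(interaction, non-interaction). On 36 × 32 inputs the spatial sizes are
31×27 → 26×22 → 24×20 → 19×15 → 17×13; with 64 channels the flattened
vector has 14,144 entries.

Class imbalance is handled by an undersampling ensemble: positives are
split 3:1:1 into train/validation/test, negatives are constructed by the
subcellular-localization strategy (only pairs whose compartment
annotations are disjoint are eligible), and five balanced training sets —
all training positives plus an equal-size negative draw — train five
independent CNNs whose interaction probabilities are averaged.

## Normalization: per-feature, then per-sample

The feature families live on wildly different scales: positional
variances of a CDS of length $N$ are of order $N^2/12$ (up to $\sim 10^5$
here), interval-distance maxima of order $L$, while compositions and
frequencies stay below one. Min-max normalization is therefore applied
twice:

1. **per feature**, with minima and maxima recorded from the
   training-partition proteins (`feature_scaler()` / `scale_features()`),
   which is what actually removes the scale differences between features;
2. **per sample** over the whole 36 × 32 matrix (`build_pair_map()`),
   which pins each map exactly onto $[0,1]$ for the image encoding.

The second step alone — normalizing each sample's matrix by its own global
minimum and maximum — cannot equalize feature scales: the positional
variance cells then set every sample's scale and all informative features
land at amplitudes of $10^{-4}$ or below. We verified empirically that a
network trained on such maps improves its validation loss by only
$\sim 10^{-4}$ per epoch (the optimizer must grow weights multiplicatively
across layers to amplify the signal), so that the patience-10 early
stopping fires long before anything is learned at this problem size.
Per-feature scaling fixes this; the same run then reaches validation loss
≈ 0.11 within 100 epochs. The scaler is fitted on training proteins only
and stored with the trained ensemble, so validation/test data never
influence it.

## The synthetic benchmark

`fixture_config()` + `write_fixtures()` generate every input the pipeline
consumes: protein FASTA, back-translated CDS FASTA (uniform codon choice
under the standard genetic code, so translation recovers the protein),
PSI-BLAST-dialect ASCII PSSMs (uniform integer scores in $[-8, 12]$ with a
+6 bias on each position's own residue column), a localization table, and
interaction labels.

The planted signal runs through the mean normalized hydrophobicity of the
sequence — a quantity the APAAC composition terms express directly. The
protein population holds two composition archetypes: a hydrophobic-rich
"sticky" class (30 % of proteins, residue weights tilted by
$e^{+2\varphi^1_m}$) and a hydrophilic-rich class (tilt $e^{-2}$). A pair
interacts when the sum of its two stickiness values exceeds the quantile
matching the configured positive rate (8 %), so with zero label noise the
labels are a deterministic function of the sequences, and the bimodal
population gives interacting pairs a real margin. This is deliberate: the
real-data experiments behind this architecture train for GPU-hours on
$10^4$ pairs, while this package's tests must certify the pipeline on one
CPU in minutes, so the scaled-down benchmark needs class structure that is
learnable at that budget. Defaults (frozen with the package): 100
proteins, lengths uniform on 60-400, uniform base composition, effect 2,
positive rate 0.08, noise 0, four equally likely compartments with a 10 %
chance of a second annotation.

What the fixtures do **not** emulate: homology/redundancy structure
(CD-HIT is consumed upstream in real use, not simulated), organism-specific
codon bias, biologically calibrated PSSMs, and any interaction mechanism
beyond hydrophobicity-driven stickiness. Passing the learnability test
therefore shows the pipeline can extract a sequence-composition signal
end-to-end — not that it reproduces the published real-data accuracies,
which depend on curated interactome data and NR-database PSSMs.

## Training and numerical choices

* Adam (framework-default moment constants, $\varepsilon = 10^{-8}$),
  batch size 128, at most 100 epochs, early stopping with patience 10 on
  the validation loss ("improve" means strictly lower; the best checkpoint
  is restored). Training is bitwise reproducible under a fixed seed.
* Hyperparameter search (`tune_cnn()`): learning rate log-uniform in
  $[10^{-5}, 10^{-3}]$ and channels in $\{2,4,\dots,64\}$, at most 3
  trials, objective = validation ROC-AUC, fresh training per trial, ties
  keep the earliest trial. The default strategy is a tree-structured
  Parzen estimator (two random start-up trials, top-quarter good set,
  Gaussian Parzen density in $\log_{10}$ learning rate, add-one
  categorical over channels, candidates ranked by the $l/g$ density
  ratio); a seeded random search is available as the fallback strategy.
* Weight initialization is the standard uniform fan-in rule
  $U(\pm 1/\sqrt{\text{fan-in}})$ with a recorded seed; the output order
  of the softmax pair is (interaction, non-interaction); classification
  uses a caller-supplied threshold, 0.5 by default; network prediction
  keeps scores strictly above 0.98 (interaction mode) or strictly below
  0.01 (non-interaction mode) by default.
* Degenerate cases: a constant pair map normalizes to all zeros; metrics
  with zero denominators report 0 and are flagged rather than raising;
  ROC requires both classes; residues absent from a segment contribute
  zeros; nucleotides absent from a CDS give zero positional statistics.
* Convolutions and max pooling run in direct compiled kernels (im2col
  materialization is deliberately avoided; on one CPU core the dominant
  cost is memory traffic, so the kernels accumulate in "extended" output
  coordinates where each kernel offset is one long contiguous stride-1
  loop). Backward passes are verified against numerical differentiation
  in the test suite.

## Benchmark problem sizes

The shipped tests and the acceptance script train the five-member
ensemble with 2-channel members at learning rate $10^{-3}$ on the default
fixture set (100 proteins, ≈ 470 balanced training samples per member,
validation and test of ≈ 160 each). These sizes were chosen so a full
ensemble run takes minutes on a single core; the channel search space and
the TPE tuner are exercised separately on miniature separable sets. The
feature-ablation experiment zeroes one family in the extracted feature
store and re-evaluates the trained pipeline (training-fitted scaler and
ensemble) unchanged, mirroring the sharp accuracy collapse reported for
the map-based model when a feature family it relies on is removed;
zeroing after the scaler instead gives a milder, partial drop and is
available by applying `zero_families()` to the scaled table.

## Known limitations

* The dataset split is by pair, not by protein; `protein_disjoint_test()`
  provides the stricter evaluation, and with pair-level splitting some
  protein identity leakage across partitions is expected (it inflates
  accuracy estimates on real interactomes).
* The subcellular-localization negative strategy mislabels interacting
  cross-compartment pairs as negatives in real data; the synthetic
  localizations are independent of the planted labels, so here it only
  restricts the eligible negative pool.
* Per-protein PSSMs are consumed, never computed: running PSI-BLAST (and
  CD-HIT) is out of scope.
* The 1D-baseline comparison and learned feature arrangements are out of
  scope; `rearrange()` supports arrangement experiments on the canonical
  map only.
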