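---
title: "chromcast: model, training scheme and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromcast: model, training scheme and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Histone-mark ChIP-seq signal is highly cell-type specific, but assaying
every mark in every cell type of interest is impractical. chromcast
implements a transfer-learning model that predicts histone-mark signal
tracks in *previously unseen* cell types from two inputs: DNA sequence
(through a frozen, pluggable backbone with a large receptive field) and
chromatin accessibility (ATAC) data for the cell type of interest. The
signal unit throughout is the MACS2-style -log10 adjusted p-value per
genomic bin, variance-stabilised with the arcsinh transform
\(\sinh^{-1} x = \ln(x + \sqrt{1 + x^2})\) before training.

## Model

The model has two branches whose outputs a combined head merges:

* **DNA branch.** A frozen backbone maps one-hot DNA of length
  `input_len` to a latent of `T = window_len / bin` positions by `C`
  channels. Two trainable heads read the latent: an *average* head
  predicting the cross-cell-type mean signal per bin and mark (positive
  link, Poisson likelihood) and a *distribution* head predicting, per bin
  and mark, the proportion of training cell types whose -log10 p-value
  falls into each of K signal bins (`[0, 0.5), [0.5, 1.0), ...` with an
  open-ended top bin; a K-simplex via softmax).
* **Cell-typing branch.** Two accessibility views are embedded at
  different resolutions and merged: the *local* view is the cell's
  arcsinh ATAC signal minus the training-average arcsinh ATAC over a
  window slightly wider than the prediction window (1,562 positions at
  full scale), embedded with a strided convolution; the *global* view is
  the cell's accessibility in a fixed window around marker-gene
  transcription start sites (1,216 genes x 12 positions = 14,592 at full
  scale), pooled and passed through a dense layer. Both embeddings are
  flattened, concatenated and passed through two shared dense layers to
  one output head per mark, predicting the *delta*: cell-specific signal
  minus cross-cell average. The global vector is a property of the cell
  only — it is identical for every genomic window, and so acts as a
  cell-identity embedding.
* **Combined head.** Per output bin, the average (M values), distribution
  (M x K probabilities) and delta (M values) features are concatenated,
  passed through a convolutional block over bins and per-mark heads with
  a positive link. Per-mark skip connections initialised at 1 make the
  combined logit start at `avg + delta` — the natural decomposition of
  the cell-specific signal — so the convolutional block learns
  corrections rather than having to rediscover the decomposition.
  Output is on the arcsinh scale; the raw -log10 p scale applies
  `sinh`.

At full scale the geometry is: 196,608 bp DNA input, 114,688 bp
prediction window at 128 bp bins (896 positions), 199,936 bp local
accessibility window, 6 marks. `run_config("paper")` validates every one
of these constants and fails loudly if any is changed. The desk-scale
(`toy`) profile keeps every ratio and threshold but shrinks the geometry
(4,096 / 2,048 / 4,352 bp, 3 marks) so the whole pipeline runs on one
CPU in about a minute.

### The toy backbone and what "pretrained" means here

`make_toy_backbone()` builds a convolution/pooling stack (base-pair-level
convolution, average pooling to the bin width, two bin-level
convolutions) whose receptive field is analytically
`R = bin * (k2 + k3 - 1) + k1 - 1` (1,672 bp at 128 bp bins with kernels
9/9/5). When given a motif vocabulary, the first-layer filters are seeded
as exact-match detectors for each motif and its reverse complement, and
the seeded channels propagate through the bin-level convolutions with a
Gaussian-spread gain whose width matches the planted peak shape. This
emulates the one property of a genome-pretrained backbone that the
transfer-learning scheme actually relies on — early filters that detect
regulatory motifs — while keeping the whole model analytically
inspectable. The backbone is frozen: its parameters live outside the
trainable tree, every trainer ignores them, and the latent for each
(window, strand, shift) is computed once and cached
(`cache_latents()`), keyed by a hash of the backbone weights so a stale
cache is rejected.

## Two-stage training

Stage one (`pretrain()`) trains the branches separately, each with its
own Adam optimiser: the DNA heads against the cross-cell average
(Poisson negative log-likelihood, `pred - target * log(pred)`) and the
distribution (cross-entropy against the soft target simplex — targets
are proportions, not classes), and the cell-typing branch against the
delta (mean squared error, since deltas are signed). Stage two
(`train_full()`) trains everything but the backbone against the
cell-specific signal with Poisson NLL, evaluating a held-out validation
set periodically and returning the best-validation checkpoint (early
stopping with a patience counter).

Numerical choices that mattered in practice:

* **Link function.** The positive link for rate heads defaults to the
  canonical exponential link. With a soft-plus link the gradient through
  the link is damped by `sigmoid(pre)`; at the bias level that sparse
  -log10 p targets require (background rate about 0.05, `pre` near -3)
  that damping is ~0.05, and sparsely-active latent channels reliably
  froze at wrong-signed weights inherited from early training. The
  exponential link's gradient is exactly `pred - target` and has no such
  regime. Soft-plus remains available as `model_config(link =
  "softplus")`.
* **Base-rate initialisation.** Rate-head biases start at the inverse
  link of a 0.05 base rate, so initial predictions sit at the background
  level rather than at `link(0)`; otherwise every active channel is
  first pushed negative while the bias travels.
* **Schedules.** The full-scale profile stores the published schedule
  (1,000 pre-training steps at learning rate 2e-4, 6,940 full steps at
  5e-3, batch 128). The desk-scale profile uses 2,000 pre-training steps
  at 5e-4 and up to 1,500 full steps at 5e-3 (batch 8, early stopping):
  Adam moves each parameter by roughly the learning rate per step, so
  the head weights (order 0.1–1) cannot be reached from initialisation
  in a few hundred steps at 2e-4.
* **Augmentation shifts are whole-bin multiples** (default up to 3 bins,
  384 bp). Sub-bin shifts would misalign targets with the bin grid, and
  whole-bin shifts keep frozen-backbone latents cacheable per
  (window, strand, shift).
* **Both held-out chromosomes and held-out cells** (20% of cells) form
  the validation set — the conservative reading when both are available.

## Variant-effect scoring

`score_variant()` predicts on reference and alternative sequence and
takes the difference. Because the prediction window (114,688 bp) is
narrower than the input (196,608 bp), a variant centred in the input can
influence bins outside the prediction window; the scorer therefore makes
three placements — centred, and slid by ±(input - window)/2 — and keeps
only the non-overlapping flanks of the off-centre prediction windows, so
the three appended segments tile the variant's full receptive field
exactly once. Differences are summed over bins per mark (on the arcsinh
training scale by default) and averaged over the augmentation set
{forward, reverse complement} x {no shift, one seeded whole-bin random
shift}: 2 alleles x 3 placements x 4 augmentations = 24 forward passes
per variant. Accessibility features are deliberately *not* modified for
the alternative allele: the accessibility input describes the assayed
cell, and no assay of the alternative haplotype exists — a stated
limitation of the approach that the synthetic benchmark reproduces (see
below).

Study-side quantities: hQTL records are filtered (`munge_hqtl()`) to cis
records within the model's receptive field of the peak edge (boundary
retained) and an optional SNP whitelist, then aggregated per SNP as
\(\hat\alpha_m = |G_m|^{-1/2} \sum_{k \in G_m} \hat\alpha_m^{(k)}\).
`export_and_concord()` writes a sumstats table (SNP, A1, A2, signed
score) for external signed-LD-profile regression and reports sign
concordance (exact binomial test against 0.5) and Spearman rank
correlation.

## Probing

* `dna_permutation_scan()` inserts random single-base variants at grid
  positions in random sequences and measures the mean absolute change of
  the central 512 bp of output (averaged over marks, arcsinh scale). For
  the convolutional toy backbone the effect is *exactly* zero beyond
  half the declared receptive field — a structural test, not a
  statistical one.
* `atac_permutation_scan()` replaces 640 bp blocks of the cell's local
  accessibility with the training average (zeroing the delta) at
  increasing distances.
* `offcentre_consistency()` compares centred and ±crop-margin-shifted
  predictions at shared genomic bins. The default cell-typing branch
  (flatten + dense) is not translation-equivariant, matching the
  published architecture; `model_config(celltyping_mode = "conv")`
  builds a purely convolutional variant (local path convolutional and
  cropped, global path a per-mark bias, combined kernel 1) that is
  exactly equivariant, for which the correlation is 1 within 1e-5.
  Equivariance additionally requires the backbone's receptive field to
  fit inside the crop margin, which holds for the toy geometry
  (836 < 1,024 bp).
* `global_attribution()` calls peaks on predicted tracks (non-overlapping
  1,024 bp windows, mean -log10 p above 2 — the mean was chosen for
  robustness to bin-level spikes), scores each peak by the summed
  absolute gradient of its mean predicted signal with respect to the
  global accessibility input (computed by backpropagation, verified
  against finite differences), keeps the top 10% by absolute
  attribution and can export their DNA to FASTA for downstream motif
  tools.

## The synthetic-data generator

The generator defines the study conditions for every end-to-end test.
A `RegulatoryGrammar` holds 6–10 bp consensus motifs with per-mark
affinities and a cells-by-motifs usage matrix: two shared motifs (usage
1 everywhere) plus one private motif per cell, guaranteeing at least one
planted cell-specific peak region per cell. Sequences are uniform-random
with motif instances planted at Poisson-distributed counts on a coarse
grid (so instances never overlap); a quarter of instances carry a
single-base lesion, which both makes motif occurrences imperfect and
provides "restorable" sites for positive-effect variants. Each intact
site contributes a truncated-Gaussian peak (sigma 200 bp, maximum
amplitude 6 on the -log10 p scale) scaled by usage and affinity;
accessibility receives a peak wherever any motif is active in that cell
(amplitude 5), so the accessibility delta carries the cell-specific
signal; half-normal noise (sd 0.05) is added everywhere. Tracks are
generated at 25 bp and rebinned by the data pipeline to 128 bp, as in
upstream peak-calling pipelines. Marker-gene TSSs sit on private sites
(cycling through cells), so the global accessibility vectors separate
cell types. Default scale: 2 chromosomes x 65,536 bp, 10 cells, 3 marks,
about 40 hQTL variants plus trans/far decoy records.

hQTL variants flip a central motif base (intact site, negative planted
effect) or restore a lesioned base (positive effect); observed betas add
Gaussian noise (sd 0.1) and p-values are one-sided normal tails. The
beta scale is arbitrary — only sign and relative magnitude enter the
concordance tests.

What the generator does *not* emulate: realistic nucleotide composition,
linkage disequilibrium between variants, replicate structure,
copy-number or mappability artefacts, and peaks without an underlying
planted motif. Passing tests therefore demonstrate that the
architecture, training scheme and scoring framework can recover planted
regulatory structure at desk scale — not that the model attains any
particular accuracy on real epigenomes.

## What the end-to-end tests show (and their limits)

On the default study conditions, the trained toy model's predictions for
*held-out* cells beat the training-average baseline (Pearson correlation
with truth inside planted cell-specific peak regions, per cell,
chromosome and mark) in well over 70% of comparisons across three
generator seeds — the desk-scale analogue of comparing cell-type-specific
predictions against the training-set average signal.

Sign concordance between model variant scores and simulated hQTL
marginals exceeds 0.5 with binomial p < 0.05 in the majority of three
seeds. It is worth recording how the failing seed fails: variants in the
study cell's *private* motif all share whatever response sign the model
happened to learn for that motif's latent channel, because the
cross-cell average barely reflects a single cell's private peaks and the
accessibility input is not modified for the alternative allele. They
fail or pass as a correlated block, not as independent coin flips. This
mirrors the real limitation that cell-type-specific variant effects are
exactly the ones a cell-generalising model has least leverage on.

## Problem sizes

The test suite trains the toy model (2,000 + up to 1,500 steps, batch 8)
for three generator seeds — about a minute per seed on one CPU — and
scores roughly 20 variants per seed at 24 forward passes each. The
full-scale profile is validated for geometry only; no full-scale
training is attempted.

## Known limitations

* The trainer is plain R; it is adequate for the desk-scale geometry the
  package targets but not for full-scale training, for which the
  backbone adapter contract (`BackboneContract`) is the intended
  integration point.
* Distribution targets default to K = 10 bins with edges 0.5–4.5 and an
  open top bin; worked examples in the field sometimes print an
  11-component vector for the same construction. K and the edges are
  configurable; first and last components — the quantities the
  acceptance checks pin — agree under either choice.
* bedGraph is the canonical interchange format (value-exact round
  trips); bigWig support is available behind the same interface but
  round-trips only to float precision.
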