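# chromcast

chromcast predicts histone-mark signal tracks in **previously unseen cell
types** from DNA sequence plus chromatin accessibility (ATAC) data. It is
aimed at computational epigenomicists who have accessibility data for a
cell type of interest but no ChIP-seq for the marks they care about, and
at methods developers who want a fully inspectable, desk-scale
implementation of the cell-type-generalising transfer-learning recipe:
a frozen, large-receptive-field DNA backbone with trainable heads, a
cell-typing branch that embeds local and global accessibility, two-stage
training, and a full-receptive-field variant-effect scoring framework
with histone-QTL (hQTL) summary-statistic aggregation.

## The model

All signal is the MACS2-style -log10 adjusted p-value per 128 bp bin,
variance-stabilised as `asinh(x) = ln(x + sqrt(1 + x^2))` for training.
Two branches feed a combined head:

* the **DNA branch** reads a frozen backbone latent over the prediction
  window and predicts, per bin and mark, the cross-cell-type **average**
  signal (positive link, Poisson negative log-likelihood
  `pred − target·log(pred)`) and the **distribution** of signal across
  training cell types (a K-simplex over bins `[0, 0.5), [0.5, 1.0), …`
  with an open top bin; cross-entropy loss);
* the **cell-typing branch** embeds the cell's local accessibility delta
  (cell minus training average, arcsinh scale) and a fixed global
  accessibility vector sampled around marker-gene TSSs, and predicts the
  **delta**: cell-specific minus average signal (MSE loss);
* the **combined head** merges average, distribution and delta features
  per bin through a convolutional block and per-mark positive-link heads
  (Poisson NLL), with skip connections so the logit starts at
  `avg + delta`.

Variant effects are scored by in-silico mutagenesis over the *full*
receptive field: three window placements (centred, slid by ±(input −
window)/2) whose kept segments tile the input span exactly once, crossed
with strand and shift augmentation — 24 forward passes per SNP. Study
marginals aggregate per SNP as `alpha_m = |G_m|^(−1/2) · sum_k beta_mk`,
and `export_and_concord()` writes sumstats for external signed-LD-profile
regression plus sign-concordance and rank-correlation reports.

At full scale the geometry is 196,608 bp DNA input → 896 × 128 bp
prediction bins (114,688 bp), 1,562 local accessibility positions and a
14,592-long global vector (1,216 marker genes × 12 positions);
`run_config("paper")` asserts every one of those constants. The `toy`
profile shrinks the geometry (4,096/2,048 bp, 3 marks) so everything —
including training — runs on one CPU in about a minute, against a
synthetic genome with a planted regulatory grammar
(`simulate_genome()`, `simulate_tracks()`, `simulate_hqtl()`).

## Worked example

```r
library(chromcast)

# distribution target over 104 cell types: 102 silent, 2 at -log10 p = 5.5
round(build_distribution(c(rep(0, 102), rep(5.5, 2))), 4)
#>  [1] 0.9808 0.0000 0.0000 0.0000 0.0000 0.0000 0.0000 0.0000 0.0000 0.0192
```

The first component says 98% of cell types have no signal at this bin;
the open-ended top component (1.9%) is the two cells at 5.5.

```r
scfg <- sim_config(seed = 1)              # 2 chromosomes, 10 cells, 3 marks
sim    <- simulate_genome(scfg)
tracks <- simulate_tracks(sim, scfg)
dcfg   <- toy_data_config(seed = 1)
mg     <- simulate_marker_genes(sim, tracks, scfg, dcfg)
ds     <- build_dataset(sim, tracks, mg, dcfg)
ds
#> chromcast dataset: 10 cells (2 held out), 3 marks, 63 regions,
#>   608 train / 50 val items

mcfg  <- model_config(dcfg, n_marks = 3, backbone_channels = 28)
bb    <- make_toy_backbone(mcfg, motifs = sim$grammar$motifs)
bb
#> BackboneContract: input 4096 bp -> latent 16 x 28,
#>   receptive field 1672 bp (frozen)
model <- build_model(mcfg, backbone = bb)

rc    <- run_config("toy", seed = 1)
cache <- cache_latents(model$backbone, ds)
model <- pretrain(model, ds, rc$pretrain, cache = cache)
model <- train_full(model, ds, rc$train, cache = cache)

preds <- predict_cell_tracks(model, ds, ds$val_cells[1])   # unseen cell
```

`preds` is one -log10 p-value `BinnedTrack` per mark for a cell the
model never trained on, driven entirely by that cell's accessibility.
Writing them out (`track_io(..., "write", "bedGraph", ...)`), scoring
variants (`score_variant()`), probing the receptive field
(`dna_permutation_scan()`) and evaluating (`mse_report()`,
`pearson_by_region()`, `classification_compare()`) all operate on the
same objects. The same pipeline is scriptable through
`inst/cli/chromcast` (`simulate | build-data | pretrain | train |
predict | score-variants | probe | evaluate`).

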