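# Bundles genome sequence, rebinned signal tracks, cell splits, regions and
# augmentation items into one object the trainer, scorer and probes share.

#' Assemble a training dataset from generator (or loaded) components
#'
#' Rebins all tracks to the model resolution, chooses held-out cells, tiles
#' and filters training windows (blacklist, flank margins, per-mark coverage
#' with the strict > coverage_frac rule over the training cells), balances
#' marks, and materialises train/validation items with strand and shift
#' augmentation. Global accessibility vectors are precomputed per cell.
#'
#' @param sim A `cc_sim_genome` (or a compatible list with `genome`,
#'   `sequences`, `blacklist`).
#' @param tracks Output of [simulate_tracks()] (or loaded tracks in the same
#'   nested shape) at any resolution dividing into `cfg$bin` cleanly via
#'   overlap-weighted rebinning.
#' @param marker_genes Marker-gene TSS data frame (`chrom`, `tss`).
#' @param cfg A `DataConfig`.
#' @return A list of class `cc_dataset`.
#' @export
build_dataset <- function(sim, tracks, marker_genes, cfg) {
  cells <- names(tracks$marks)
  marks <- names(tracks$marks[[1]])
  tr128 <- lapply(tracks$marks, function(per_cell)
    lapply(per_cell, rebin, new_bin = cfg$bin))
  atac128 <- lapply(tracks$atac, rebin, new_bin = cfg$bin)

  splits_seed <- cfg$seed
  val_cells <- nn_seeded(splits_seed, {
    n_val <- round(cfg$val_cell_frac * length(cells))
    if (n_val < 1)
      stop("chromcast_error: val_cell_frac rounds to zero validation cells")
    sort(sample(cells, n_val))
  })
  train_cells <- setdiff(cells, val_cells)

  cand <- enumerate_candidates(sim$genome, sim$blacklist, cfg)
  by_mark <- lapply(stats::setNames(marks, marks), function(m)
    lapply(train_cells, function(cl) tr128[[cl]][[m]]))
  per_mark <- coverage_filter(cand, by_mark, cfg)
  regions <- balance_marks(per_mark, seed = cfg$seed)
  splits <- make_splits_and_augment(regions, cells, cfg)

  atac_arc_avg <- average_tracks(lapply(train_cells, function(cl)
    arcsinh_transform(atac128[[cl]], "forward")))
  globals <- vapply(cells, function(cl)
    global_features(tracks$atac[[cl]], marker_genes, cfg),
    numeric(nrow(marker_genes) * (cfg$tss_window %/% cfg$global_bin)))

  structure(list(genome = sim$genome, sequences = sim$sequences,
                 blacklist = sim$blacklist, cfg = cfg,
                 cells = cells, marks = marks,
                 train_cells = splits$train_cells,
                 val_cells = splits$val_cells,
                 regions = regions, items = splits[c("train", "val")],
                 tracks = tr128, atac = atac128,
                 atac_arc_avg = atac_arc_avg,
                 marker_genes = marker_genes, globals = globals),
            class = "cc_dataset")
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf(
    "chromcast dataset: %d cells (%d held out), %d marks, %d regions, %d train / %d val items\n",
    length(x$cells), length(x$val_cells), length(x$marks),
    nrow(x$regions), nrow(x$items$train), nrow(x$items$val)))
  invisible(x)
}

seq_window_onehot <- function(dataset, chrom, start, width, strand = "+") {
  s <- substring(dataset$sequences[[chrom]], start + 1, start + width)
  oh <- one_hot(s)
  if (strand == "-") oh <- one_hot_revcomp(oh)
  oh
}

#' One-hot DNA input for a training item
#' @param dataset A `cc_dataset`.
#' @param item One row of an item data frame.
#' @return Matrix (input_len x 4).
#' @export
item_onehot <- function(dataset, item) {
  cfg <- dataset$cfg
  seq_window_onehot(dataset, item$chrom, item$input_start + item$shift,
                    cfg$input_len, item$strand)
}

#' Cell-type features for a training item
#'
#' Local feature: arcsinh cell accessibility minus the training-average
#' arcsinh accessibility over the local window centred on the (shifted)
#' prediction window; reversed for minus-strand items. Global feature: the
#' cell's fixed marker-gene accessibility vector.
#' @param dataset A `cc_dataset`.
#' @param item One row of an item data frame.
#' @return A `CelltypeFeatures`.
#' @export
item_features <- function(dataset, item) {
  cfg <- dataset$cfg
  nl <- n_local_bins(cfg)
  lm <- (cfg$local_atac_len - cfg$window_len) / 2
  lstart <- item$window_start + item$shift - lm
  cell_arc <- asinh(track_window(dataset$atac[[item$cell]], item$chrom,
                                 lstart, nl))
  avg_arc <- track_window(dataset$atac_arc_avg, item$chrom, lstart, nl)
  local_delta <- cell_arc - avg_arc
  if (item$strand == "-") local_delta <- rev(local_delta)
  celltype_features(local_delta, dataset$globals[, item$cell])
}

#' Targets for a training item
#' @param dataset A `cc_dataset`.
#' @param item One row of an item data frame.
#' @return A `TargetBundle`, rows reversed for minus-strand items.
#' @export
item_targets <- function(dataset, item) {
  cfg <- dataset$cfg
  reg <- data.frame(chrom = item$chrom,
                    window_start = item$window_start + item$shift)
  tb <- build_targets(reg, dataset$tracks, item$cell, cfg,
                      avg_cells = dataset$train_cells)
  if (item$strand == "-") {
    nb <- nrow(tb$avg)
    tb$avg <- tb$avg[nb:1, , drop = FALSE]
    tb$delta <- tb$delta[nb:1, , drop = FALSE]
    tb$cell_signal <- tb$cell_signal[nb:1, , drop = FALSE]
    tb$dist <- tb$dist[nb:1, , , drop = FALSE]
  }
  tb
}

# distribution array -> mark-block matrix matching the dist head layout
dist_array_to_mat <- function(dist) {
  nb <- dim(dist)[1]; M <- dim(dist)[2]; K <- dim(dist)[3]
  out <- matrix(0, nb, M * K)
  for (m in seq_len(M)) out[, ((m - 1) * K + 1):(m * K)] <- dist[, m, ]
  out
}

#' Predict a whole-chromosome track for one cell
#'
#' Tiles each chromosome with non-overlapping prediction windows (skipping
#' flank-infeasible ends), runs the combined model and stitches the window
#' predictions into one `BinnedTrack` per mark. Uncovered margins stay 0.
#'
#' @param model A trained `cc_model`.
#' @param dataset A `cc_dataset`.
#' @param cell Cell label (its accessibility must be in the dataset).
#' @param chroms Chromosomes to predict (default: all).
#' @param output_scale `"neglog10p"` (default) or `"arcsinh"`.
#' @param cache Optional latent cache from [cache_latents()].
#' @return Named list (one `BinnedTrack` per mark).
#' @export
predict_cell_tracks <- function(model, dataset, cell,
                                chroms = dataset$genome$names,
                                output_scale = c("neglog10p", "arcsinh"),
                                cache = NULL) {
  output_scale <- match.arg(output_scale)
  cfg <- dataset$cfg
  nb <- n_bins(cfg)
  margin <- max(crop_margin(cfg), (cfg$local_atac_len - cfg$window_len) / 2)
  out_vals <- lapply(dataset$marks, function(m)
    lapply(dataset$genome$names, function(ch)
      numeric(n_track_bins(dataset$genome, ch, cfg$bin))))
  names(out_vals) <- dataset$marks
  for (mi in seq_along(dataset$marks))
    names(out_vals[[mi]]) <- dataset$genome$names
  for (chrom in chroms) {
    len <- chrom_length(dataset$genome, chrom)
    starts <- seq(0, len - cfg$window_len, by = cfg$window_len)
    starts <- starts[starts - margin >= 0 &
                       starts + cfg$window_len + margin <= len]
    for (ws in starts) {
      item <- data.frame(chrom = chrom, window_start = ws,
                         input_start = ws - crop_margin(cfg),
                         cell = cell, strand = "+", shift = 0)
      latent <- get_latent(model, dataset, item, cache)
      pred <- combined_forward(model, latent, item_features(dataset, item),
                               output_scale = output_scale,
                               is_latent = TRUE)
      b0 <- ws / cfg$bin
      for (mi in seq_along(dataset$marks))
        out_vals[[mi]][[chrom]][(b0 + 1):(b0 + nb)] <- pred[, mi]
    }
  }
  lapply(stats::setNames(dataset$marks, dataset$marks), function(m)
    binned_track(dataset$genome, cfg$bin, out_vals[[m]], assay = m,
                 cell = cell,
                 scale = if (output_scale == "neglog10p") "neglog10p"
                 else "arcsinh"))
}
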