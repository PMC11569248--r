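#' Empirical DNA receptive-field scan
#'
#' For random input sequences, inserts one random single-base variant per
#' replicate at each grid position across the input window and measures the
#' mean absolute change (over replicates and mark channels, arcsinh scale)
#' of the prediction averaged over the centre span (default 512 bp, i.e. 4
#' output bins). For the convolutional toy backbone the effect is exactly
#' zero once the variant is farther from every centre-span bin than half
#' the declared receptive field plus the combined head's convolutional
#' halo.
#'
#' @param model A `cc_model`.
#' @param features A `CelltypeFeatures` held fixed across the scan.
#' @param n_positions Number of evenly spaced variant positions.
#' @param reps Replicates (fresh random sequence + variant) per position.
#' @param seed Integer seed.
#' @param centre_span Centre span in bp the effect is measured over.
#' @return A list of class `ProbeResult`: `distance` (bp offsets from the
#'   input centre), `effect`, `replicates`, `centre_span`.
#' @export
dna_permutation_scan <- function(model, features, n_positions = 32,
                                 reps = 3, seed = 1L, centre_span = 512) {
  cfg <- model$cfg$data_cfg
  L <- cfg$input_len
  if (n_positions > L)
    stop("chromcast_error: more probe positions than input bases")
  nb <- n_bins(cfg)
  span_bins <- centre_span / cfg$bin
  ctr <- (nb - span_bins) / 2
  ctr_bins <- (ctr + 1):(ctr + span_bins)
  positions <- round(seq(1, L, length.out = n_positions))
  nn_seeded(seed, {
    eff <- matrix(0, reps, n_positions)
    for (r in seq_len(reps)) {
      oh <- one_hot(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                          collapse = ""))
      base_pred <- combined_forward(model, oh, features)
      base_ctr <- base_pred[ctr_bins, , drop = FALSE]
      for (j in seq_len(n_positions)) {
        pos <- positions[j]
        cur <- which(oh[pos, ] == 1)
        alt <- sample(setdiff(1:4, cur), 1)
        oh2 <- oh
        oh2[pos, ] <- 0; oh2[pos, alt] <- 1
        pred <- combined_forward(model, oh2, features)
        eff[r, j] <- mean(abs(pred[ctr_bins, , drop = FALSE] - base_ctr))
      }
    }
    structure(list(distance = positions - (L / 2), effect = colMeans(eff),
                   replicates = reps, centre_span = centre_span),
              class = "ProbeResult")
  })
}

#' Local-accessibility receptive-field scan
#'
#' At each requested distance from the window centre, replaces a block of
#' the cell's local accessibility signal with the training average (i.e.
#' zeroes the local delta over the block) and measures the centre-span mean
#' absolute prediction change.
#'
#' @param model A `cc_model`.
#' @param onehot Fixed one-hot DNA input.
#' @param features Baseline `CelltypeFeatures`.
#' @param block Block width in bp (multiple of the bin width; default 640).
#' @param distances Bp offsets of the block centre from the window centre
#'   (default: an even grid across the local window).
#' @param centre_span Centre span in bp.
#' @return A `ProbeResult`.
#' @export
atac_permutation_scan <- function(model, onehot, features, block = 640,
                                  distances = NULL, centre_span = 512) {
  cfg <- model$cfg$data_cfg
  if (block %% cfg$bin != 0)
    stop("chromcast_error: block must be a whole-bin multiple")
  nl <- n_local_bins(cfg)
  nb <- n_bins(cfg)
  block_bins <- block / cfg$bin
  half_local <- cfg$local_atac_len / 2
  if (is.null(distances))
    distances <- round(seq(-(half_local - block), half_local - block,
                           length.out = 9) / cfg$bin) * cfg$bin
  span_bins <- centre_span / cfg$bin
  ctr <- (nb - span_bins) / 2
  ctr_bins <- (ctr + 1):(ctr + span_bins)
  base_pred <- combined_forward(model, onehot, features)
  base_ctr <- base_pred[ctr_bins, , drop = FALSE]
  eff <- numeric(length(distances))
  for (i in seq_along(distances)) {
    centre_bin <- nl / 2 + distances[i] / cfg$bin
    b0 <- round(centre_bin - block_bins / 2)
    if (b0 < 0 || b0 + block_bins > nl)
      stop("chromcast_error: block outside the local window")
    ld <- features$local_delta
    ld[(b0 + 1):(b0 + block_bins)] <- 0
    pred <- combined_forward(model, onehot,
                             celltype_features(ld, features$global))
    eff[i] <- mean(abs(pred[ctr_bins, , drop = FALSE] - base_ctr))
  }
  structure(list(distance = distances, effect = eff, replicates = 1L,
                 centre_span = centre_span),
            class = "ProbeResult")
}

#' Off-centre prediction consistency
#'
#' For each region and cell, compares the centred prediction with two
#' off-centre predictions (input window slid by +/- the crop margin) at the
#' genomic bins the windows share, with or without a planted variant.
#' Reports the Pearson correlation per (region, cell, direction);
#' correlations over constant predictions are returned as `NA`.
#'
#' @param model A `cc_model`.
#' @param dataset A `cc_dataset`.
#' @param regions `RegionSpec` rows to test.
#' @param cells Cell labels.
#' @param add_variant Plant one random variant inside the shared span.
#' @param seed Seed for variant planting.
#' @return Data frame (chrom, window_start, cell, direction, variant,
#'   correlation).
#' @export
offcentre_consistency <- function(model, dataset, regions, cells,
                                  add_variant = FALSE, seed = 1L) {
  cfg <- dataset$cfg
  off <- crop_margin(cfg)
  nb <- n_bins(cfg)
  off_bins <- off / cfg$bin
  if (off_bins >= nb)
    stop("chromcast_error: no overlapping bins between placements")
  out <- list()
  nn_seeded(seed, {
    for (ri in seq_len(nrow(regions))) {
      for (cell in cells) {
        mk_item <- function(ws) data.frame(
          chrom = regions$chrom[ri], window_start = ws,
          input_start = ws - off, cell = cell, strand = "+", shift = 0)
        base_item <- mk_item(regions$window_start[ri])
        seqs <- dataset$sequences
        if (add_variant) {
          # plant inside the span shared by the centred and both shifted
          # prediction windows
          vpos <- regions$window_start[ri] + round(off / 2) +
            sample.int(cfg$window_len - off, 1)
          ch <- regions$chrom[ri]
          cur <- substring(seqs[[ch]], vpos + 1, vpos + 1)
          alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
          substring(seqs[[ch]], vpos + 1, vpos + 1) <- alt
        }
        ds2 <- dataset
        ds2$sequences <- seqs
        pred_for <- function(item)
          combined_forward(model, item_onehot(ds2, item),
                           item_features(ds2, item))
        p0 <- pred_for(base_item)
        for (dir in c(-1, 1)) {
          item <- mk_item(regions$window_start[ri] + dir * off)
          p1 <- pred_for(item)
          if (dir < 0) {
            a <- p0[seq_len(nb - off_bins), ]
            b <- p1[(off_bins + 1):nb, ]
          } else {
            a <- p0[(off_bins + 1):nb, ]
            b <- p1[seq_len(nb - off_bins), ]
          }
          r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
          else stats::cor(as.numeric(a), as.numeric(b))
          out[[length(out) + 1]] <- data.frame(
            chrom = regions$chrom[ri],
            window_start = regions$window_start[ri], cell = cell,
            direction = if (dir < 0) "upstream" else "downstream",
            variant = add_variant, correlation = r)
        }
      }
    }
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Gradient attribution of predicted peaks to the global accessibility input
#'
#' Calls peaks on the model's predicted tracks as non-overlapping 1024-bp
#' windows with mean -log10 p-value above the cutoff, scores each peak by
#' the summed absolute partial derivative of its mean predicted (arcsinh)
#' signal with respect to the global accessibility input, keeps the top 10%
#' by absolute attribution and optionally writes their DNA to FASTA.
#'
#' @param model A `cc_model`.
#' @param dataset A `cc_dataset`.
#' @param cell Cell label.
#' @param marks Marks to scan (default: all model marks).
#' @param peak_res Peak resolution in bp (default 1024).
#' @param cutoff Peak cutoff on the -log10 p scale (default 2).
#' @param top_frac Fraction of peaks kept (default 0.1).
#' @param fasta Optional FASTA output path for the selected peak sequences.
#' @return A list of class `AttributionReport`: `peaks` (all called peaks
#'   with attributions), `selected` (top fraction), `top_frac`.
#' @export
global_attribution <- function(model, dataset, cell,
                               marks = dataset$marks, peak_res = 1024,
                               cutoff = 2, top_frac = 0.1, fasta = NULL) {
  cfg <- dataset$cfg
  nb <- n_bins(cfg)
  bins_per_peak <- peak_res / cfg$bin
  preds <- predict_cell_tracks(model, dataset, cell,
                               output_scale = "neglog10p")
  rows <- list()
  for (mark in marks) {
    tr <- preds[[mark]]
    for (chrom in names(tr$values)) {
      v <- tr$values[[chrom]]
      n_pk <- floor(length(v) / bins_per_peak)
      if (n_pk < 1) next
      grp <- rep(seq_len(n_pk), each = bins_per_peak)
      mu <- rowsum(v[seq_len(n_pk * bins_per_peak)], grp)[, 1] / bins_per_peak
      hit <- which(mu > cutoff)
      for (h in hit)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = (h - 1) * peak_res, end = h * peak_res,
          mark = mark, mean_signal = mu[h])
    }
  }
  if (length(rows) == 0)
    return(structure(list(peaks = data.frame(), selected = data.frame(),
                          top_frac = top_frac),
                     class = "AttributionReport"))
  peaks <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  peaks$attribution <- NA_real_
  off <- crop_margin(cfg)
  for (i in seq_len(nrow(peaks))) {
    ws <- floor(peaks$start[i] / cfg$window_len) * cfg$window_len
    item <- data.frame(chrom = peaks$chrom[i], window_start = ws,
                       input_start = ws - off, cell = cell,
                       strand = "+", shift = 0)
    margin <- max(off, (cfg$local_atac_len - cfg$window_len) / 2)
    len <- chrom_length(dataset$genome, peaks$chrom[i])
    if (ws - margin < 0 || ws + cfg$window_len + margin > len) {
      peaks$attribution[i] <- 0
      next
    }
    latent <- backbone_forward(model$backbone, item_onehot(dataset, item))
    fw <- model_forward(model, latent, item_features(dataset, item),
                        keep_cache = TRUE)
    mi <- match(peaks$mark[i], dataset$marks)
    b0 <- (peaks$start[i] - ws) / cfg$bin
    pbins <- intersect((b0 + 1):(b0 + bins_per_peak), seq_len(nb))
    up <- matrix(0, nb, model$cfg$n_marks)
    up[pbins, mi] <- 1 / length(pbins)
    bk <- model_backward(model, fw, up)
    peaks$attribution[i] <- sum(abs(bk$dglobal))
  }
  n_keep <- max(1, floor(top_frac * nrow(peaks)))
  ord <- order(abs(peaks$attribution), decreasing = TRUE)
  selected <- peaks[ord[seq_len(n_keep)], , drop = FALSE]
  rownames(selected) <- NULL
  if (!is.null(fasta) && nrow(selected) > 0) {
    seqs <- vapply(seq_len(nrow(selected)), function(i)
      substring(dataset$sequences[[selected$chrom[i]]],
                selected$start[i] + 1, selected$end[i]), character(1))
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- sprintf("%s:%d-%d_%s", selected$chrom, selected$start,
                         selected$end, selected$mark)
    Biostrings::writeXStringSet(ss, fasta)
  }
  structure(list(peaks = peaks, selected = selected, top_frac = top_frac),
            class = "AttributionReport")
}
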