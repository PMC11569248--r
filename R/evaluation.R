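#' Stratified mean-squared-error report
#'
#' MSE between prediction and truth over all bins, over peak bins (truth at
#' or above the cutoff) and over no-peak bins, with the standard deviation
#' of the squared errors per stratum. Empty strata are reported as absent
#' (`NA` with zero count).
#'
#' @param pred,truth `BinnedTrack`s with matching geometry and scale.
#' @param cutoff Peak cutoff on the truth track's scale (default 2.0,
#'   -log10 p).
#' @return Data frame with one row per stratum (`all`, `peak`, `no_peak`):
#'   `mse`, `sd`, `n`.
#' @export
mse_report <- function(pred, truth, cutoff = 2.0) {
  if (!identical(pred$bin_size, truth$bin_size) ||
      !identical(lengths(pred$values), lengths(truth$values)))
    stop("chromcast_error: geometry mismatch between pred and truth")
  if (!identical(pred$scale, truth$scale))
    stop("chromcast_error: scale mismatch between pred and truth")
  p <- unlist(pred$values, use.names = FALSE)
  t <- unlist(truth$values, use.names = FALSE)
  se <- (p - t)^2
  strata <- list(all = rep(TRUE, length(t)), peak = t >= cutoff,
                 no_peak = t < cutoff)
  out <- lapply(names(strata), function(s) {
    m <- strata[[s]]
    if (!any(m)) return(data.frame(stratum = s, mse = NA_real_,
                                   sd = NA_real_, n = 0L))
    data.frame(stratum = s, mse = mean(se[m]), sd = stats::sd(se[m]),
               n = sum(m))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-chromosome Pearson correlation over a region set
#'
#' Correlates prediction and truth over bins falling inside the region set,
#' grouped by chromosome. Groups with fewer than 3 overlapping bins are
#' skipped with a message. When a `baseline` prediction is supplied, the
#' report tallies how many chromosomes the model out-correlates it on.
#'
#' @param pred,truth `BinnedTrack`s with matching geometry.
#' @param regions An `IntervalSet` restricting the evaluated bins.
#' @param baseline Optional second prediction `BinnedTrack`.
#' @return Data frame (chrom, n_bins, r, r_baseline, model_beats_baseline);
#'   attribute `n_beats` / `n_groups` summarise the tally.
#' @export
pearson_by_region <- function(pred, truth, regions, baseline = NULL) {
  if (!identical(pred$bin_size, truth$bin_size))
    stop("chromcast_error: geometry mismatch")
  bin <- pred$bin_size
  out <- list()
  for (chrom in names(truth$values)) {
    reg <- regions[regions$chrom == chrom, , drop = FALSE]
    if (nrow(reg) == 0) next
    nbv <- length(truth$values[[chrom]])
    sel <- rep(FALSE, nbv)
    for (i in seq_len(nrow(reg))) {
      b0 <- floor(reg$start[i] / bin)
      b1 <- min(nbv - 1, ceiling(reg$end[i] / bin) - 1)
      if (b1 >= b0) sel[(b0 + 1):(b1 + 1)] <- TRUE
    }
    if (sum(sel) < 3) {
      message("chromcast: skipping ", chrom, " (", sum(sel),
              " overlapping bins)")
      next
    }
    t <- truth$values[[chrom]][sel]
    p <- pred$values[[chrom]][sel]
    r <- suppressWarnings(stats::cor(p, t))
    rb <- if (!is.null(baseline))
      suppressWarnings(stats::cor(baseline$values[[chrom]][sel], t))
    else NA_real_
    out[[chrom]] <- data.frame(chrom = chrom, n_bins = sum(sel), r = r,
                               r_baseline = rb,
                               model_beats_baseline =
                                 if (!is.null(baseline)) isTRUE(r > rb)
                               else NA)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!is.null(res) && !is.null(baseline)) {
    attr(res, "n_beats") <- sum(res$model_beats_baseline, na.rm = TRUE)
    attr(res, "n_groups") <- nrow(res)
  }
  res
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a / gcd2(a, b) * b

#' Binarise-and-coarsen classification comparison
#'
#' Averages prediction and truth to the lowest common multiple of their bin
#' sizes (e.g. 128 and 200 bp meet at 3200 bp), binarises the truth at the
#' cutoff and reports AUROC plus the rank-based average precision of the
#' continuous prediction against the binary labels.
#'
#' @param pred,truth `BinnedTrack`s (possibly at different resolutions).
#' @param cutoff Binarisation cutoff on the truth scale (default 2.0).
#' @return List: `common_bin`, `auroc`, `ap`, `n`, `n_pos`.
#' @export
classification_compare <- function(pred, truth, cutoff = 2.0) {
  common <- lcm2(pred$bin_size, truth$bin_size)
  for (chrom in names(truth$values)) {
    if (common > chrom_length(truth$genome, chrom))
      stop("chromcast_error: common resolution exceeds chromosome length")
  }
  pc <- rebin(pred, common)
  tc <- rebin(truth, common)
  score <- unlist(pc$values, use.names = FALSE)
  labels <- as.integer(unlist(tc$values, use.names = FALSE) >= cutoff)
  if (length(unique(labels)) < 2)
    stop("chromcast_error: single-class truth after binarisation")
  roc <- pROC::roc(labels, score, quiet = TRUE, direction = "<")
  list(common_bin = common, auroc = as.numeric(pROC::auc(roc)),
       ap = average_precision(score, labels), n = length(labels),
       n_pos = sum(labels))
}

#' Rank-based average precision
#'
#' Mean of precisions at each threshold, weighted by the increase in recall
#' from the previous threshold: `sum_k (R_k - R_{k-1}) P_k` over predictions
#' sorted by decreasing score.
#'
#' @param score Numeric prediction scores.
#' @param labels Binary labels (0/1).
#' @return Average precision in \[0, 1\].
#' @export
average_precision <- function(score, labels) {
  o <- order(score, decreasing = TRUE)
  y <- labels[o]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}
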