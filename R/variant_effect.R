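#' Read a variant table (1-based TSV) into the internal 0-based form
#'
#' @param path TSV with columns `id`, `chrom`, `pos` (1-based), `ref`, `alt`.
#' @return Data frame with 0-based `pos`.
#' @export
read_variants <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$pos <- df$pos - 1
  df
}

validate_variant <- function(dataset, variant) {
  bases <- c("A", "C", "G", "T")
  if (!variant$ref %in% bases || !variant$alt %in% bases)
    stop("chromcast_error: only single-base A/C/G/T alleles supported")
  actual <- substring(dataset$sequences[[variant$chrom]],
                      variant$pos + 1, variant$pos + 1)
  if (actual != variant$ref)
    stop("chromcast_error: ref allele mismatch at ", variant$chrom, ":",
         variant$pos, " (genome has ", actual, ", variant says ",
         variant$ref, ")")
  invisible(TRUE)
}

#' Input-window placements covering a variant's full receptive field
#'
#' The variant is first centred in the input window; two further placements
#' slide the window by +/- (input_len - window_len) / 2 so that, keeping
#' only the non-overlapping flanks of the off-centre prediction windows, the
#' three appended prediction segments tile the full input span around the
#' variant without gaps or overlap. Placements whose input (or local
#' accessibility) window would leave the chromosome are dropped with a
#' warning.
#'
#' @param variant One-row data frame (`chrom`, `pos` 0-based).
#' @param cfg A `DataConfig`.
#' @param genome Optional `GenomeIndex` for boundary clipping.
#' @return Data frame with `window_start`, `input_start`, `keep_from`,
#'   `keep_to` (bin indices of the segment kept from each placement).
#' @export
window_placements <- function(variant, cfg, genome = NULL) {
  off <- crop_margin(cfg)
  nb <- n_bins(cfg)
  flank_bins <- off / cfg$bin
  centre_ws <- round((variant$pos - cfg$window_len / 2) / cfg$bin) * cfg$bin
  pl <- data.frame(
    placement = c("upstream", "centre", "downstream"),
    window_start = centre_ws + c(-off, 0, off),
    keep_from = c(1, 1, nb - flank_bins + 1),
    keep_to = c(flank_bins, nb, nb))
  pl$input_start <- pl$window_start - off
  if (!is.null(genome)) {
    len <- chrom_length(genome, variant$chrom)
    margin <- max(off, (cfg$local_atac_len - cfg$window_len) / 2)
    ok <- pl$window_start - margin >= 0 &
      pl$window_start + cfg$window_len + margin <= len
    if (!all(ok)) {
      warning("chromcast_warning: ", sum(!ok),
              " placement(s) clipped at chromosome end")
      pl <- pl[ok, , drop = FALSE]
    }
  }
  pl
}

onehot_with_allele <- function(oh, offset, base) {
  row <- numeric(4)
  row[match(base, c("A", "C", "G", "T"))] <- 1
  oh[offset, ] <- row
  oh
}

#' Full-receptive-field in-silico mutagenesis score for one variant
#'
#' For each window placement and augmentation (forward / reverse-complement
#' crossed with no shift / one seeded random whole-bin shift), predicts on
#' the reference and alternative sequence, takes the per-bin difference
#' (alt - ref) on the arcsinh scale, appends the three tiled placement
#' segments, sums over bins per mark and averages over augmentations. At
#' default settings this is 2 x 3 x 4 = 24 forward passes.
#'
#' @param model A `cc_model` (ignored when `predict_fn` is given).
#' @param dataset A `cc_dataset` (provides genome, sequence, accessibility).
#' @param variant One-row data frame (`id`, `chrom`, `pos` 0-based, `ref`,
#'   `alt`).
#' @param cell Cell whose accessibility conditions the prediction.
#'   Accessibility features are never modified for the alternative allele.
#' @param augment Use the full strand x shift augmentation set (default) or
#'   `FALSE` for the centred forward pass only.
#' @param sum_scale Scale differences are summed on: `"arcsinh"` (training
#'   scale, default) or `"neglog10p"`.
#' @param check_ref Verify the reference allele against the genome.
#' @param predict_fn Optional override `function(onehot, features)` returning
#'   a prediction grid; used for closed-form testing.
#' @return A list of class `SnpEffectScore`: `id`, `cell`, `score` (named
#'   per-mark signed sums), `n_passes`.
#' @export
score_variant <- function(model, dataset, variant, cell,
                          augment = TRUE, sum_scale = "arcsinh",
                          check_ref = TRUE, predict_fn = NULL) {
  cfg <- dataset$cfg
  if (check_ref) validate_variant(dataset, variant)
  if (is.null(predict_fn)) {
    predict_fn <- function(oh, feats)
      combined_forward(model, oh, feats,
                       output_scale = if (sum_scale == "arcsinh")
                         "arcsinh" else "neglog10p")
    M <- model$cfg$n_marks
    mark_names <- dataset$marks[seq_len(M)]
  } else {
    mark_names <- NULL
  }
  pl <- window_placements(variant, cfg, dataset$genome)
  shift_bins <- cfg$shift_max %/% cfg$bin
  var_seed <- sum(utf8ToInt(as.character(variant$id))) %% 1000000L
  rshift <- nn_seeded(var_seed, {
    s <- sample(setdiff((-shift_bins):shift_bins, 0), 1) * cfg$bin
    s
  })
  augs <- if (augment)
    expand.grid(strand = c("+", "-"), shift = c(0, rshift),
                stringsAsFactors = FALSE)
  else data.frame(strand = "+", shift = 0)
  total <- NULL
  n_passes <- 0L
  nl <- n_local_bins(cfg)
  lm <- (cfg$local_atac_len - cfg$window_len) / 2
  for (a in seq_len(nrow(augs))) {
    acc <- NULL
    for (p in seq_len(nrow(pl))) {
      ws <- pl$window_start[p] + augs$shift[a]
      ist <- pl$input_start[p] + augs$shift[a]
      oh <- seq_window_onehot(dataset, variant$chrom, ist, cfg$input_len, "+")
      offset <- variant$pos - ist + 1
      oh_ref <- onehot_with_allele(oh, offset, variant$ref)
      oh_alt <- onehot_with_allele(oh, offset, variant$alt)
      lstart <- ws - lm
      cell_arc <- asinh(track_window(dataset$atac[[cell]], variant$chrom,
                                     lstart, nl))
      avg_arc <- track_window(dataset$atac_arc_avg, variant$chrom,
                              lstart, nl)
      ld <- cell_arc - avg_arc
      if (augs$strand[a] == "-") {
        oh_ref <- one_hot_revcomp(oh_ref)
        oh_alt <- one_hot_revcomp(oh_alt)
        ld <- rev(ld)
      }
      feats <- celltype_features(ld, dataset$globals[, cell])
      pr <- predict_fn(oh_ref, feats)
      pa <- predict_fn(oh_alt, feats)
      n_passes <- n_passes + 2L
      d <- pa - pr
      if (augs$strand[a] == "-") d <- d[nrow(d):1, , drop = FALSE]
      seg <- d[pl$keep_from[p]:pl$keep_to[p], , drop = FALSE]
      acc <- if (is.null(acc)) colSums(seg) else acc + colSums(seg)
    }
    total <- if (is.null(total)) acc else total + acc
  }
  score <- total / nrow(augs)
  if (!is.null(mark_names)) names(score) <- mark_names
  structure(list(id = variant$id, cell = cell, score = score,
                 n_passes = n_passes),
            class = "SnpEffectScore")
}

#' Filter hQTL association records for model-based concordance testing
#'
#' Drops trans records (SNP and peak on different chromosomes), records
#' whose SNP-to-nearest-peak-edge distance exceeds the receptive field
#' (boundary retained), and SNPs outside the whitelist. Malformed records
#' (missing coordinates or non-finite beta) are skipped and counted.
#'
#' @param records Data frame with `id`, `chrom`, `pos`, `peak_chrom`,
#'   `peak_start`, `peak_end`, `beta`, `p`.
#' @param receptive_field Distance bound in bp.
#' @param whitelist Optional character vector of retained SNP ids.
#' @return Filtered records, with attribute `n_skipped` counting malformed
#'   rows.
#' @export
munge_hqtl <- function(records, receptive_field, whitelist = NULL) {
  need <- c("id", "chrom", "pos", "peak_chrom", "peak_start", "peak_end",
            "beta", "p")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0)
    stop("chromcast_error: records lack columns: ",
         paste(missing_cols, collapse = ", "))
  malformed <- !stats::complete.cases(records[need]) |
    !is.finite(records$beta) | records$p <= 0 | records$p > 1
  n_skipped <- sum(malformed)
  rec <- records[!malformed, , drop = FALSE]
  cis <- rec$chrom == rec$peak_chrom
  dist_edge <- pmax(0, pmax(rec$peak_start - rec$pos,
                            rec$pos - rec$peak_end + 1))
  near <- dist_edge <= receptive_field
  keep <- cis & near
  if (!is.null(whitelist)) keep <- keep & rec$id %in% whitelist
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Aggregate per-peak marginal effects to one signed value per SNP
#'
#' For SNP m with tested peak set G_m, the aggregate is
#' \eqn{\hat\alpha_m = |G_m|^{-1/2} \sum_{k \in G_m} \hat\alpha_m^{(k)}}.
#'
#' @param records Filtered hQTL records (`id`, `beta`).
#' @return Data frame with `id`, `alpha` and `n_peaks` (one row per SNP).
#' @export
aggregate_marginal <- function(records) {
  if (nrow(records) == 0)
    stop("chromcast_error: no records to aggregate")
  ids <- unique(records$id)
  out <- data.frame(id = ids, alpha = NA_real_, n_peaks = NA_integer_)
  for (i in seq_along(ids)) {
    b <- records$beta[records$id == ids[i]]
    out$alpha[i] <- sum(b) / sqrt(length(b))
    out$n_peaks[i] <- length(b)
  }
  out
}

#' Export sumstats and report score-vs-study concordance
#'
#' Joins model-side signed scores with study-side aggregated marginals,
#' writes a tab-separated sumstats file (SNP, A1, A2, signed score)
#' consumable by external signed-LD-profile tooling, and reports the
#' sign-concordance fraction with an exact binomial test against 0.5 plus
#' the Spearman rank correlation.
#'
#' @param scores List of `SnpEffectScore` objects (or a data frame with
#'   `id`, `score`).
#' @param marginals Output of [aggregate_marginal()].
#' @param variants Variant table supplying alleles for the export.
#' @param path Optional sumstats output path.
#' @param mark Mark whose score column is used when scores are multi-mark.
#' @return List: `n`, `concordance`, `binom_p`, `rank_cor`, `table`.
#' @export
export_and_concord <- function(scores, marginals, variants = NULL,
                               path = NULL, mark = NULL) {
  if (is.list(scores) && !is.data.frame(scores) &&
      inherits(scores[[1]], "SnpEffectScore")) {
    scores <- do.call(rbind, lapply(scores, function(s) {
      sc <- if (!is.null(mark) && !is.null(names(s$score)))
        s$score[[mark]] else s$score[[1]]
      data.frame(id = s$id, score = sc)
    }))
  }
  joined <- merge(scores, marginals, by = "id")
  if (nrow(joined) == 0)
    stop("chromcast_error: empty join between scores and marginals")
  if (!is.null(path)) {
    exp_df <- joined[, c("id", "score")]
    names(exp_df) <- c("SNP", "Z")
    if (!is.null(variants)) {
      vj <- merge(data.frame(id = joined$id), variants, by = "id",
                  sort = FALSE)
      exp_df <- data.frame(SNP = joined$id, A1 = vj$alt, A2 = vj$ref,
                           Z = joined$score)
    }
    utils::write.table(exp_df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  usable <- joined$score != 0 & joined$alpha != 0
  agree <- sign(joined$score[usable]) == sign(joined$alpha[usable])
  n <- sum(usable)
  conc <- if (n > 0) mean(agree) else NA_real_
  bp <- if (n > 0) stats::binom.test(sum(agree), n, p = 0.5)$p.value
  else NA_real_
  rc <- if (nrow(joined) > 2)
    stats::cor(joined$score, joined$alpha, method = "spearman")
  else NA_real_
  list(n = n, concordance = conc, binom_p = bp, rank_cor = rc,
       table = joined)
}
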