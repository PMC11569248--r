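#' Region specification table
#'
#' Training windows are rows of a data frame with columns `chrom`,
#' `window_start` (0-based prediction-window start), `input_start`
#' (derived: `window_start - (input_len - window_len) / 2`) and
#' `admitting_mark` (the histone mark whose coverage admitted the window, or
#' `"dna-only"` before coverage filtering).
#'
#' @name RegionSpec
NULL

region_spec <- function(chrom, window_start, cfg,
                        admitting_mark = "dna-only") {
  data.frame(chrom = as.character(chrom), window_start = window_start,
             input_start = window_start - crop_margin(cfg),
             admitting_mark = rep_len(admitting_mark,
                                      length(window_start)),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate training windows
#'
#' Tiles each chromosome with non-overlapping prediction windows of
#' `window_len` bp, then removes windows whose full DNA input window plus the
#' augmentation-shift margin would leave the chromosome, and windows
#' overlapping the blacklist.
#'
#' @param genome A `GenomeIndex`.
#' @param blacklist An `IntervalSet` (may be empty).
#' @param cfg A `DataConfig`.
#' @return A `RegionSpec` data frame; zero rows (with a warning) when no
#'   window survives.
#' @export
enumerate_candidates <- function(genome, blacklist, cfg) {
  margin <- max(crop_margin(cfg),
                (cfg$local_atac_len - cfg$window_len) / 2) + cfg$shift_max
  out <- list()
  for (chrom in genome$names) {
    len <- chrom_length(genome, chrom)
    if (len <= cfg$input_len + 2 * cfg$shift_max) next
    starts <- seq(0, len - cfg$window_len, by = cfg$window_len)
    ok <- (starts - margin >= 0) & (starts + cfg$window_len + margin <= len)
    starts <- starts[ok]
    if (length(starts) == 0) next
    bad <- overlaps_any(chrom, starts, starts + cfg$window_len, blacklist)
    starts <- starts[!bad]
    if (length(starts) > 0)
      out[[chrom]] <- region_spec(chrom, starts, cfg)
  }
  if (length(out) == 0) {
    warning("chromcast_warning: no candidate windows survive filtering")
    return(region_spec(character(), numeric(), cfg)[0, ])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Coverage-filter windows per histone mark
#'
#' A window passes for a mark iff, in at least one supplied cell track for
#' that mark, the fraction of window bins with -log10 p-value at or above
#' `peak_cutoff` strictly exceeds `coverage_frac`.
#'
#' @param regions A `RegionSpec` data frame.
#' @param mark_tracks Named list (one element per mark) of lists of
#'   neglog10p-scale `BinnedTrack`s at `cfg$bin` resolution (one per cell).
#' @param cfg A `DataConfig`.
#' @return Named list of `RegionSpec` data frames, one per mark, with
#'   `admitting_mark` set.
#' @export
coverage_filter <- function(regions, mark_tracks, cfg) {
  nb <- n_bins(cfg)
  out <- list()
  for (mark in names(mark_tracks)) {
    tracks <- mark_tracks[[mark]]
    for (tr in tracks) {
      if (tr$scale != "neglog10p")
        stop("chromcast_error: coverage filter needs neglog10p-scale tracks")
      if (tr$bin_size != cfg$bin)
        stop("chromcast_error: track resolution != cfg$bin")
    }
    pass <- logical(nrow(regions))
    for (i in seq_len(nrow(regions))) {
      for (tr in tracks) {
        w <- track_window(tr, regions$chrom[i], regions$window_start[i], nb)
        if (mean(w >= cfg$peak_cutoff) > cfg$coverage_frac) {
          pass[i] <- TRUE
          break
        }
      }
    }
    kept <- regions[pass, , drop = FALSE]
    kept$admitting_mark <- rep_len(mark, nrow(kept))
    rownames(kept) <- NULL
    out[[mark]] <- kept
  }
  out
}

#' Balance admitted windows across marks
#'
#' Down-samples every mark's admitted-window list to the size of the
#' smallest one (uniformly, without replacement, reproducibly from `seed`)
#' and returns the union.
#'
#' @param per_mark_regions Named list of `RegionSpec` data frames.
#' @param seed Integer seed.
#' @return A `RegionSpec` data frame with equal per-mark counts.
#' @export
balance_marks <- function(per_mark_regions, seed = 1L) {
  sizes <- vapply(per_mark_regions, nrow, integer(1))
  if (any(sizes == 0))
    stop("chromcast_error: a mark has no admitted regions")
  n_min <- min(sizes)
  out <- nn_seeded(seed, {
    lapply(seq_along(per_mark_regions), function(i) {
      df <- per_mark_regions[[i]]
      df <- df[sort(sample.int(nrow(df), n_min)), , drop = FALSE]
      nm <- names(per_mark_regions)[i]
      if (!is.null(nm) && nzchar(nm))
        df$admitting_mark <- rep_len(nm, nrow(df))
      df
    })
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Distribution target over cell types
#'
#' Component k is the fraction of cell types whose signal value falls into
#' bin k, with bins `[0, e1), [e1, e2), ..., [e_{K-1}, Inf)`. Values are raw
#' -log10 p-values by default (a configuration flag switches to the arcsinh
#' scale; first and last components are unaffected for typical edges).
#'
#' @param values Non-negative numeric vector, one value per cell type.
#' @param edges Strictly increasing internal bin edges (the top bin is
#'   open-ended); default `seq(0.5, 4.5, 0.5)` giving K = 10.
#' @return Numeric K-simplex vector (sums to 1).
#' @export
build_distribution <- function(values, edges = seq(0.5, 4.5, by = 0.5)) {
  if (any(values < 0))
    stop("chromcast_error: negative input to build_distribution")
  breaks <- c(0, edges, Inf)
  h <- hist(values, breaks = breaks, right = FALSE, plot = FALSE)
  h$counts / length(values)
}

#' Per-window target bundle
#'
#' For one training window and one target cell, builds the three
#' prediction targets: `avg` (cross-cell mean of the arcsinh signal, bins x
#' marks), `dist` (per bin x mark K-simplex of the cross-cell signal
#' distribution) and `delta` (target-cell arcsinh signal minus `avg`), plus
#' the cell's own signal (`cell_signal = avg + delta`).
#'
#' @param region One-row `RegionSpec`.
#' @param mark_tracks_by_cell Nested list `tracks[[cell]][[mark]]` of
#'   neglog10p-scale `BinnedTrack`s at `cfg$bin` resolution.
#' @param cell Target cell label (must be present in the table).
#' @param cfg A `DataConfig`.
#' @param avg_cells Cells the average/distribution are computed over
#'   (defaults to all; pass the training cells to exclude a held-out target).
#' @return A list of class `TargetBundle`.
#' @export
build_targets <- function(region, mark_tracks_by_cell, cell, cfg,
                          avg_cells = names(mark_tracks_by_cell)) {
  if (!cell %in% names(mark_tracks_by_cell))
    stop("chromcast_error: cell '", cell, "' absent from track table")
  marks <- names(mark_tracks_by_cell[[1]])
  nb <- n_bins(cfg)
  K <- cfg$n_dist_bins
  avg <- matrix(0, nb, length(marks), dimnames = list(NULL, marks))
  delta <- avg
  cell_signal <- avg
  dist <- array(0, dim = c(nb, length(marks), K))
  for (mi in seq_along(marks)) {
    raw <- vapply(avg_cells, function(cl)
      track_window(mark_tracks_by_cell[[cl]][[marks[mi]]],
                   region$chrom, region$window_start, nb), numeric(nb))
    if (!is.matrix(raw)) raw <- matrix(raw, nrow = nb)
    a <- asinh(raw)
    avg[, mi] <- rowMeans(a)
    dvals <- if (cfg$dist_on_arcsinh) a else raw
    for (b in seq_len(nb))
      dist[b, mi, ] <- build_distribution(dvals[b, ], cfg$dist_edges)
    cs <- asinh(track_window(mark_tracks_by_cell[[cell]][[marks[mi]]],
                             region$chrom, region$window_start, nb))
    cell_signal[, mi] <- cs
    delta[, mi] <- cs - avg[, mi]
  }
  structure(list(avg = avg, dist = dist, delta = delta,
                 cell_signal = cell_signal),
            class = "TargetBundle")
}

#' Train/validation split with augmentation
#'
#' Training items are (region, cell, strand, shift) tuples over regions off
#' the validation chromosomes and cells outside the held-out fraction; both
#' strands are emitted per (region, cell) with a seeded whole-bin random
#' shift in `[-shift_max, shift_max]`. Validation items use the held-out
#' cells on the validation chromosomes, forward strand, with window starts
#' jittered by a seeded whole-bin shift.
#'
#' @param regions A `RegionSpec` data frame.
#' @param cells Character vector of cell labels.
#' @param cfg A `DataConfig`.
#' @return List with `train` and `val` item data frames (columns `chrom`,
#'   `window_start`, `input_start`, `admitting_mark`, `cell`, `strand`,
#'   `shift`) and `train_cells` / `val_cells`.
#' @export
make_splits_and_augment <- function(regions, cells, cfg) {
  n_val <- round(cfg$val_cell_frac * length(cells))
  if (n_val < 1)
    stop("chromcast_error: val_cell_frac rounds to zero validation cells")
  nn_seeded(cfg$seed, {
    val_cells <- sort(sample(cells, n_val))
    train_cells <- setdiff(cells, val_cells)
    is_val_chrom <- regions$chrom %in% cfg$val_chroms
    tr_reg <- regions[!is_val_chrom, , drop = FALSE]
    va_reg <- regions[is_val_chrom, , drop = FALSE]
    shift_bins <- cfg$shift_max %/% cfg$bin
    shift_pool <- (-shift_bins):shift_bins * cfg$bin
    mk_items <- function(reg, cls, strands) {
      if (nrow(reg) == 0 || length(cls) == 0)
        return(cbind(reg[0, ], cell = character(), strand = character(),
                     shift = numeric()))
      g <- expand.grid(r = seq_len(nrow(reg)), cell = cls,
                       strand = strands, stringsAsFactors = FALSE)
      items <- reg[g$r, , drop = FALSE]
      items$cell <- g$cell
      items$strand <- g$strand
      items$shift <- sample(shift_pool, nrow(items), replace = TRUE)
      rownames(items) <- NULL
      items
    }
    train <- mk_items(tr_reg, train_cells, c("+", "-"))
    val <- mk_items(va_reg, val_cells, "+")
    if (nrow(val) > 0) {
      val$window_start <- val$window_start + val$shift
      val$input_start <- val$input_start + val$shift
      val$shift <- 0
    }
    list(train = train, val = val, train_cells = train_cells,
         val_cells = val_cells)
  })
}
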