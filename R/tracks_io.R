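#' Binned signal track
#'
#' A fixed-resolution per-chromosome signal vector with a scale tag. The three
#' scales are `neglog10p` (MACS2-style -log10 adjusted p-values, non-negative),
#' `arcsinh` (variance-stabilised signal used for training) and `delta`
#' (signed cell-minus-average differences).
#'
#' @param genome A `GenomeIndex`.
#' @param bin_size Bin width in base pairs.
#' @param values Named list with one numeric vector per chromosome of length
#'   `ceiling(chrom_length / bin_size)`.
#' @param assay Assay label (histone-mark name or "ATAC").
#' @param cell Cell-type label.
#' @param scale One of `"neglog10p"`, `"arcsinh"`, `"delta"`.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(genome, bin_size, values, assay = "signal",
                         cell = "cell", scale = "neglog10p") {
  scale <- match.arg(scale, c("neglog10p", "arcsinh", "delta"))
  if (!all(names(values) %in% genome$names))
    stop("chromcast_error: unknown chromosome in track values")
  for (chrom in names(values)) {
    v <- values[[chrom]]
    nb <- ceiling(chrom_length(genome, chrom) / bin_size)
    if (length(v) != nb)
      stop("chromcast_error: ", chrom, " has ", length(v),
           " bins, expected ", nb)
    if (any(!is.finite(v)))
      stop("chromcast_error: non-finite values on ", chrom)
    if (scale == "neglog10p" && any(v < 0))
      stop("chromcast_error: negative values on neglog10p scale")
  }
  structure(list(genome = genome, bin_size = bin_size, values = values,
                 assay = assay, cell = cell, scale = scale),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack: assay=%s cell=%s scale=%s bin=%d bp, %d chromosome(s)\n",
              x$assay, x$cell, x$scale, as.integer(x$bin_size),
              length(x$values)))
  invisible(x)
}

n_track_bins <- function(genome, chrom, bin_size) {
  as.integer(ceiling(chrom_length(genome, chrom) / bin_size))
}

#' Read or write a binned signal track
#'
#' One entry point for track serialisation. Reading fills unspecified
#' positions with 0 (the "no evidence" convention for -log10 p-value tracks)
#' and bin-averages intervals that do not align with the bin grid, weighting
#' by base-pair overlap. bedGraph writing emits values at 17 significant
#' digits so a write-then-read round trip is value-exact.
#'
#' @param path File path.
#' @param mode `"read"` or `"write"`.
#' @param format `"bedGraph"`, `"wig"` (fixedStep) or `"bigWig"`.
#' @param genome `GenomeIndex` the track lives on.
#' @param track For `mode = "write"`, the `BinnedTrack` to serialise.
#' @param bin_size For `mode = "read"`, the target bin width in base pairs.
#' @param assay,cell,scale Labels attached to a track being read.
#' @return A `BinnedTrack` for reads; `path` invisibly for writes.
#' @export
track_io <- function(path, mode = c("read", "write"),
                     format = c("bedGraph", "wig", "bigWig"),
                     genome, track = NULL, bin_size = NULL,
                     assay = "signal", cell = "cell", scale = "neglog10p") {
  mode <- match.arg(mode)
  format <- match.arg(format)
  if (mode == "write") {
    if (is.null(track)) stop("chromcast_error: no track supplied for write")
    switch(format,
           bedGraph = write_bedgraph(track, path),
           wig = write_wig_fixedstep(track, path),
           bigWig = write_bigwig(track, path))
    return(invisible(path))
  }
  if (is.null(bin_size)) stop("chromcast_error: bin_size required for read")
  if (!file.exists(path)) stop("chromcast_error: file not found: ", path)
  gr <- switch(format,
               bedGraph = rtracklayer::import(path, format = "bedGraph"),
               wig = rtracklayer::import(path, format = "wig"),
               bigWig = rtracklayer::import(path, format = "bigWig"))
  granges_to_track(gr, genome, bin_size, assay = assay, cell = cell,
                   scale = scale,
                   check_overlap = (format == "bedGraph"))
}

granges_to_track <- function(gr, genome, bin_size, assay, cell, scale,
                             check_overlap = TRUE) {
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- setdiff(unique(chroms), genome$names)
  if (length(bad) > 0)
    stop("chromcast_error: unknown chromosome '", bad[1], "' in track file")
  starts <- GenomicRanges::start(gr) - 1    # to 0-based half-open
  ends <- GenomicRanges::end(gr)
  score <- as.numeric(gr$score)
  values <- list()
  for (chrom in genome$names) {
    len <- chrom_length(genome, chrom)
    idx <- which(chroms == chrom)
    # accumulate base-pair level coverage-weighted sums per bin; bins fully
    # covered by a single interval take its score directly so that aligned
    # write-then-read round trips are value-exact to the last bit
    nb <- as.integer(ceiling(len / bin_size))
    acc <- numeric(nb)
    covered <- numeric(nb)
    nint <- integer(nb)
    direct <- numeric(nb)
    if (length(idx) > 0) {
      o <- idx[order(starts[idx])]
      if (check_overlap && length(o) > 1 &&
          any(starts[o][-1] < ends[o][-length(o)]))
        stop("chromcast_error: overlapping bedGraph intervals on ", chrom)
      if (any(ends[idx] > len))
        stop("chromcast_error: interval beyond end of ", chrom)
      for (i in idx) {
        s <- starts[i]; e <- ends[i]
        b0 <- floor(s / bin_size); b1 <- floor((e - 1) / bin_size)
        bins <- b0:b1
        left <- pmax(s, bins * bin_size)
        right <- pmin(e, (bins + 1) * bin_size)
        acc[bins + 1] <- acc[bins + 1] + score[i] * (right - left)
        covered[bins + 1] <- covered[bins + 1] + (right - left)
        nint[bins + 1] <- nint[bins + 1] + 1L
        direct[bins + 1] <- score[i]
      }
    }
    widths <- pmin((seq_len(nb)) * bin_size, len) - (seq_len(nb) - 1) * bin_size
    vals <- acc / widths
    exact <- nint == 1L & covered == widths
    vals[exact] <- direct[exact]
    values[[chrom]] <- vals
  }
  binned_track(genome, bin_size, values, assay = assay, cell = cell,
               scale = scale)
}

# Collapse a per-bin vector into (start, end, value) runs, dropping zeros.
track_runs <- function(track, keep_zero = FALSE) {
  out <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    len <- chrom_length(track$genome, chrom)
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- if (keep_zero) rep(TRUE, length(r$values)) else r$values != 0
    if (!any(keep)) next
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = starts_bin[keep] * track$bin_size,
      end = pmin(ends_bin[keep] * track$bin_size, len),
      value = r$values[keep])
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

write_bedgraph <- function(track, path) {
  runs <- track_runs(track, keep_zero = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(runs) > 0)
    writeLines(sprintf("%s\t%s\t%s\t%.17g", runs$chrom,
                       format(runs$start, scientific = FALSE, trim = TRUE),
                       format(runs$end, scientific = FALSE, trim = TRUE),
                       runs$value), con)
  invisible(path)
}

write_wig_fixedstep <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       chrom, as.integer(track$bin_size),
                       as.integer(track$bin_size)), con)
    writeLines(sprintf("%.17g", v), con)
  }
  invisible(path)
}

track_to_granges <- function(track, keep_zero = TRUE) {
  runs <- track_runs(track, keep_zero = keep_zero)
  gr <- GenomicRanges::GRanges(
    seqnames = runs$chrom,
    ranges = IRanges::IRanges(start = runs$start + 1, end = runs$end),
    score = runs$value)
  GenomeInfoDb::seqinfo(gr) <-
    genome_seqinfo(track$genome)[GenomeInfoDb::seqlevels(gr)]
  gr
}

write_bigwig <- function(track, path) {
  rtracklayer::export(track_to_granges(track), path, format = "bigWig")
  invisible(path)
}

#' Rebin a track to a coarser resolution
#'
#' Each output bin holds the base-pair-overlap-weighted mean of the input bins
#' it covers; fractional overlaps are handled exactly (needed e.g. when going
#' from 25 bp to 128 bp bins, which do not nest). Trailing partial bins at
#' chromosome ends hold the mean over covered bases only, so the base-pair
#' weighted genome-wide mean is conserved.
#'
#' @param track A `BinnedTrack`.
#' @param new_bin New bin width in base pairs (`>= track$bin_size`).
#' @return A `BinnedTrack` at `new_bin` resolution.
#' @export
rebin <- function(track, new_bin) {
  if (new_bin < track$bin_size)
    stop("chromcast_error: upsampling unsupported (new_bin < bin_size)")
  if (new_bin == track$bin_size) return(track)
  values <- list()
  for (chrom in names(track$values)) {
    len <- chrom_length(track$genome, chrom)
    per_base <- rep(track$values[[chrom]], each = track$bin_size)[seq_len(len)]
    cs <- c(0, cumsum(per_base))
    nb <- as.integer(ceiling(len / new_bin))
    lo <- (seq_len(nb) - 1) * new_bin
    hi <- pmin(seq_len(nb) * new_bin, len)
    values[[chrom]] <- (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
  }
  binned_track(track$genome, new_bin, values, assay = track$assay,
               cell = track$cell, scale = track$scale)
}

#' Arcsinh-transform a track (forward or inverse)
#'
#' Applies the variance-stabilising transform
#' \eqn{\sinh^{-1} x = \ln(x + \sqrt{1 + x^2})} elementwise (forward), or its
#' inverse \eqn{\sinh}. The scale tag flips between `neglog10p` and `arcsinh`.
#'
#' @param track A `BinnedTrack` on the matching input scale.
#' @param direction `"forward"` (neglog10p -> arcsinh) or `"inverse"`.
#' @return A transformed `BinnedTrack`.
#' @export
arcsinh_transform <- function(track, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (direction == "forward" && track$scale != "neglog10p")
    stop("chromcast_error: forward transform needs a neglog10p-scale track")
  if (direction == "inverse" && track$scale != "arcsinh")
    stop("chromcast_error: inverse transform needs an arcsinh-scale track")
  f <- if (direction == "forward") asinh else sinh
  values <- lapply(track$values, f)
  binned_track(track$genome, track$bin_size, values, assay = track$assay,
               cell = track$cell,
               scale = if (direction == "forward") "arcsinh" else "neglog10p")
}

#' Elementwise mean of a set of tracks
#'
#' All tracks must share genome, bin size, scale and assay. The result carries
#' cell label `"average"`.
#'
#' @param tracks List of `BinnedTrack` objects.
#' @return The average `BinnedTrack`.
#' @export
average_tracks <- function(tracks) {
  if (length(tracks) == 0) stop("chromcast_error: no tracks to average")
  t1 <- tracks[[1]]
  for (tr in tracks[-1]) {
    if (!identical(tr$bin_size, t1$bin_size) ||
        !identical(tr$scale, t1$scale) ||
        !identical(tr$assay, t1$assay) ||
        !identical(names(tr$values), names(t1$values)) ||
        !identical(lengths(tr$values), lengths(t1$values)))
      stop("chromcast_error: mismatched geometry or scale in average_tracks")
  }
  values <- list()
  for (chrom in names(t1$values)) {
    m <- vapply(tracks, function(tr) tr$values[[chrom]],
                numeric(length(t1$values[[chrom]])))
    values[[chrom]] <- if (is.matrix(m)) rowMeans(m) else mean(m)
  }
  binned_track(t1$genome, t1$bin_size, values, assay = t1$assay,
               cell = "average", scale = t1$scale)
}

#' Extract a window of bins from a track
#'
#' @param track A `BinnedTrack`.
#' @param chrom Chromosome name.
#' @param start Window start in bp (0-based, must be bin-aligned).
#' @param n_bins Number of bins.
#' @return Numeric vector of length `n_bins`.
#' @export
track_window <- function(track, chrom, start, n_bins) {
  if (start %% track$bin_size != 0)
    stop("chromcast_error: window start not bin-aligned")
  b0 <- start / track$bin_size
  v <- track$values[[chrom]]
  if (is.null(v)) stop("chromcast_error: no values for ", chrom)
  if (b0 < 0 || b0 + n_bins > length(v))
    stop("chromcast_error: window outside chromosome")
  v[(b0 + 1):(b0 + n_bins)]
}
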