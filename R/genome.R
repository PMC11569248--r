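#' Genome index
#'
#' A minimal chromosome-name/length table against which all tracks, intervals
#' and windows are validated. Coordinates are 0-based, half-open everywhere
#' inside the package; 1-based inputs (e.g. variant TSVs) are converted at
#' their readers.
#'
#' @param names Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in base pairs (> 0).
#' @return An object of class `GenomeIndex`.
#' @export
genome_index <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths))
    stop("chromcast_error: names and lengths differ in length")
  if (anyDuplicated(names))
    stop("chromcast_error: duplicate chromosome names")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromcast_error: chromosome lengths must be finite and > 0")
  structure(list(names = names, lengths = stats::setNames(lengths, names)),
            class = "GenomeIndex")
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat("GenomeIndex with", length(x$names), "chromosomes\n")
  print(utils::head(data.frame(chrom = x$names, length = unname(x$lengths)), 10))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  if (!chrom %in% genome$names)
    stop("chromcast_error: unknown chromosome '", chrom, "'")
  unname(genome$lengths[[chrom]])
}

#' Seqinfo view of a GenomeIndex
#' @param genome A `GenomeIndex`.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @keywords internal
genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = genome$names,
                        seqlengths = as.integer(genome$lengths))
}

#' Interval set
#'
#' Records of (chromosome, start, end) in 0-based half-open coordinates with an
#' optional name. Used for blacklists, region sets and peak intervals.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open (`start < end`).
#' @param name Optional character vector of record names.
#' @param genome Optional `GenomeIndex`; when given, intervals are checked to
#'   lie within chromosome bounds.
#' @return A data frame of class `IntervalSet`.
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), name = NULL, genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (nrow(df) > 0) {
    if (any(df$start >= df$end))
      stop("chromcast_error: interval start must be < end")
    if (any(df$start < 0))
      stop("chromcast_error: negative interval start")
    if (!is.null(genome)) {
      for (i in seq_len(nrow(df))) {
        len <- chrom_length(genome, df$chrom[i])
        if (df$end[i] > len)
          stop("chromcast_error: interval beyond chromosome end on ", df$chrom[i])
      }
    }
  }
  class(df) <- c("IntervalSet", "data.frame")
  df
}

#' Convert an IntervalSet to GRanges (1-based closed, as GRanges expects)
#' @keywords internal
intervals_to_granges <- function(x, genome = NULL) {
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
  if (!is.null(genome))
    GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(genome)[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Read a BED3/BED4 file as an IntervalSet
#'
#' @param path Path to a BED file.
#' @param genome Optional `GenomeIndex` used for bounds checking.
#' @return An `IntervalSet` (0-based half-open).
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NULL
  interval_set(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr),
               name = nm, genome = genome)
}

#' Write an IntervalSet as BED
#'
#' @param x An `IntervalSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)[, c("chrom", "start", "end")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  if (!is.null(x$name)) df$name <- x$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fraction of an interval overlapping a window, in base pairs
#' @keywords internal
overlaps_any <- function(chrom, start, end, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(start)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  s <- intervals_to_granges(intervals)
  IRanges::overlapsAny(q, s)
}
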