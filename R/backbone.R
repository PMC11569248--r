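#' Construct a frozen toy DNA backbone
#'
#' A small convolution/pooling stack standing in for a large pre-trained
#' sequence model: a base-pair-level convolution, average pooling down to the
#' output bin width, and two bin-level convolutions, cropped to the central
#' prediction bins. The receptive field is analytically computable and the
#' weights are frozen (never updated by any trainer in this package).
#'
#' When a motif vocabulary is supplied, the first-layer filters are seeded as
#' exact-match detectors for each motif and its reverse complement (remaining
#' channels random). This emulates the motif-detecting early filters that a
#' genome-pretrained backbone brings to transfer learning; without motifs the
#' backbone is a random frozen feature extractor.
#'
#' @param cfg A `ModelConfig`.
#' @param seed Integer seed for weight initialisation.
#' @param motifs Optional character vector of consensus motifs (A/C/G/T,
#'   length <= base-level kernel width).
#' @return An object of class `BackboneContract` with fields `params`,
#'   `input_len`, `n_bins` (T), `channels` (C), `receptive_field` (R, bp),
#'   `frozen`, `hash`.
#' @export
make_toy_backbone <- function(cfg, seed = cfg$seed, motifs = NULL) {
  dcfg <- cfg$data_cfg
  bin <- dcfg$bin
  if (dcfg$input_len %% bin != 0 ||
      (dcfg$input_len - dcfg$window_len) %% (2 * bin) != 0)
    stop("chromcast_error: input geometry not reducible to output bins")
  ks <- cfg$backbone_kernels
  C <- cfg$backbone_channels
  if (!is.null(motifs) && any(nchar(motifs) > ks[1]))
    stop("chromcast_error: motif longer than base-level kernel")
  n_seeded <- if (is.null(motifs)) 0L else 2L * length(motifs)
  if (n_seeded > C)
    stop("chromcast_error: backbone_channels too small for motif seeding")
  params <- nn_seeded(seed, {
    conv1 <- init_conv1d(ks[1], 4L, C, sd = 0.3)
    conv2 <- init_conv1d(ks[2], C, C, sd = 0.01)
    conv3 <- init_conv1d(ks[3], C, C, sd = 0.01)
    if (n_seeded > 0) {
      base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ch <- 0L
      for (mot in motifs) {
        for (orient in 1:2) {
          ch <- ch + 1L
          s <- strsplit(mot, "")[[1]]
          if (orient == 2) s <- rev(unname(comp[s]))
          m <- length(s)
          off <- (ks[1] - m) %/% 2
          W <- matrix(0, ks[1], 4)
          for (j in seq_len(m)) {
            W[off + j, ] <- -1
            W[off + j, base_idx[[s[j]]]] <- 1
          }
          conv1$W[, , ch] <- W
          conv1$b[ch] <- -(m - 1)
        }
      }
      # seeded channels propagate through bin-level convs with a
      # Gaussian-spread gain, so a single motif hit surfaces in the latent
      # as a peak-shaped bump of order-one height spanning a few bins
      mid2 <- (ks[2] + 1) %/% 2
      mid3 <- (ks[3] + 1) %/% 2
      prof2 <- exp(-((seq_len(ks[2]) - mid2)^2) / (2 * 1.2^2))
      prof3 <- exp(-((seq_len(ks[3]) - mid3)^2) / (2 * 1.0^2))
      gain <- sqrt(bin * 2 / (max(prof2) * max(prof3)))
      for (c in seq_len(n_seeded)) {
        conv2$W[, c, c] <- gain * prof2
        conv3$W[, c, c] <- gain * prof3
      }
    }
    list(conv1 = conv1, conv2 = conv2, conv3 = conv3)
  })
  R <- bin * ((ks[2] - 1) + (ks[3] - 1) + 1) + (ks[1] - 1)
  bb <- structure(list(params = params, input_len = dcfg$input_len,
                       bin = bin, n_bins = n_bins(dcfg), channels = C,
                       kernels = ks, receptive_field = R, frozen = TRUE,
                       hash = NA_character_),
                  class = "BackboneContract")
  bb$hash <- object_hash(bb$params)
  bb
}

#' @export
print.BackboneContract <- function(x, ...) {
  cat(sprintf(
    "BackboneContract: input %d bp -> latent %d x %d, receptive field %d bp%s\n",
    x$input_len, x$n_bins, x$channels, x$receptive_field,
    if (x$frozen) " (frozen)" else ""))
  invisible(x)
}

#' Forward pass through the frozen backbone
#'
#' @param backbone A `BackboneContract`.
#' @param onehot One-hot DNA matrix (`input_len` x 4).
#' @return Latent matrix (T x C) over the central prediction bins.
#' @export
backbone_forward <- function(backbone, onehot) {
  if (nrow(onehot) != backbone$input_len || ncol(onehot) != 4)
    stop("chromcast_error: one-hot input must be ", backbone$input_len, " x 4")
  p <- backbone$params
  h <- relu_forward(conv1d_forward(onehot, p$conv1)$y)$y
  h <- avgpool_forward(h, backbone$bin)$y
  h <- relu_forward(conv1d_forward(h, p$conv2)$y)$y
  h <- relu_forward(conv1d_forward(h, p$conv3)$y)$y
  total_bins <- backbone$input_len %/% backbone$bin
  margin <- (total_bins - backbone$n_bins) %/% 2
  h[(margin + 1):(margin + backbone$n_bins), , drop = FALSE]
}

#' One-hot encode a DNA string
#'
#' A = (1,0,0,0), C = (0,1,0,0), G = (0,0,1,0), T = (0,0,0,1); any other
#' letter (e.g. N) encodes as all-zero.
#'
#' @param seq A character scalar or `Biostrings::DNAString`.
#' @return Matrix (nchar x 4).
#' @export
one_hot <- function(seq) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  m <- matrix(0, length(s), 4)
  for (i in 1:4) m[s == c("A", "C", "G", "T")[i], i] <- 1
  m
}

#' Reverse-complement a one-hot matrix
#' @param onehot Matrix (L x 4) in A,C,G,T column order.
#' @return The reverse-complemented one-hot matrix.
#' @export
one_hot_revcomp <- function(onehot) {
  onehot[rev(seq_len(nrow(onehot))), c(4, 3, 2, 1), drop = FALSE]
}
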