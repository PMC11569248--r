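#' Data-geometry and filtering configuration
#'
#' Holds every geometry constant and filter threshold used when building
#' training windows and targets. Defaults are the full-scale profile (196,608
#' bp DNA input, 114,688 bp prediction window, 128 bp bins); use
#' [toy_data_config()] for a desk-scale geometry.
#'
#' @param window_len Prediction-window length in bp (multiple of `bin`).
#' @param input_len DNA input length in bp (> `window_len`).
#' @param local_atac_len Local accessibility window length in bp.
#' @param bin Output bin width in bp.
#' @param global_bin Bin width for the global accessibility vector, bp.
#' @param tss_window Width around each marker-gene TSS, bp.
#' @param n_marker_genes Number of marker-gene TSSs anchoring the global
#'   accessibility vector.
#' @param n_dist_bins Number of distribution-target bins K.
#' @param dist_edges Ascending internal edges of the distribution bins; the
#'   top bin is open-ended. `length(dist_edges) == n_dist_bins - 1`.
#' @param peak_cutoff -log10 p-value at or above which a bin counts as a peak.
#' @param coverage_frac Fraction of peak bins a window must strictly exceed
#'   for a mark to admit it.
#' @param dist_on_arcsinh Build distribution targets on the arcsinh scale
#'   instead of raw -log10 p-values.
#' @param val_cell_frac Fraction of cells held out for validation.
#' @param val_chroms Chromosomes held out for validation.
#' @param shift_max Maximum augmentation shift in bp (whole-bin multiple).
#' @param seed Integer seed for all randomised choices downstream.
#' @return A list of class `DataConfig`.
#' @export
data_config <- function(window_len = 114688, input_len = 196608,
                        local_atac_len = 199936, bin = 128, global_bin = 250,
                        tss_window = 3000, n_marker_genes = 1216,
                        n_dist_bins = 10,
                        dist_edges = seq(0.5, 4.5, by = 0.5),
                        peak_cutoff = 2.0, coverage_frac = 0.125,
                        dist_on_arcsinh = FALSE,
                        val_cell_frac = 0.2, val_chroms = character(),
                        shift_max = 3 * bin, seed = 1L) {
  cfg <- list(window_len = window_len, input_len = input_len,
              local_atac_len = local_atac_len, bin = bin,
              global_bin = global_bin, tss_window = tss_window,
              n_marker_genes = as.integer(n_marker_genes),
              n_dist_bins = n_dist_bins, dist_edges = dist_edges,
              peak_cutoff = peak_cutoff, coverage_frac = coverage_frac,
              dist_on_arcsinh = dist_on_arcsinh,
              val_cell_frac = val_cell_frac, val_chroms = val_chroms,
              shift_max = shift_max, seed = as.integer(seed))
  class(cfg) <- "DataConfig"
  validate_data_config(cfg)
  cfg
}

validate_data_config <- function(cfg) {
  stopifnot(cfg$window_len %% cfg$bin == 0,
            cfg$input_len %% cfg$bin == 0,
            cfg$local_atac_len %% cfg$bin == 0)
  if (cfg$window_len >= cfg$input_len)
    stop("chromcast_error: window_len must be < input_len")
  if (cfg$coverage_frac <= 0 || cfg$coverage_frac >= 1)
    stop("chromcast_error: coverage_frac must be in (0, 1)")
  if (is.unsorted(cfg$dist_edges, strictly = TRUE))
    stop("chromcast_error: dist_edges must be strictly increasing")
  if (length(cfg$dist_edges) != cfg$n_dist_bins - 1)
    stop("chromcast_error: need n_dist_bins - 1 distribution edges")
  if (cfg$shift_max %% cfg$bin != 0)
    stop("chromcast_error: shift_max must be a whole-bin multiple")
  invisible(cfg)
}

#' Desk-scale data configuration
#'
#' 4,096 bp DNA input, 2,048 bp prediction window, 128 bp bins; every filter
#' threshold matches the full-scale profile so behaviour differs only in
#' geometry.
#'
#' @param ... Overrides passed to [data_config()].
#' @return A `DataConfig`.
#' @export
toy_data_config <- function(...) {
  args <- list(window_len = 2048, input_len = 4096, local_atac_len = 4352,
               bin = 128, global_bin = 250, tss_window = 3000,
               n_marker_genes = 8, val_chroms = "chr2", shift_max = 384)
  over <- list(...)
  args[names(over)] <- over
  do.call(data_config, args)
}

#' Derived geometry helpers
#' @param cfg A `DataConfig`.
#' @return Number of prediction bins (`n_bins`), the input-to-window margin in
#'   bp (`crop_margin`), or the local-accessibility bin count.
#' @export
n_bins <- function(cfg) cfg$window_len / cfg$bin

#' @rdname n_bins
#' @export
crop_margin <- function(cfg) (cfg$input_len - cfg$window_len) / 2

#' @rdname n_bins
#' @export
n_local_bins <- function(cfg) cfg$local_atac_len / cfg$bin

#' Model configuration
#'
#' Architecture hyper-parameters for the dual-branch model. Embedding widths
#' and head sizes are free choices (the architecture fixes only the branch
#' structure); defaults are sized for desk-scale training.
#'
#' @param data_cfg A `DataConfig`.
#' @param n_marks Number of histone marks predicted (6 at full scale).
#' @param backbone_channels Latent channels C of the DNA backbone.
#' @param backbone_kernels Kernel widths of the backbone stack: base-pair
#'   level conv, then two bin-level convs.
#' @param local_channels,local_kernel,local_stride Local-accessibility
#'   embedding convolution.
#' @param global_pool,global_dim Global-accessibility embedding (average-pool
#'   factor, then dense width).
#' @param hidden_dim Width of the two shared dense layers in the cell-typing
#'   branch.
#' @param comb_channels,comb_kernel Combined-head convolution over bins.
#' @param celltyping_mode `"dense"` (flatten + dense, the default
#'   architecture) or `"conv"` (purely convolutional, translation-equivariant
#'   variant used by the probing module). In `"conv"` mode the combined-head
#'   kernel is forced to 1.
#' @param link Positive link for rate heads: `"exp"` (canonical Poisson
#'   link, default: its gradient `pred - target` does not vanish at low
#'   rates, which matters for sparse peak targets) or `"softplus"`.
#' @param seed Seed for weight initialisation.
#' @return A list of class `ModelConfig`.
#' @export
model_config <- function(data_cfg, n_marks = 3, backbone_channels = 24,
                         backbone_kernels = c(9, 9, 5),
                         local_channels = 8, local_kernel = 9,
                         local_stride = 2, global_pool = 4, global_dim = 16,
                         hidden_dim = 48, comb_channels = 24, comb_kernel = 5,
                         celltyping_mode = c("dense", "conv"),
                         link = c("exp", "softplus"), seed = 1L) {
  celltyping_mode <- match.arg(celltyping_mode)
  link <- match.arg(link)
  if (celltyping_mode == "conv") comb_kernel <- 1
  cfg <- list(data_cfg = data_cfg, n_marks = as.integer(n_marks),
              backbone_channels = backbone_channels,
              backbone_kernels = backbone_kernels,
              local_channels = local_channels, local_kernel = local_kernel,
              local_stride = local_stride, global_pool = global_pool,
              global_dim = global_dim, hidden_dim = hidden_dim,
              comb_channels = comb_channels, comb_kernel = comb_kernel,
              celltyping_mode = celltyping_mode, link = link,
              seed = as.integer(seed))
  if (cfg$n_marks < 1) stop("chromcast_error: n_marks must be >= 1")
  class(cfg) <- "ModelConfig"
  cfg
}

#' Synthetic-data configuration
#'
#' Study conditions for the planted-grammar generator. Defaults give two
#' 65,536 bp chromosomes, 10 cell types and 3 marks: large enough for the
#' toy-geometry model to train end-to-end in minutes while keeping every
#' structural feature of the real data (shared and cell-specific peaks,
#' accessibility correlated with activity, decoy hQTL records).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_cells Number of cell types.
#' @param n_marks Number of histone marks.
#' @param n_marker_genes Number of marker-gene TSSs.
#' @param n_shared_motifs Motifs used by every cell (housekeeping-like).
#' @param motif_len Consensus length in bp.
#' @param sites_per_kb Mean planted motif sites per kilobase.
#' @param peak_halfwidth Gaussian peak sigma in bp on the -log10 p scale.
#' @param peak_amp Maximum peak amplitude (-log10 p).
#' @param atac_amp Accessibility peak amplitude at active sites.
#' @param noise_sd Scale of the non-negative background noise.
#' @param sim_bin Resolution tracks are generated at (25 bp mirrors upstream
#'   peak-calling pipelines; the data pipeline rebins to the model bin).
#' @param n_hqtl Planted causal hQTL variants.
#' @param n_trans_decoys,n_far_decoys Decoy association records for filter
#'   tests.
#' @param hqtl_noise_sd Noise added to planted hQTL effect sizes.
#' @param blacklist_n,blacklist_len Planted blacklist intervals.
#' @param seed Integer seed.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_chrom = 2, chrom_len = 65536, n_cells = 10,
                       n_marks = 3, n_marker_genes = 8, n_shared_motifs = 2,
                       motif_len = 8, sites_per_kb = 0.6,
                       peak_halfwidth = 200, peak_amp = 6, atac_amp = 5,
                       noise_sd = 0.05, sim_bin = 25, n_hqtl = 40,
                       n_trans_decoys = 3, n_far_decoys = 2,
                       hqtl_noise_sd = 0.1, blacklist_n = 2,
                       blacklist_len = 600, seed = 1L) {
  cfg <- list(n_chrom = n_chrom, chrom_len = chrom_len, n_cells = n_cells,
              n_marks = n_marks, n_marker_genes = n_marker_genes,
              n_shared_motifs = n_shared_motifs, motif_len = motif_len,
              sites_per_kb = sites_per_kb, peak_halfwidth = peak_halfwidth,
              peak_amp = peak_amp, atac_amp = atac_amp, noise_sd = noise_sd,
              sim_bin = sim_bin, n_hqtl = n_hqtl,
              n_trans_decoys = n_trans_decoys, n_far_decoys = n_far_decoys,
              hqtl_noise_sd = hqtl_noise_sd, blacklist_n = blacklist_n,
              blacklist_len = blacklist_len, seed = as.integer(seed))
  stopifnot(cfg$n_chrom >= 1, cfg$n_cells >= 1, cfg$n_marks >= 1,
            cfg$motif_len >= 4, cfg$chrom_len >= 8192)
  class(cfg) <- "SimConfig"
  cfg
}

#' Training-state configuration
#'
#' @param stage `"pretrain"` or `"full"`.
#' @param lr Learning rate; defaults to 2e-4 for pre-training and 5e-3 for
#'   the full stage.
#' @param batch_size Items per optimisation step.
#' @param n_steps Optimisation steps.
#' @param eval_every Steps between validation evaluations (full stage).
#' @param patience Validation evaluations without improvement before early
#'   stopping.
#' @param seed Integer seed for batch sampling.
#' @return A list of class `TrainState`.
#' @export
train_state <- function(stage = c("pretrain", "full"), lr = NULL,
                        batch_size = 8, n_steps = 200, eval_every = 25,
                        patience = 3, seed = 1L) {
  stage <- match.arg(stage)
  if (is.null(lr)) lr <- if (stage == "pretrain") 2e-4 else 5e-3
  if (lr <= 0) stop("chromcast_error: learning rate must be > 0")
  structure(list(stage = stage, lr = lr, batch_size = batch_size,
                 n_steps = n_steps, eval_every = eval_every,
                 patience = patience, seed = as.integer(seed), step = 0L),
            class = "TrainState")
}

#' Full-scale ("paper profile") constants
#'
#' The published full-scale configuration: every constant is asserted by
#' [run_config()] when `profile = "paper"` so that an accidental change fails
#' loudly.
#' @return Named list of constants.
#' @export
paper_profile_constants <- function() {
  list(input_len = 196608, window_len = 114688, local_atac_len = 199936,
       bin = 128, global_bin = 250, tss_window = 3000, n_marks = 6,
       n_cells = 104, n_marker_genes = 1216, n_local_bins = 1562,
       n_global = 14592, n_bins = 896, lr_pretrain = 2e-4, lr_full = 5e-3,
       batch_size = 128, pretrain_steps = 1000, full_steps = 6940,
       peak_cutoff = 2.0, coverage_frac = 0.125)
}

#' Merged run configuration for the command-line pipeline
#'
#' @param profile `"toy"` (desk scale, default) or `"paper"` (full-scale
#'   geometry; validated against [paper_profile_constants()]).
#' @param overrides Named list of overrides applied to the sub-configs
#'   (`data`, `model`, `sim`, `train`); e.g.
#'   `list(sim = list(n_cells = 6))`.
#' @param seed Global seed.
#' @return A list of class `RunConfig` with elements `data`, `model`, `sim`,
#'   `pretrain`, `train`, `profile`, `seed`.
#' @export
run_config <- function(profile = c("toy", "paper"), overrides = list(),
                       seed = 1L) {
  profile <- match.arg(profile)
  seed <- as.integer(seed)
  dargs <- if (profile == "toy") list() else
    list(window_len = 114688, input_len = 196608, local_atac_len = 199936,
         bin = 128, global_bin = 250, tss_window = 3000, val_chroms = "chr2")
  dargs$seed <- seed
  dargs[names(overrides$data)] <- overrides$data
  dcfg <- if (profile == "toy") do.call(toy_data_config, dargs) else
    do.call(data_config, dargs)
  margs <- list(data_cfg = dcfg, seed = seed,
                n_marks = if (profile == "paper") 6L else 3L)
  margs[names(overrides$model)] <- overrides$model
  mcfg <- do.call(model_config, margs)
  sargs <- list(seed = seed, n_marks = mcfg$n_marks)
  if (profile == "paper") {
    sargs$n_cells <- 104L
    sargs$n_marker_genes <- 1216L
    sargs$chrom_len <- 2^21
  }
  sargs[names(overrides$sim)] <- overrides$sim
  scfg <- do.call(sim_config, sargs)
  pt_args <- list(stage = "pretrain", seed = seed)
  ft_args <- list(stage = "full", seed = seed)
  if (profile == "paper") {
    pt_args <- c(pt_args, list(batch_size = 128, n_steps = 1000))
    ft_args <- c(ft_args, list(batch_size = 128, n_steps = 6940))
  } else {
    # desk-scale schedule: the tiny model trains in well under a minute, and
    # the head layers need the extra steps (at a slightly larger pre-training
    # rate) to converge past their base-rate initialisation
    pt_args <- c(pt_args, list(lr = 5e-4, n_steps = 2000))
    ft_args <- c(ft_args, list(n_steps = 1500, eval_every = 50,
                               patience = 5))
  }
  pt_args[names(overrides$pretrain)] <- overrides$pretrain
  ft_args[names(overrides$train)] <- overrides$train
  cfg <- list(profile = profile, seed = seed, data = dcfg, model = mcfg,
              sim = scfg, pretrain = do.call(train_state, pt_args),
              train = do.call(train_state, ft_args))
  class(cfg) <- "RunConfig"
  if (profile == "paper") validate_paper_profile(cfg)
  cfg
}

#' Assert every full-scale constant of the paper profile
#' @param cfg A `RunConfig`.
#' @return `cfg` invisibly; errors loudly on any deviation.
#' @export
validate_paper_profile <- function(cfg) {
  k <- paper_profile_constants()
  checks <- list(
    input_len = cfg$data$input_len, window_len = cfg$data$window_len,
    local_atac_len = cfg$data$local_atac_len, bin = cfg$data$bin,
    global_bin = cfg$data$global_bin, tss_window = cfg$data$tss_window,
    n_marks = cfg$model$n_marks, n_cells = cfg$sim$n_cells,
    n_marker_genes = cfg$sim$n_marker_genes,
    n_local_bins = n_local_bins(cfg$data),
    n_bins = n_bins(cfg$data),
    lr_pretrain = cfg$pretrain$lr, lr_full = cfg$train$lr,
    batch_size = cfg$train$batch_size,
    pretrain_steps = cfg$pretrain$n_steps, full_steps = cfg$train$n_steps,
    peak_cutoff = cfg$data$peak_cutoff, coverage_frac = cfg$data$coverage_frac)
  for (nm in names(checks)) {
    if (!isTRUE(all.equal(unname(checks[[nm]]), k[[nm]])))
      stop("chromcast_error: paper profile constant '", nm,
           "' deviates: ", checks[[nm]], " != ", k[[nm]])
  }
  ng <- k$n_marker_genes * (k$tss_window %/% k$global_bin)
  if (ng != k$n_global)
    stop("chromcast_error: global vector length mismatch")
  invisible(cfg)
}
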