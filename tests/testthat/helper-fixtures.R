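# Shared fixtures, all built in code. Heavyweight objects (the simulated
# study and trained models) are memoised per session so several test files
# can reuse them.

.cc_memo <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .cc_memo, inherits = FALSE))
    assign(key, builder(), envir = .cc_memo)
  get(key, envir = .cc_memo)
}

# A very small geometry for fast model/gradient tests: 512 bp input, 256 bp
# prediction window, 32 bp bins (8 output bins).
tiny_data_cfg <- function(...) {
  data_config(window_len = 256, input_len = 512, local_atac_len = 576,
              bin = 32, global_bin = 250, tss_window = 3000,
              n_marker_genes = 2, shift_max = 64, val_chroms = "chr2", ...)
}

tiny_model_cfg <- function(dcfg = tiny_data_cfg(), ...) {
  model_config(dcfg, n_marks = 2, backbone_channels = 8, local_channels = 4,
               global_dim = 6, hidden_dim = 12, comb_channels = 6, ...)
}

random_genome <- function(chroms = c("chr1", "chr2"), len = 4096,
                          seed = 42) {
  set.seed(seed)
  g <- genome_index(chroms, rep(len, length(chroms)))
  seqs <- lapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(seqs) <- chroms
  list(genome = g, sequences = seqs)
}

random_track <- function(genome, bin = 32, seed = 1, assay = "mark1",
                         cell = "cellA", scale = "neglog10p") {
  set.seed(seed)
  vals <- lapply(genome$names, function(ch)
    abs(stats::rnorm(ceiling(genome$lengths[[ch]] / bin), 1, 1)))
  names(vals) <- genome$names
  binned_track(genome, bin, vals, assay = assay, cell = cell, scale = scale)
}

# The desk-scale study conditions used across the suite (one generator
# seed; the acceptance file builds its own three seeds).
study_fixture <- function(seed = 1) {
  memo(paste0("study_", seed), function() {
    scfg <- sim_config(seed = seed)
    sim <- simulate_genome(scfg)
    tracks <- simulate_tracks(sim, scfg)
    dcfg <- toy_data_config(seed = seed)
    mg <- simulate_marker_genes(sim, tracks, scfg, dcfg)
    ds <- build_dataset(sim, tracks, mg, dcfg)
    list(scfg = scfg, sim = sim, tracks = tracks, dcfg = dcfg, mg = mg,
         ds = ds)
  })
}

# An untrained toy model over the study fixture (motif-seeded backbone).
study_model <- function(seed = 1) {
  memo(paste0("model_", seed), function() {
    fx <- study_fixture(seed)
    mcfg <- model_config(fx$dcfg, n_marks = fx$scfg$n_marks,
                         backbone_channels = 28, seed = seed)
    bb <- make_toy_backbone(mcfg, seed = seed,
                            motifs = fx$sim$grammar$motifs)
    build_model(mcfg, backbone = bb, seed = seed)
  })
}

# Fully trained toy model (pretrain + full stage) under the default toy
# schedule; memoised because both acceptance criteria reuse it.
trained_study <- function(seed = 1) {
  memo(paste0("trained_", seed), function() {
    fx <- study_fixture(seed)
    model <- study_model(seed)
    cache <- cache_latents(model$backbone, fx$ds)
    rc <- run_config("toy", seed = seed)
    model <- pretrain(model, fx$ds, rc$pretrain, cache = cache)
    model <- train_full(model, fx$ds, rc$train, cache = cache)
    list(model = model, cache = cache)
  })
}

numeric_grad <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- x[i] + eps
  xm <- x; xm[i] <- x[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}
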