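test_that("DNA permutation effects vanish beyond the receptive field", {
  fx <- study_fixture()
  model <- study_model()
  item <- fx$ds$items$train[1, ]
  feats <- item_features(fx$ds, item)
  pr <- dna_permutation_scan(model, feats, n_positions = 16, reps = 2,
                             seed = 5)
  R <- model$backbone$receptive_field
  half_span <- 256                                 # centre span half-width
  halo <- (model$cfg$comb_kernel - 1) / 2 * model$cfg$data_cfg$bin
  far <- abs(pr$distance) > R / 2 + half_span + halo + model$cfg$data_cfg$bin
  expect_true(any(far))
  expect_true(all(pr$effect[far] == 0))            # exact zero outside R
  near <- which.min(abs(pr$distance))
  expect_gte(pr$effect[near], max(pr$effect[far]))
  pr2 <- dna_permutation_scan(model, feats, n_positions = 16, reps = 2,
                              seed = 5)
  expect_identical(pr, pr2)                        # seeded determinism
  expect_error(dna_permutation_scan(model, feats, n_positions = 1e6),
               "positions")
})

test_that("accessibility permutation effects match a two-forward oracle", {
  fx <- study_fixture()
  model <- study_model()
  item <- fx$ds$items$train[1, ]
  feats <- item_features(fx$ds, item)
  oh <- item_onehot(fx$ds, item)
  pr <- atac_permutation_scan(model, oh, feats,
                              distances = c(-1280, 0, 1280))
  cfg <- model$cfg$data_cfg
  nl <- n_local_bins(cfg)
  base <- combined_forward(model, oh, feats)
  for (i in seq_along(pr$distance)) {
    ld <- feats$local_delta
    centre_bin <- nl / 2 + pr$distance[i] / cfg$bin
    b0 <- round(centre_bin - (640 / cfg$bin) / 2)
    ld[(b0 + 1):(b0 + 5)] <- 0
    alt <- combined_forward(model, oh, celltype_features(ld, feats$global))
    ctr <- ((n_bins(cfg) - 4) / 2 + 1):((n_bins(cfg) - 4) / 2 + 4)
    expect_equal(pr$effect[i], mean(abs(alt[ctr, ] - base[ctr, ])),
                 tolerance = 1e-12)
  }

  # replacing a block whose delta is already zero changes nothing
  fz <- celltype_features(rep(0, nl), feats$global)
  przero <- atac_permutation_scan(model, oh, fz, distances = c(-640, 0, 640))
  expect_true(all(przero$effect == 0))

  # ablating the cell-typing branch removes all sensitivity
  m0 <- model
  m0$params$ct <- chromcast:::param_zero(m0$params$ct)
  pra <- atac_permutation_scan(model = m0, oh, feats,
                               distances = c(-1280, 0, 1280))
  expect_true(all(pra$effect == 0))

  expect_error(atac_permutation_scan(model, oh, feats, block = 100),
               "whole-bin")
})

test_that("purely convolutional models predict identically off-centre", {
  fx <- study_fixture()
  mcfg <- model_config(fx$dcfg, n_marks = 3, backbone_channels = 28,
                       celltyping_mode = "conv", seed = 2)
  bb <- make_toy_backbone(mcfg, seed = 2, motifs = fx$sim$grammar$motifs)
  model <- build_model(mcfg, backbone = bb, seed = 2)
  safe <- fx$ds$regions$window_start > 4096 &
    fx$ds$regions$window_start < fx$scfg$chrom_len - 4096 - 2048
  regions <- fx$ds$regions[safe, ][1:2, ]
  res <- offcentre_consistency(model, fx$ds, regions, fx$ds$cells[1])
  expect_true(all(res$correlation > 1 - 1e-5))
  # both off-centre directions agree for an equivariant model
  up <- res$correlation[res$direction == "upstream"]
  down <- res$correlation[res$direction == "downstream"]
  expect_equal(up, down, tolerance = 1e-5)

  # with a planted variant inside the shared span the correlation holds
  resv <- offcentre_consistency(model, fx$ds, regions, fx$ds$cells[1],
                                add_variant = TRUE, seed = 9)
  expect_true(all(resv$correlation > 1 - 1e-5))
})

test_that("constant predictions yield an undefined off-centre correlation", {
  fx <- study_fixture()
  model <- study_model()
  m0 <- model
  m0$params <- chromcast:::param_zero(m0$params)    # constant output
  safe <- fx$ds$regions$window_start > 4096 &
    fx$ds$regions$window_start < fx$scfg$chrom_len - 4096 - 2048
  res <- offcentre_consistency(m0, fx$ds, fx$ds$regions[safe, ][1, ],
                               fx$ds$cells[1])
  expect_true(all(is.na(res$correlation)))
})

test_that("global-input attribution matches central finite differences", {
  fx <- study_fixture()
  model <- study_model()
  item <- fx$ds$items$train[1, ]
  feats <- item_features(fx$ds, item)
  lat <- backbone_forward(model$backbone, item_onehot(fx$ds, item))
  fw <- model_forward(model, lat, feats, keep_cache = TRUE)
  nb <- n_bins(fx$dcfg)
  pbins <- 3:6
  up <- matrix(0, nb, model$cfg$n_marks)
  up[pbins, 1] <- 1 / length(pbins)
  bk <- model_backward(model, fw, up)
  mean_pred <- function(g) {
    f2 <- celltype_features(feats$local_delta, g)
    mean(model_forward(model, lat, f2)$pred[pbins, 1])
  }
  for (i in c(1, 10, 40, 96)) {
    expect_equal(bk$dglobal[i], numeric_grad(mean_pred, feats$global, i),
                 tolerance = 1e-4)
  }
})

test_that("attribution report selects the top decile and severed models score zero", {
  ts <- trained_study(1)
  fx <- study_fixture()
  fasta <- withr::local_tempfile(fileext = ".fa")
  rep <- global_attribution(ts$model, fx$ds, fx$ds$val_cells[1],
                            fasta = fasta)
  expect_gt(nrow(rep$peaks), 0)
  expect_equal(nrow(rep$selected),
               max(1, floor(0.1 * nrow(rep$peaks))))
  expect_true(all(rep$peaks$mean_signal > 2))
  expect_true(all(abs(rep$selected$attribution) >=
                    sort(abs(rep$peaks$attribution), decreasing = TRUE)[
                      nrow(rep$selected)]))
  seqs <- Biostrings::readDNAStringSet(fasta)
  expect_equal(length(seqs), nrow(rep$selected))
  expect_true(all(Biostrings::width(seqs) == 1024))

  # severing the global pathway zeroes every attribution
  m0 <- ts$model
  m0$params$ct$glob$W[] <- 0
  m0$params$ct$glob$b[] <- 0
  rep0 <- global_attribution(m0, fx$ds, fx$ds$val_cells[1])
  if (nrow(rep0$peaks) > 0)
    expect_true(all(rep0$peaks$attribution == 0))
})
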