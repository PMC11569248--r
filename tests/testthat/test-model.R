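test_that("toy backbone is deterministic, frozen and respects its receptive field", {
  mcfg <- tiny_model_cfg()
  bb <- make_toy_backbone(mcfg, seed = 4, motifs = c("ACGTGATT", "TTGCACAA"))
  bb2 <- make_toy_backbone(mcfg, seed = 4, motifs = c("ACGTGATT", "TTGCACAA"))
  expect_identical(bb$hash, bb2$hash)
  set.seed(10)
  oh <- one_hot(paste(sample(c("A", "C", "G", "T"), 512, replace = TRUE),
                      collapse = ""))
  expect_identical(backbone_forward(bb, oh), backbone_forward(bb, oh))

  # a flip farther than R/2 from a latent bin's centre leaves it unchanged
  lat0 <- backbone_forward(bb, oh)
  b <- 4                                          # absolute bin 4 + margin
  total_bins <- 512 / 32
  margin <- (total_bins - bb$n_bins) / 2
  centre_bp <- (b - 1 + margin) * 32 + 16
  far <- centre_bp + bb$receptive_field / 2 + 40
  oh2 <- oh
  cur <- which(oh[far, ] == 1)
  oh2[far, ] <- 0
  oh2[far, (cur %% 4) + 1] <- 1                   # a different base
  expect_identical(backbone_forward(bb, oh2)[b, ], lat0[b, ])
})

test_that("declared receptive field equals exhaustive single-base flip measurement", {
  mcfg <- tiny_model_cfg()
  bb <- make_toy_backbone(mcfg, seed = 4, motifs = c("ACGTGATT"))
  set.seed(11)
  oh <- one_hot(paste(sample(c("A", "C", "G", "T"), 512, replace = TRUE),
                      collapse = ""))
  b <- 4
  lat0 <- backbone_forward(bb, oh)[b, ]
  hit <- logical(512)
  for (p in 1:512) {
    oh2 <- oh
    cur <- which(oh[p, ] == 1)
    oh2[p, ] <- 0
    oh2[p, (cur %% 4) + 1] <- 1
    hit[p] <- any(backbone_forward(bb, oh2)[b, ] != lat0)
  }
  span <- range(which(hit))
  expect_equal(diff(span) + 1, bb$receptive_field)
})

test_that("dna branch emits positive rates and per-bin simplex distributions", {
  mcfg <- tiny_model_cfg()
  model <- build_model(mcfg, seed = 6)
  set.seed(12)
  lat <- matrix(rnorm(8 * 8), 8, 8)
  out <- dna_branch(model, lat)
  expect_equal(dim(out$avg), c(8, 2))
  expect_true(all(out$avg > 0))
  expect_equal(dim(out$dist), c(8, 2, 10))
  expect_equal(apply(out$dist, c(1, 2), sum), matrix(1, 8, 2),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(dna_branch(model, lat[, 1:3]), "shape")
})

test_that("celltyping branch maps features to an (n_bins x n_marks) delta", {
  mcfg <- tiny_model_cfg()
  model <- build_model(mcfg, seed = 7)
  f <- celltype_features(rnorm(18), rnorm(24))
  d <- celltyping_branch(model, f)
  expect_equal(dim(d), c(8, 2))
  z <- celltyping_branch(model, celltype_features(rep(0, 18), rep(0, 24)))
  expect_true(all(is.finite(z)))
  expect_error(celltyping_branch(model, celltype_features(rnorm(5),
                                                          rnorm(24))),
               "local feature length")
})

test_that("full-scale geometry checks: 896 x 6 output, 1562/14592 features", {
  k <- paper_profile_constants()
  dcfg <- data_config()
  expect_equal(n_bins(dcfg), 896)
  expect_equal(n_local_bins(dcfg), 1562)
  mcfg <- model_config(dcfg, n_marks = 6, backbone_channels = 8,
                       local_channels = 2, global_dim = 4, hidden_dim = 8,
                       comb_channels = 8)
  model <- build_model(mcfg, seed = 2)
  f <- celltype_features(rep(0.1, 1562), rep(0.2, 14592))
  d <- celltyping_branch(model, f)
  expect_equal(dim(d), c(896, 6))
  set.seed(30)
  oh <- one_hot(paste(sample(c("A", "C", "G", "T"), 196608, replace = TRUE),
                      collapse = ""))
  pred <- combined_forward(model, oh, f, output_scale = "neglog10p")
  expect_equal(dim(pred), c(896, 6))
  expect_true(all(pred >= 0))
})

test_that("combined forward is deterministic and non-negative on the raw scale", {
  mcfg <- tiny_model_cfg()
  model <- build_model(mcfg, seed = 8)
  set.seed(13)
  oh <- one_hot(paste(sample(c("A", "C", "G", "T"), 512, replace = TRUE),
                      collapse = ""))
  f <- celltype_features(rnorm(18), rnorm(24))
  p1 <- combined_forward(model, oh, f, output_scale = "neglog10p")
  p2 <- combined_forward(model, oh, f, output_scale = "neglog10p")
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
  pa <- combined_forward(model, oh, f, output_scale = "arcsinh")
  expect_equal(sinh(pa), p1, ignore_attr = TRUE)
})

test_that("analytic gradients match finite differences in both branch modes", {
  for (mode in c("dense", "conv")) {
    mcfg <- tiny_model_cfg(celltyping_mode = mode)
    model <- build_model(mcfg, seed = 9)
    set.seed(14)
    lat <- matrix(rnorm(8 * 8), 8, 8)
    f <- celltype_features(rnorm(18), rnorm(24))
    tgt <- matrix(abs(rnorm(16)), 8, 2)
    fw <- model_forward(model, lat, f, keep_cache = TRUE)
    bk <- model_backward(model, fw, poisson_nll_grad(fw$pred, tgt))
    loss_of <- function(m) poisson_nll(model_forward(m, lat, f)$pred, tgt)
    paths <- list(
      c("dna", "avg", "W"), c("dna", "dist", "W"),
      c("comb", "conv", "W"), c("ct", "conv_l", "W"),
      c("ct", "glob", "W"))
    for (pth in paths) {
      v <- model$params[[pth[1]]][[pth[2]]][[pth[3]]]
      g <- bk$grads[[pth[1]]][[pth[2]]][[pth[3]]]
      i <- ((seed_i <- sum(utf8ToInt(paste(pth, collapse = "")))) %%
              length(v)) + 1
      num <- numeric_grad(function(x) {
        m2 <- model
        m2$params[[pth[1]]][[pth[2]]][[pth[3]]] <- x
        loss_of(m2)
      }, v, i)
      expect_equal(g[i], num, tolerance = 1e-5,
                   label = paste(mode, paste(pth, collapse = "$")))
    }
    # input gradient wrt the global accessibility vector
    i <- 3
    num <- numeric_grad(function(x) {
      poisson_nll(model_forward(model, lat,
                                celltype_features(f$local_delta, x))$pred,
                  tgt)
    }, f$global, i)
    expect_equal(bk$dglobal[i], num, tolerance = 1e-5)
  }
})

test_that("paper profile validation pins every full-scale constant", {
  rc <- run_config("paper", seed = 1)
  expect_identical(rc$data$input_len, 196608)
  expect_identical(rc$data$window_len, 114688)
  expect_identical(rc$data$local_atac_len, 199936)
  expect_identical(rc$train$lr, 5e-3)
  expect_identical(rc$pretrain$lr, 2e-4)
  expect_identical(rc$train$batch_size, 128)
  # changing any constant fails loudly
  expect_error(run_config("paper", overrides = list(data = list(bin = 64))),
               "paper profile constant")
  expect_error(run_config("paper",
                          overrides = list(train = list(lr = 1e-3))),
               "paper profile constant")
})
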