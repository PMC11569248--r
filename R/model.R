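#' Assemble the dual-branch model
#'
#' Builds the trainable parts around a frozen DNA backbone: the DNA-branch
#' average and distribution heads, the cell-typing branch (local + global
#' accessibility embeddings) and the combined head. Backbone weights live
#' outside the trainable parameter tree, so optimisers can never touch them.
#'
#' @param cfg A `ModelConfig`.
#' @param backbone A `BackboneContract`; created via [make_toy_backbone()]
#'   when `NULL`.
#' @param seed Seed for weight initialisation.
#' @return An object of class `cc_model`.
#' @export
build_model <- function(cfg, backbone = NULL, seed = cfg$seed) {
  if (is.null(backbone)) backbone <- make_toy_backbone(cfg, seed = seed)
  dcfg <- cfg$data_cfg
  M <- cfg$n_marks; K <- cfg$n_dist_bins
  if (is.null(K)) K <- dcfg$n_dist_bins
  C <- backbone$channels
  nb <- n_bins(dcfg)
  nl <- n_local_bins(dcfg)
  ng <- n_global_len(dcfg)
  if (ng %% cfg$global_pool != 0)
    stop("chromcast_error: global_pool does not divide global vector length")
  params <- nn_seeded(seed + 1L, {
    # head weights start small so initial distributions sit near uniform
    # whatever the latent scale; the rate-head bias starts at the inverse
    # link of a small base rate (standard base-rate initialisation for
    # sparse targets, so sparsely-active channels are not pushed negative
    # while the bias is still travelling)
    dna <- list(avg = init_dense(C, M, sd = 0.01),
                dist = init_dense(C, M * K, sd = 0.01))
    dna$avg$b[] <- if (cfg$link == "softplus") log(expm1(0.05)) else log(0.05)
    ct <- if (cfg$celltyping_mode == "dense") {
      tl <- length(seq(1L, nl, by = cfg$local_stride))
      flat <- tl * cfg$local_channels
      list(conv_l = init_conv1d(cfg$local_kernel, 1L, cfg$local_channels),
           glob = init_dense(ng %/% cfg$global_pool, cfg$global_dim),
           fc1 = init_dense(flat + cfg$global_dim, cfg$hidden_dim),
           fc2 = init_dense(cfg$hidden_dim, cfg$hidden_dim),
           heads = lapply(seq_len(M), function(m)
             init_dense(cfg$hidden_dim, nb)))
    } else {
      if ((nl - nb) %% 2 != 0)
        stop("chromcast_error: local window not centred on prediction window")
      list(conv_l = init_conv1d(cfg$local_kernel, 1L, cfg$local_channels),
           proj = init_dense(cfg$local_channels, M),
           glob = init_dense(ng %/% cfg$global_pool, M))
    }
    Fdim <- M * (2 + K)
    # per-mark skip weights start at 1: the combined logit begins as
    # avg + delta (the natural decomposition of the cell signal) plus the
    # distribution-implied mean signal, and the convolutional block learns
    # corrections on top
    comb <- list(conv = init_conv1d(cfg$comb_kernel, Fdim, cfg$comb_channels),
                 heads = lapply(seq_len(M), function(m)
                   init_dense(cfg$comb_channels, 1L, sd = 0.05)),
                 skip = list(wa = rep(1, M), wd = rep(1, M)))
    list(dna = dna, ct = ct, comb = comb)
  })
  edges <- dcfg$dist_edges
  step <- if (length(edges) > 1) edges[2] - edges[1] else edges[1]
  mids <- c(edges[1] / 2, (edges[-length(edges)] + edges[-1]) / 2,
            edges[length(edges)] + step / 2)
  structure(list(cfg = cfg, backbone = backbone, params = params,
                 n_dist_bins = K, dist_mids = mids, assembled = TRUE),
            class = "cc_model")
}

#' @export
print.cc_model <- function(x, ...) {
  cat(sprintf(
    "chromcast model: %d marks, %d output bins, %s cell-typing branch\n",
    x$cfg$n_marks, n_bins(x$cfg$data_cfg), x$cfg$celltyping_mode))
  cat(sprintf("  trainable parameters: %d (+ frozen backbone: %d)\n",
              param_count(x$params), param_count(x$backbone$params)))
  invisible(x)
}

n_global_len <- function(dcfg, n_marker_genes = NULL) {
  per_gene <- dcfg$tss_window %/% dcfg$global_bin
  if (is.null(n_marker_genes))
    n_marker_genes <- dcfg$n_marker_genes
  if (is.null(n_marker_genes)) stop("chromcast_error: n_marker_genes unset")
  n_marker_genes * per_gene
}

#' Count of trainable parameters (excludes the frozen backbone)
#' @param model A `cc_model`.
#' @return Integer parameter count.
#' @export
trainable_param_count <- function(model) param_count(model$params)

link_forward <- function(z, link) {
  if (link == "softplus") softplus(z) else exp(pmin(z, 30))
}
link_grad <- function(z, link) {
  if (link == "softplus") softplus_grad(z) else exp(pmin(z, 30))
}

#' Cell-type feature bundle
#'
#' @param local_delta Numeric vector of length `local_atac_len / bin`
#'   (cell accessibility minus average accessibility, arcsinh scale).
#' @param global Numeric vector of length
#'   `n_marker_genes * (tss_window / global_bin)`.
#' @return A list of class `CelltypeFeatures`.
#' @export
celltype_features <- function(local_delta, global) {
  if (any(!is.finite(local_delta)) || any(!is.finite(global)))
    stop("chromcast_error: non-finite cell-type features")
  structure(list(local_delta = as.numeric(local_delta),
                 global = as.numeric(global)),
            class = "CelltypeFeatures")
}

check_features <- function(model, features) {
  dcfg <- model$cfg$data_cfg
  if (length(features$local_delta) != n_local_bins(dcfg))
    stop("chromcast_error: local feature length ",
         length(features$local_delta), " != ", n_local_bins(dcfg))
  ng <- nrow(model$params$ct$glob$W) * model$cfg$global_pool
  if (length(features$global) != ng)
    stop("chromcast_error: global feature length ",
         length(features$global), " != ", ng)
  invisible(TRUE)
}

# ---- DNA branch ----------------------------------------------------------

dna_heads_forward <- function(model, latent, keep_cache = FALSE) {
  M <- model$cfg$n_marks; K <- model$n_dist_bins
  if (ncol(latent) != nrow(model$params$dna$avg$W))
    stop("chromcast_error: latent shape mismatch")
  da <- dense_forward(latent, model$params$dna$avg)
  avg <- link_forward(da$y, model$cfg$link)
  dd <- dense_forward(latent, model$params$dna$dist)
  probs <- dd$y
  for (m in seq_len(M)) {
    blk <- ((m - 1) * K + 1):(m * K)
    probs[, blk] <- softmax_rows(dd$y[, blk, drop = FALSE])
  }
  out <- list(avg = avg, dist_mat = probs)
  if (keep_cache) out$cache <- list(da = da, dd = dd, probs = probs)
  out
}

# davg: gradient wrt the positive-link output; ddist: gradient wrt the
# probabilities. Returns parameter grads and the latent gradient.
dna_heads_backward <- function(model, latent, cache, davg, ddist) {
  M <- model$cfg$n_marks; K <- model$n_dist_bins
  dpre_a <- davg * link_grad(cache$da$y, model$cfg$link)
  ga <- dense_backward(cache$da, model$params$dna$avg, dpre_a)
  dlogits <- ddist
  for (m in seq_len(M)) {
    blk <- ((m - 1) * K + 1):(m * K)
    dlogits[, blk] <- softmax_backward(cache$probs[, blk, drop = FALSE],
                                       ddist[, blk, drop = FALSE])
  }
  gd <- dense_backward(cache$dd, model$params$dna$dist, dlogits)
  list(grads = list(avg = list(W = ga$dW, b = ga$db),
                    dist = list(W = gd$dW, b = gd$db)),
       dlatent = ga$dx + gd$dx)
}

#' DNA-branch forward pass
#'
#' Maps a backbone latent to the average-signal prediction (positive link,
#' suitable for a Poisson likelihood) and the per-bin, per-mark K-simplex
#' distribution prediction.
#'
#' @param model A `cc_model`.
#' @param latent Backbone latent (T x C), e.g. from [backbone_forward()].
#' @return List with `avg` (T x n_marks, > 0, arcsinh scale) and `dist`
#'   (T x n_marks x K array of simplex vectors).
#' @export
dna_branch <- function(model, latent) {
  if (nrow(latent) != n_bins(model$cfg$data_cfg) ||
      ncol(latent) != model$backbone$channels)
    stop("chromcast_error: latent shape mismatch")
  fw <- dna_heads_forward(model, latent)
  M <- model$cfg$n_marks; K <- model$n_dist_bins
  dist <- array(0, dim = c(nrow(latent), M, K))
  for (m in seq_len(M))
    dist[, m, ] <- fw$dist_mat[, ((m - 1) * K + 1):(m * K)]
  list(avg = fw$avg, dist = dist)
}

# ---- cell-typing branch --------------------------------------------------

ct_forward <- function(model, features, keep_cache = FALSE) {
  check_features(model, features)
  cfg <- model$cfg
  ct <- model$params$ct
  M <- cfg$n_marks
  nb <- n_bins(cfg$data_cfg)
  x_l <- matrix(features$local_delta, ncol = 1)
  gp <- avgpool_forward(matrix(features$global, ncol = 1), cfg$global_pool)
  if (cfg$celltyping_mode == "dense") {
    c1 <- conv1d_forward(x_l, ct$conv_l, stride = cfg$local_stride)
    r1 <- relu_forward(c1$y)
    u_l <- as.numeric(r1$y)
    gd <- dense_forward(matrix(gp$y, nrow = 1), ct$glob)
    rg <- relu_forward(gd$y)
    u <- matrix(c(u_l, as.numeric(rg$y)), nrow = 1)
    f1 <- dense_forward(u, ct$fc1); rf1 <- relu_forward(f1$y)
    f2 <- dense_forward(rf1$y, ct$fc2); rf2 <- relu_forward(f2$y)
    delta <- matrix(0, nb, M)
    hc <- vector("list", M)
    for (m in seq_len(M)) {
      hc[[m]] <- dense_forward(rf2$y, ct$heads[[m]])
      delta[, m] <- as.numeric(hc[[m]]$y)
    }
    cache <- if (keep_cache)
      list(c1 = c1, r1 = r1, gp = gp, gd = gd, rg = rg, f1 = f1, rf1 = rf1,
           f2 = f2, rf2 = rf2, hc = hc, dims_r1 = dim(r1$y)) else NULL
  } else {
    c1 <- conv1d_forward(x_l, ct$conv_l, stride = 1L)
    r1 <- relu_forward(c1$y)
    pj <- dense_forward(r1$y, ct$proj)
    margin <- (n_local_bins(cfg$data_cfg) - nb) %/% 2
    rows <- (margin + 1):(margin + nb)
    gd <- dense_forward(matrix(gp$y, nrow = 1), ct$glob)
    delta <- pj$y[rows, , drop = FALSE] +
      matrix(rep(as.numeric(gd$y), each = nb), nb, M)
    cache <- if (keep_cache)
      list(c1 = c1, r1 = r1, gp = gp, pj = pj, gd = gd, rows = rows) else NULL
  }
  list(delta = delta, cache = cache)
}

ct_backward <- function(model, cache, ddelta) {
  cfg <- model$cfg
  ct <- model$params$ct
  M <- cfg$n_marks
  nb <- n_bins(cfg$data_cfg)
  if (cfg$celltyping_mode == "dense") {
    drf2 <- matrix(0, 1, cfg$hidden_dim)
    ghead <- vector("list", M)
    for (m in seq_len(M)) {
      g <- dense_backward(cache$hc[[m]], ct$heads[[m]],
                          matrix(ddelta[, m], nrow = 1))
      ghead[[m]] <- list(W = g$dW, b = g$db)
      drf2 <- drf2 + g$dx
    }
    df2 <- relu_backward(cache$rf2, drf2)
    g2 <- dense_backward(cache$f2, ct$fc2, df2)
    df1 <- relu_backward(cache$rf1, g2$dx)
    g1 <- dense_backward(cache$f1, ct$fc1, df1)
    du <- g1$dx
    flat <- prod(cache$dims_r1)
    du_l <- matrix(du[1, seq_len(flat)], cache$dims_r1[1], cache$dims_r1[2])
    du_g <- matrix(du[1, (flat + 1):ncol(du)], nrow = 1)
    dc1 <- relu_backward(cache$r1, du_l)
    gl <- conv1d_backward(cache$c1, ct$conv_l, dc1)
    drg <- relu_backward(cache$rg, du_g)
    gg <- dense_backward(cache$gd, ct$glob, drg)
    dglobal <- avgpool_backward(cache$gp, matrix(as.numeric(gg$dx), ncol = 1))
    list(grads = list(conv_l = list(W = gl$dW, b = gl$db),
                      glob = list(W = gg$dW, b = gg$db),
                      fc1 = list(W = g1$dW, b = g1$db),
                      fc2 = list(W = g2$dW, b = g2$db),
                      heads = ghead),
         dlocal = as.numeric(gl$dx), dglobal = as.numeric(dglobal))
  } else {
    dgb <- matrix(colSums(ddelta), nrow = 1)
    gg <- dense_backward(cache$gd, ct$glob, dgb)
    dpj <- matrix(0, nrow(cache$pj$y), M)
    dpj[cache$rows, ] <- ddelta
    gp_ <- dense_backward(cache$pj, ct$proj, dpj)
    dc1 <- relu_backward(cache$r1, gp_$dx)
    gl <- conv1d_backward(cache$c1, ct$conv_l, dc1)
    dglobal <- avgpool_backward(cache$gp, matrix(as.numeric(gg$dx), ncol = 1))
    list(grads = list(conv_l = list(W = gl$dW, b = gl$db),
                      proj = list(W = gp_$dW, b = gp_$db),
                      glob = list(W = gg$dW, b = gg$db)),
         dlocal = as.numeric(gl$dx), dglobal = as.numeric(dglobal))
  }
}

#' Cell-typing branch forward pass
#'
#' Embeds the local accessibility delta and the global accessibility vector
#' at their own resolutions and predicts the per-bin, per-mark deviation from
#' the cross-cell average signal (unbounded, arcsinh scale).
#'
#' @param model A `cc_model`.
#' @param features A `CelltypeFeatures` object.
#' @return Matrix (n_bins x n_marks) of predicted deltas.
#' @export
celltyping_branch <- function(model, features) {
  ct_forward(model, features)$delta
}

# ---- combined model ------------------------------------------------------

model_forward <- function(model, latent, features, keep_cache = FALSE) {
  M <- model$cfg$n_marks; K <- model$n_dist_bins
  dh <- dna_heads_forward(model, latent, keep_cache = keep_cache)
  ctf <- ct_forward(model, features, keep_cache = keep_cache)
  feat <- cbind(dh$avg, dh$dist_mat, ctf$delta)
  cc <- conv1d_forward(feat, model$params$comb$conv)
  rc <- relu_forward(cc$y)
  nb <- nrow(feat)
  z <- matrix(0, nb, M)
  hc <- vector("list", M)
  skip <- model$params$comb$skip
  for (m in seq_len(M)) {
    hc[[m]] <- dense_forward(rc$y, model$params$comb$heads[[m]])
    z[, m] <- as.numeric(hc[[m]]$y) +
      skip$wa[m] * dh$avg[, m] + skip$wd[m] * ctf$delta[, m]
  }
  pred <- link_forward(z, model$cfg$link)
  out <- list(pred = pred, z = z, avg = dh$avg, dist_mat = dh$dist_mat,
              delta = ctf$delta)
  if (keep_cache)
    out$cache <- list(dh = dh$cache, ct = ctf$cache, cc = cc, rc = rc,
                      hc = hc, latent = latent)
  out
}

# dpred is the gradient wrt the combined, positive-link output (arcsinh
# scale). Returns the full trainable-gradient tree plus input gradients.
model_backward <- function(model, fw, dpred,
                           davg_extra = NULL, ddist_extra = NULL,
                           ddelta_extra = NULL) {
  M <- model$cfg$n_marks; K <- model$n_dist_bins
  cache <- fw$cache
  dz <- dpred * link_grad(fw$z, model$cfg$link)
  drc <- matrix(0, nrow(fw$pred), model$cfg$comb_channels)
  ghead <- vector("list", M)
  for (m in seq_len(M)) {
    g <- dense_backward(cache$hc[[m]], model$params$comb$heads[[m]],
                        matrix(dz[, m], ncol = 1))
    ghead[[m]] <- list(W = g$dW, b = g$db)
    drc <- drc + g$dx
  }
  dcc <- relu_backward(cache$rc, drc)
  gconv <- conv1d_backward(cache$cc, model$params$comb$conv, dcc)
  dfeat <- gconv$dx
  davg <- dfeat[, seq_len(M), drop = FALSE]
  ddist <- dfeat[, (M + 1):(M + M * K), drop = FALSE]
  ddelta <- dfeat[, (M + M * K + 1):(M + M * K + M), drop = FALSE]
  skip <- model$params$comb$skip
  gskip <- list(wa = colSums(dz * fw$avg), wd = colSums(dz * fw$delta))
  davg <- davg + sweep(dz, 2, skip$wa, "*")
  ddelta <- ddelta + sweep(dz, 2, skip$wd, "*")
  if (!is.null(davg_extra)) davg <- davg + davg_extra
  if (!is.null(ddist_extra)) ddist <- ddist + ddist_extra
  if (!is.null(ddelta_extra)) ddelta <- ddelta + ddelta_extra
  gdna <- dna_heads_backward(model, cache$latent, cache$dh, davg, ddist)
  gct <- ct_backward(model, cache$ct, ddelta)
  list(grads = list(dna = gdna$grads, ct = gct$grads,
                    comb = list(conv = list(W = gconv$dW, b = gconv$db),
                                heads = ghead, skip = gskip)),
       dlatent = gdna$dlatent, dlocal = gct$dlocal, dglobal = gct$dglobal)
}

#' Combined forward pass: DNA plus cell-type features to a prediction grid
#'
#' Concatenates the per-bin average, distribution and delta features and runs
#' them through the combined convolutional block and per-mark positive-link
#' heads. Output is on the arcsinh training scale by default; the raw
#' -log10 p-value scale applies the inverse arcsinh (sinh).
#'
#' @param model An assembled `cc_model`.
#' @param dna One-hot DNA matrix (input_len x 4), or a precomputed backbone
#'   latent (T x C) when `is_latent = TRUE`.
#' @param features A `CelltypeFeatures` object.
#' @param output_scale `"arcsinh"` or `"neglog10p"`.
#' @param is_latent Set when `dna` is already a backbone latent.
#' @return Matrix (n_bins x n_marks) with attribute `scale`.
#' @export
combined_forward <- function(model, dna, features,
                             output_scale = c("arcsinh", "neglog10p"),
                             is_latent = FALSE) {
  output_scale <- match.arg(output_scale)
  if (!isTRUE(model$assembled))
    stop("chromcast_error: model not assembled")
  latent <- if (is_latent) dna else backbone_forward(model$backbone, dna)
  fw <- model_forward(model, latent, features)
  pred <- fw$pred
  if (output_scale == "neglog10p") pred <- sinh(pred)
  attr(pred, "scale") <- output_scale
  pred
}
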