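#' Poisson negative log-likelihood loss
#'
#' Mean over elements of `pred - target * log(pred)`; the constant
#' `log(target!)` term is omitted. Used for the average-signal head during
#' pre-training and for the combined output during the full stage.
#'
#' @param pred Positive rates.
#' @param target Non-negative values (arcsinh-scale signal).
#' @return Scalar loss.
#' @export
poisson_nll <- function(pred, target) {
  if (any(!is.finite(pred)))
    stop("chromcast_error: non-finite Poisson rates")
  if (any(pred <= 0)) stop("chromcast_error: non-positive Poisson rates")
  if (any(target < 0)) stop("chromcast_error: negative Poisson targets")
  mean(pred - target * log(pred))
}

poisson_nll_grad <- function(pred, target) {
  (1 - target / pred) / length(pred)
}

cross_entropy <- function(probs, target) {
  -mean(rowSums(target * log(pmax(probs, 1e-12)))) * 1
}

cross_entropy_grad <- function(probs, target) {
  -(target / pmax(probs, 1e-12)) / nrow(probs)
}

mse_loss <- function(pred, target) mean((pred - target)^2)
mse_grad <- function(pred, target) 2 * (pred - target) / length(pred)

# ---- frozen-backbone latent caching --------------------------------------

latent_key <- function(item) {
  sprintf("%s:%d:%s:%d", item$chrom,
          as.integer(item$input_start + item$shift), item$strand,
          as.integer(0))
}

#' Precompute and cache frozen-backbone latents
#'
#' Because the backbone is frozen, its latent for a given (chromosome, input
#' start, strand) is computed once and reused every epoch. The cache records
#' the backbone hash; loading it against a different backbone fails.
#'
#' @param backbone A frozen `BackboneContract`.
#' @param dataset A `cc_dataset`.
#' @param items Item data frame (defaults to all train + validation items).
#' @param path Optional directory to persist the cache (`saveRDS`).
#' @return A `LatentCache` (environment-backed), with a forward-pass counter
#'   in `$n_forward`.
#' @export
cache_latents <- function(backbone, dataset, items = NULL, path = NULL) {
  if (!isTRUE(backbone$frozen))
    stop("chromcast_error: latent caching requires a frozen backbone")
  if (is.null(items))
    items <- rbind(dataset$items$train, dataset$items$val)
  store <- new.env(parent = emptyenv())
  cache <- structure(list(store = store, hash = backbone$hash,
                          counter = new.env(parent = emptyenv())),
                     class = "LatentCache")
  assign("n", 0L, envir = cache$counter)
  for (i in seq_len(nrow(items))) {
    item <- items[i, ]
    key <- latent_key(item)
    if (!exists(key, envir = store, inherits = FALSE)) {
      oh <- item_onehot(dataset, item)
      assign(key, backbone_forward(backbone, oh), envir = store)
      assign("n", get("n", envir = cache$counter) + 1L,
             envir = cache$counter)
    }
  }
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    saveRDS(list(hash = cache$hash,
                 latents = as.list(store)),
            file.path(path, "latent_cache.rds"))
  }
  cache
}

#' Load a persisted latent cache, validating the backbone hash
#' @param path Directory the cache was saved to.
#' @param backbone The backbone the cache must match.
#' @return A `LatentCache`.
#' @export
load_latent_cache <- function(path, backbone) {
  obj <- readRDS(file.path(path, "latent_cache.rds"))
  if (!identical(obj$hash, backbone$hash))
    stop("chromcast_error: stale latent cache (backbone hash mismatch)")
  store <- list2env(obj$latents, parent = emptyenv())
  cache <- structure(list(store = store, hash = obj$hash,
                          counter = new.env(parent = emptyenv())),
                     class = "LatentCache")
  assign("n", 0L, envir = cache$counter)
  cache
}

#' Latent for an item, from cache when available
#' @param model A `cc_model`.
#' @param dataset A `cc_dataset`.
#' @param item One item row.
#' @param cache Optional `LatentCache`.
#' @return Latent matrix (T x C).
#' @export
get_latent <- function(model, dataset, item, cache = NULL) {
  if (!is.null(cache)) {
    if (!identical(cache$hash, model$backbone$hash))
      stop("chromcast_error: stale latent cache (backbone hash mismatch)")
    key <- latent_key(item)
    if (exists(key, envir = cache$store, inherits = FALSE))
      return(get(key, envir = cache$store))
    lat <- backbone_forward(model$backbone, item_onehot(dataset, item))
    assign(key, lat, envir = cache$store)
    assign("n", get("n", envir = cache$counter) + 1L, envir = cache$counter)
    return(lat)
  }
  backbone_forward(model$backbone, item_onehot(dataset, item))
}

target_cache_for <- function(dataset, items) {
  env <- new.env(parent = emptyenv())
  get_tb <- function(i) {
    key <- as.character(i)
    if (!exists(key, envir = env, inherits = FALSE))
      assign(key, item_targets(dataset, items[i, ]), envir = env)
    get(key, envir = env)
  }
  get_tb
}

check_finite_loss <- function(loss, state, what) {
  if (!is.finite(loss)) {
    stop("chromcast_error: non-finite ", what, " loss at step ", state$step,
         " (lr=", state$lr, ", batch=", state$batch_size, ")")
  }
  invisible(loss)
}

#' Pre-train the DNA heads and the cell-typing branch
#'
#' Stage one of the two-stage scheme: the DNA-branch heads are optimised
#' against the cross-cell average (Poisson NLL) and distribution
#' (cross-entropy against the soft target simplex), while the cell-typing
#' branch is optimised against the delta target (MSE). Each submodule has
#' its own Adam optimiser. The backbone stays frozen; latents come from the
#' cache.
#'
#' @param model A `cc_model`.
#' @param dataset A `cc_dataset`.
#' @param state A `TrainState` with `stage = "pretrain"`.
#' @param items Training items (defaults to `dataset$items$train`).
#' @param cache Optional `LatentCache` (built on the fly when `NULL`).
#' @return The model with updated heads/branch, `$pretrained = TRUE`, and a
#'   `$traces$pretrain` data frame (step, dna_avg, dna_dist, ct_delta).
#' @export
pretrain <- function(model, dataset, state = train_state("pretrain"),
                     items = dataset$items$train, cache = NULL) {
  if (nrow(items) == 0) stop("chromcast_error: no training items")
  if (is.null(cache))
    cache <- cache_latents(model$backbone, dataset, items)
  get_tb <- target_cache_for(dataset, items)
  opt_dna <- adam_init(model$params$dna)
  opt_ct <- adam_init(model$params$ct)
  M <- model$cfg$n_marks
  trace <- matrix(0, state$n_steps, 3,
                  dimnames = list(NULL, c("dna_avg", "dna_dist", "ct_delta")))
  nn_seeded(state$seed, {
    for (step in seq_len(state$n_steps)) {
      state$step <- step
      idx <- sample.int(nrow(items), min(state$batch_size, nrow(items)))
      g_dna <- param_zero(model$params$dna)
      g_ct <- param_zero(model$params$ct)
      l_avg <- 0; l_dist <- 0; l_delta <- 0
      for (i in idx) {
        item <- items[i, ]
        tb <- get_tb(i)
        latent <- get_latent(model, dataset, item, cache)
        fw <- dna_heads_forward(model, latent, keep_cache = TRUE)
        tgt_dist <- dist_array_to_mat(tb$dist)
        l_avg <- l_avg + poisson_nll(fw$avg, tb$avg)
        l_dist <- l_dist + cross_entropy(fw$dist_mat, tgt_dist)
        bk <- dna_heads_backward(model, latent, fw$cache,
                                 poisson_nll_grad(fw$avg, tb$avg),
                                 cross_entropy_grad(fw$dist_mat, tgt_dist))
        g_dna <- param_add(g_dna, bk$grads)
        ctf <- ct_forward(model, item_features(dataset, item),
                          keep_cache = TRUE)
        l_delta <- l_delta + mse_loss(ctf$delta, tb$delta)
        cbk <- ct_backward(model, ctf$cache,
                           mse_grad(ctf$delta, tb$delta))
        g_ct <- param_add(g_ct, cbk$grads)
      }
      nb <- length(idx)
      check_finite_loss(l_avg + l_dist + l_delta, state, "pretrain")
      st <- adam_step(model$params$dna, param_scale(g_dna, 1 / nb),
                      opt_dna, state$lr)
      model$params$dna <- st$params; opt_dna <- st$opt
      st <- adam_step(model$params$ct, param_scale(g_ct, 1 / nb),
                      opt_ct, state$lr)
      model$params$ct <- st$params; opt_ct <- st$opt
      trace[step, ] <- c(l_avg, l_dist, l_delta) / nb
    }
  })
  model$traces$pretrain <- data.frame(step = seq_len(state$n_steps), trace)
  model$pretrained <- TRUE
  model
}

full_loss_for_items <- function(model, dataset, items, get_tb, cache,
                                idx = seq_len(nrow(items))) {
  tot <- 0
  for (i in idx) {
    item <- items[i, ]
    tb <- get_tb(i)
    latent <- get_latent(model, dataset, item, cache)
    fw <- model_forward(model, latent, item_features(dataset, item))
    tot <- tot + poisson_nll(fw$pred, tb$cell_signal)
  }
  tot / length(idx)
}

#' Full training stage of the combined model
#'
#' Stage two: the combined head (together with the branch parameters feeding
#' it, but never the frozen backbone) is trained with Poisson NLL against
#' the cell-specific arcsinh signal. Validation loss is evaluated every
#' `eval_every` steps on the held-out cells / chromosomes; training stops
#' early after `patience` evaluations without improvement and the
#' best-validation checkpoint is returned.
#'
#' @param model A pre-trained `cc_model` (set `allow_unpretrained = TRUE` to
#'   skip the check, e.g. for ablation experiments).
#' @param dataset A `cc_dataset`.
#' @param state A `TrainState` with `stage = "full"`.
#' @param cache Optional `LatentCache`.
#' @param allow_unpretrained Skip the pre-training check.
#' @return The model at its best-validation checkpoint with
#'   `$traces$full` (per-step training loss) and `$traces$val`
#'   (step, validation loss).
#' @export
train_full <- function(model, dataset, state = train_state("full"),
                       cache = NULL, allow_unpretrained = FALSE) {
  if (!isTRUE(model$pretrained) && !allow_unpretrained)
    stop("chromcast_error: model not pre-trained (pass allow_unpretrained to override)")
  items <- dataset$items$train
  val_items <- dataset$items$val
  if (nrow(val_items) == 0)
    stop("chromcast_error: empty validation set")
  if (is.null(cache))
    cache <- cache_latents(model$backbone, dataset)
  get_tb <- target_cache_for(dataset, items)
  get_vtb <- target_cache_for(dataset, val_items)
  opt <- adam_init(model$params)
  trace <- numeric(state$n_steps)
  val_trace <- list()
  best <- list(loss = Inf, params = model$params, step = 0L)
  bad_evals <- 0L
  nn_seeded(state$seed, {
    for (step in seq_len(state$n_steps)) {
      state$step <- step
      idx <- sample.int(nrow(items), min(state$batch_size, nrow(items)))
      grads <- param_zero(model$params)
      l_tot <- 0
      for (i in idx) {
        item <- items[i, ]
        tb <- get_tb(i)
        latent <- get_latent(model, dataset, item, cache)
        fw <- model_forward(model, latent, item_features(dataset, item),
                            keep_cache = TRUE)
        l_tot <- l_tot + poisson_nll(fw$pred, tb$cell_signal)
        bk <- model_backward(model, fw,
                             poisson_nll_grad(fw$pred, tb$cell_signal))
        grads <- param_add(grads, bk$grads)
      }
      check_finite_loss(l_tot, state, "full-stage")
      st <- adam_step(model$params, param_scale(grads, 1 / length(idx)),
                      opt, state$lr)
      model$params <- st$params; opt <- st$opt
      trace[step] <- l_tot / length(idx)
      if (step %% state$eval_every == 0 || step == state$n_steps) {
        vl <- full_loss_for_items(model, dataset, val_items, get_vtb, cache)
        val_trace[[length(val_trace) + 1]] <-
          data.frame(step = step, val_loss = vl)
        if (vl < best$loss) {
          best <- list(loss = vl, params = model$params, step = step)
          bad_evals <- 0L
        } else {
          bad_evals <- bad_evals + 1L
          if (bad_evals >= state$patience) break
        }
      }
    }
  })
  last_step <- max(which(trace != 0), 1)
  model$params <- best$params
  model$traces$full <- data.frame(step = seq_len(last_step),
                                  loss = trace[seq_len(last_step)])
  model$traces$val <- do.call(rbind, val_trace)
  model$best_val <- best[c("loss", "step")]
  model
}
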