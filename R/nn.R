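# Minimal neural-network primitives: 1-D convolution, dense layers, pooling,
# softplus/softmax links and the Adam optimiser. Everything is plain matrix
# algebra; each forward returns the caches its backward needs, and every
# backward is checked against central finite differences in the test suite.

nn_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

init_conv1d <- function(k, in_ch, out_ch, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (k * in_ch))
  list(W = array(stats::rnorm(k * in_ch * out_ch, sd = sd),
                 dim = c(k, in_ch, out_ch)),
       b = numeric(out_ch))
}

init_dense <- function(in_dim, out_dim, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / in_dim)
  list(W = matrix(stats::rnorm(in_dim * out_dim, sd = sd), in_dim, out_dim),
       b = numeric(out_dim))
}

# Unfold a (T x C) input into the (Tout x k*C) patch matrix for a conv with
# zero "same" padding and the given stride. Column order matches the
# column-major flattening of the (k, C_in, C_out) weight array: kernel
# position fastest-varying within each input-channel block.
unfold1d <- function(x, k, stride = 1L) {
  Tn <- nrow(x); C <- ncol(x)
  pad <- (k - 1) %/% 2
  out_pos <- seq(1L, Tn, by = stride)
  Tout <- length(out_pos)
  patch <- matrix(0, Tout, k * C)
  for (j in seq_len(k)) {
    src <- out_pos + (j - 1L) - pad
    ok <- src >= 1L & src <= Tn
    cols <- (seq_len(C) - 1L) * k + j
    if (any(ok)) patch[ok, cols] <- x[src[ok], , drop = FALSE]
  }
  patch
}

conv1d_forward <- function(x, par, stride = 1L) {
  k <- dim(par$W)[1]; C <- dim(par$W)[2]
  patch <- unfold1d(x, k, stride)
  Wm <- matrix(par$W, k * C, dim(par$W)[3])
  y <- patch %*% Wm
  y <- sweep(y, 2, par$b, "+")
  list(y = y, patch = patch, in_dim = dim(x), stride = stride, k = k)
}

conv1d_backward <- function(cache, par, dy) {
  k <- cache$k; C <- cache$in_dim[2]; Tn <- cache$in_dim[1]
  Wm <- matrix(par$W, k * C, dim(par$W)[3])
  dW <- array(crossprod(cache$patch, dy), dim = dim(par$W))
  db <- colSums(dy)
  dpatch <- dy %*% t(Wm)
  dx <- matrix(0, Tn, C)
  pad <- (k - 1) %/% 2
  out_pos <- seq(1L, Tn, by = cache$stride)
  for (j in seq_len(k)) {
    src <- out_pos + (j - 1L) - pad
    ok <- src >= 1L & src <= Tn
    cols <- (seq_len(C) - 1L) * k + j
    if (any(ok))
      dx[src[ok], ] <- dx[src[ok], , drop = FALSE] +
        dpatch[ok, cols, drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

dense_forward <- function(x, par) {
  y <- x %*% par$W
  y <- sweep(y, 2, par$b, "+")
  list(y = y, x = x)
}

dense_backward <- function(cache, par, dy) {
  list(dW = crossprod(cache$x, dy), db = colSums(dy),
       dx = dy %*% t(par$W))
}

relu_forward <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_backward <- function(cache, dy) dy * cache$mask

# Non-overlapping average pooling along rows.
avgpool_forward <- function(x, width) {
  Tn <- nrow(x)
  if (Tn %% width != 0)
    stop("chromcast_error: pooling width does not divide input length")
  Tout <- Tn %/% width
  grp <- rep(seq_len(Tout), each = width)
  y <- rowsum(x, grp) / width
  list(y = y, width = width, Tn = Tn)
}

avgpool_backward <- function(cache, dy) {
  dy[rep(seq_len(nrow(dy)), each = cache$width), , drop = FALSE] / cache$width
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
softplus_grad <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax over matrices (rows = positions, cols = classes).
softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# d(loss)/d(logits) given d(loss)/d(probs), for row-wise softmax.
softmax_backward <- function(p, dp) {
  s <- rowSums(dp * p)
  p * (dp - s)
}

# ---- parameter-tree utilities -------------------------------------------

param_map <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- param_map(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

param_zero <- function(a) {
  if (is.list(a)) lapply(a, param_zero) else a * 0
}

param_add <- function(a, b) param_map(a, b, `+`)
param_scale <- function(a, s) {
  if (is.list(a)) lapply(a, param_scale, s = s) else a * s
}

param_count <- function(a) {
  if (is.list(a)) sum(vapply(a, param_count, numeric(1))) else length(a)
}

param_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, param_flatten), use.names = FALSE)
  else as.numeric(a)
}

#' Adam optimiser state
#' @keywords internal
adam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = param_zero(params), v = param_zero(params), t = 0L,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, opt, lr) {
  opt$t <- opt$t + 1L
  opt$m <- param_map(opt$m, grads, function(m, g) opt$beta1 * m + (1 - opt$beta1) * g)
  opt$v <- param_map(opt$v, grads, function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  upd <- param_map(opt$m, opt$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + opt$eps)
  })
  params <- param_map(params, upd, function(p, u) p - lr * u)
  list(params = params, opt = opt)
}

# Stable hash of an R object (used for backbone identity / CLI manifests).
object_hash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
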