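# Elementary differentiable layers on (time, channel, batch) arrays.
# Each layer has a forward returning list(y, cache) and a backward taking the
# upstream gradient plus the cache. Nothing here is exported; the network
# module composes these into the full architecture.

# Multiply an (L, C, B) array elementwise by a per-channel vector.
# Relies on column-major recycling: rep(v, each = L) tiles over (L, C) and
# recycles across B.
channel_scale <- function(x, v) {
  d <- dim(x)
  x * rep(v, each = d[1L])
}

# Per-channel sums over the time and batch axes of an (L, C, B) array.
channel_sum <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1L])           # L x (C*B)
  rowSums(matrix(colSums(m), d[2L], d[3L]))
}

# Truncated-normal fan-in initializer (+/- 2 sd), draws from the R RNG.
init_truncnorm <- function(n, fan_in) {
  sd <- 1 / sqrt(max(fan_in, 1))
  lo <- pnorm(-2); hi <- pnorm(2)
  qnorm(runif(n, lo, hi)) * sd
}

## ---- grouped temporal convolution (C++ backed) ----

conv1d_fwd <- function(x, w, groups = 1L, single = FALSE) {
  .cpp_conv1d_fwd(x, w, dim(x), dim(w), as.integer(groups), single)
}

conv1d_bwd <- function(x, w, dy, groups = 1L, need_dx = TRUE,
                       single = FALSE) {
  .cpp_conv1d_bwd(x, w, dy, dim(x), dim(w), as.integer(groups), need_dx,
                  single)
}

spatial_dw_fwd <- function(x, w) .cpp_spatial_dw_fwd(x, w, dim(x), dim(w))

spatial_dw_bwd <- function(x, w, dy, need_dx = TRUE) {
  .cpp_spatial_dw_bwd(x, w, dy, dim(x), dim(w), need_dx)
}

## ---- batch normalization (per channel over time x batch) ----

bn_fwd <- function(x, gamma, beta, running, mode, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  n <- d[1L] * d[3L]
  if (mode == "train") {
    if (d[3L] < 2L)
      stop("batch normalization in training mode requires batch size >= 2")
    mom <- .cpp_channel_moments(x, d)
    mu <- mom[1L, ] / n
    v <- mom[2L, ] / n - mu^2
    inv_sd <- 1 / sqrt(v + eps)
    na <- .cpp_bn_norm_affine(x, d, mu, inv_sd, gamma, beta)
    xhat <- na$xhat
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    inv_sd <- 1 / sqrt(running$var + eps)
    na <- .cpp_bn_norm_affine(x, d, running$mean, inv_sd, gamma, beta)
    xhat <- na$xhat
  }
  y <- na$y
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma,
                           mode = mode, n = n),
       running = running)
}

bn_bwd <- function(dy, cache) {
  d <- dim(dy)
  sums <- .cpp_bn_bwd_sums(dy, cache$xhat, d)
  dgamma <- sums[1L, ]
  dbeta <- sums[2L, ]
  scale <- cache$gamma * cache$inv_sd
  if (cache$mode == "train") {
    n <- cache$n
    dx <- .cpp_bn_dx(dy, cache$xhat, d, dbeta / n, dgamma / n, scale)
  } else {
    dx <- .cpp_scale_shift(dy, d, scale, numeric(length(scale)))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- ELU ----

elu_fwd <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- exp(x[neg]) - 1
  list(y = y, cache = list(y = y, neg = neg))
}

elu_bwd <- function(dy, cache) {
  g <- dy
  g[cache$neg] <- dy[cache$neg] * (cache$y[cache$neg] + 1)
  g
}

## ---- average pooling along time with an explicit output length ----
# out_len * size <= L truncates the tail; out_len * size > L right-pads the
# final window, which is averaged over its real samples only.

pool_fwd <- function(x, size, out_len) {
  d <- dim(x)
  L <- d[1L]
  full <- out_len * size <= L
  if (full) {
    xx <- x[seq_len(out_len * size), , , drop = FALSE]
    dim(xx) <- c(size, out_len, d[2L], d[3L])
    y <- colMeans(xx)                      # (out_len, C, B)
    counts <- rep(size, out_len)
  } else {
    counts <- pmin(seq_len(out_len) * size, L) -
      (seq_len(out_len) - 1L) * size
    if (any(counts <= 0)) stop("pool output length exceeds input coverage")
    y <- array(0, c(out_len, d[2L], d[3L]))
    for (j in seq_len(out_len)) {
      idx <- ((j - 1L) * size + 1L):min(j * size, L)
      y[j, , ] <- colMeans(x[idx, , , drop = FALSE], dims = 1L)
    }
  }
  dim(y) <- c(out_len, d[2L], d[3L])
  list(y = y, cache = list(L = L, size = size, out_len = out_len,
                           counts = counts, d = d))
}

pool_bwd <- function(dy, cache) {
  d <- cache$d
  dx <- array(0, d)
  for (j in seq_len(cache$out_len)) {
    idx <- ((j - 1L) * cache$size + 1L):min(j * cache$size, cache$L)
    share <- dy[j, , , drop = FALSE] / cache$counts[j]
    dx[idx, , ] <- dx[idx, , , drop = FALSE] +
      array(rep(share, each = length(idx)),
            c(length(idx), d[2L], d[3L]))
  }
  dx
}

## ---- dropout (inverted; identity in eval mode) ----

dropout_fwd <- function(x, p, mode) {
  if (mode != "train" || p <= 0) {
    return(list(y = x, cache = NULL))
  }
  keep <- array(rbinom(length(x), 1L, 1 - p), dim(x)) / (1 - p)
  list(y = x * keep, cache = keep)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

## ---- affine classifier + softmax ----

linear_fwd <- function(x, w, b) {
  # x: (n_features, B); w: (n_out, n_features); b: (n_out)
  list(y = w %*% x + b, cache = list(x = x, w = w))
}

linear_bwd <- function(dy, cache) {
  list(dx = crossprod(cache$w, dy),
       dw = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}
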