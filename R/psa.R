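#' Configure a pyramid squeeze attention (PSA) block
#'
#' A PSA block recalibrates a feature map in four steps: (1) the channels are
#' split into `S` contiguous groups and each group is convolved along time
#' with its own kernel size ("squeeze and concat", the multi-scale step);
#' (2) a squeeze-and-excitation bottleneck turns each branch into a
#' per-channel attention vector in (0, 1); (3) the attention vectors are
#' normalized across branches with a softmax, per channel slot; (4) each
#' branch is multiplied elementwise by its normalized weights and the
#' branches are concatenated back. Output shape always equals input shape.
#'
#' @param n_channels Channel count `C` of the feature map entering the block.
#' @param kernel_sizes Odd temporal kernel extents, one per branch.
#' @param se_hidden Hidden width of the excitation bottleneck; default
#'   `max((C/S) %/% 4, 1)`.
#' @param branch_groups Convolution group count inside each branch (default 1,
#'   a plain convolution).
#' @param split_channels If `TRUE` (default) branch `i` sees only its own
#'   contiguous `C/S` channels; if `FALSE` every branch convolves all `C`
#'   channels down to `C/S`.
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(n_channels, kernel_sizes = c(3, 5, 7, 9),
                       se_hidden = NULL, branch_groups = 1L,
                       split_channels = TRUE) {
  S <- length(kernel_sizes)
  if (S < 1L) stop("at least one branch kernel is required")
  if (n_channels %% S != 0L)
    stop("n_channels (", n_channels, ") must be divisible by the number of branches (", S, ")")
  if (any(kernel_sizes < 1L) || any(kernel_sizes %% 2L == 0L))
    stop("PSA kernel sizes must be odd and >= 1")
  cpg <- n_channels %/% S
  if (is.null(se_hidden)) se_hidden <- max(cpg %/% 4L, 1L)
  if (se_hidden < 1L) stop("se_hidden must be >= 1")
  structure(list(n_channels = as.integer(n_channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 n_branches = as.integer(S),
                 channels_per_branch = as.integer(cpg),
                 se_hidden = as.integer(se_hidden),
                 branch_groups = as.integer(branch_groups),
                 split_channels = isTRUE(split_channels)),
            class = "psa_config")
}

# Initialize PSA parameters (branch convolution kernels + excitation MLPs).
psa_init <- function(config) {
  cpg <- config$channels_per_branch
  cin <- if (config$split_channels) cpg else config$n_channels
  cin_pg <- cin %/% config$branch_groups
  branches <- lapply(seq_len(config$n_branches), function(i) {
    k <- config$kernel_sizes[i]
    list(
      w = array(init_truncnorm(k * cin_pg * cpg, fan_in = k * cin_pg),
                c(k, cin_pg, cpg)),
      se = list(
        W1 = matrix(init_truncnorm(config$se_hidden * cpg, cpg),
                    config$se_hidden, cpg),
        b1 = numeric(config$se_hidden),
        W2 = matrix(init_truncnorm(cpg * config$se_hidden, config$se_hidden),
                    cpg, config$se_hidden),
        b2 = numeric(cpg)
      )
    )
  })
  list(branches = branches)
}

#' Multi-scale squeeze-and-concat convolution
#'
#' Splits the channels of a `(time, channel, batch)` feature map into the
#' block's contiguous groups and convolves each group along time with its
#' branch kernel (same zero padding, no bias).
#'
#' @param x Numeric array `(time, channel, batch)`.
#' @param params PSA parameter list as produced by the network initializer.
#' @param config A [psa_config()].
#' @return A list of `S` branch arrays, each `(time, C/S, batch)`.
#' @export
squeeze_concat <- function(x, params, config) {
  cpg <- config$channels_per_branch
  lapply(seq_len(config$n_branches), function(i) {
    xi <- if (config$split_channels)
      x[, ((i - 1L) * cpg + 1L):(i * cpg), , drop = FALSE]
    else x
    conv1d_fwd(xi, params$branches[[i]]$w, groups = config$branch_groups)
  })
}

#' Squeeze-and-excitation attention vector for one branch
#'
#' Global average over time per channel, then a bottleneck of two affine maps
#' with a rectifier between them and a logistic output, yielding one
#' attention value in (0, 1) per channel and batch item.
#'
#' @param branch Array `(time, C/S, batch)`.
#' @param se List with `W1`, `b1`, `W2`, `b2`.
#' @return Matrix `(C/S, batch)` of attention values in (0, 1).
#' @export
se_weight <- function(branch, se) {
  d <- dim(branch)
  z <- matrix(colMeans(matrix(branch, d[1L])), d[2L], d[3L])
  h <- pmax(se$W1 %*% z + se$b1, 0)
  stats::plogis(se$W2 %*% h + se$b2)
}

#' Cross-branch softmax normalization
#'
#' For every channel slot (and batch item), the `S` branch attention values
#' are normalized with a numerically stabilized softmax so that they sum to
#' one across branches.
#'
#' @param vectors List of `S` matrices `(C/S, batch)` (or vectors).
#' @return List of `S` matrices of the same shape, summing to 1 across the
#'   list at every position.
#' @export
cross_branch_softmax <- function(vectors) {
  S <- length(vectors)
  m <- do.call(rbind, lapply(vectors, as.vector))  # S x (C/S * B)
  m <- sweep(m, 2L, apply(m, 2L, max))
  e <- exp(m)
  w <- sweep(e, 2L, colSums(e), "/")
  lapply(seq_len(S), function(i) {
    out <- vectors[[i]]
    out[] <- w[i, ]
    out
  })
}

#' Full PSA block forward pass
#'
#' Composes [squeeze_concat()], [se_weight()], [cross_branch_softmax()] and
#' the elementwise recalibration; the output has exactly the input shape.
#'
#' @inheritParams squeeze_concat
#' @param want_cache Keep intermediates for the backward pass (internal).
#' @return Array with the shape of `x` (or, with `want_cache`, a list with
#'   elements `y` and `cache`).
#' @export
psa_forward <- function(x, params, config, want_cache = FALSE) {
  d <- dim(x)
  if (d[2L] != config$n_channels)
    stop("feature map has ", d[2L], " channels but the PSA block expects ",
         config$n_channels)
  branches <- squeeze_concat(x, params, config)
  att <- lapply(seq_len(config$n_branches), function(i)
    se_weight(branches[[i]], params$branches[[i]]$se))
  wgt <- cross_branch_softmax(att)
  cpg <- config$channels_per_branch
  y <- array(0, d)
  for (i in seq_len(config$n_branches)) {
    cols <- ((i - 1L) * cpg + 1L):(i * cpg)
    y[, cols, ] <- branches[[i]] * rep(wgt[[i]], each = d[1L])
  }
  if (!want_cache) return(y)
  list(y = y, cache = list(x = x, branches = branches, att = att, wgt = wgt))
}

# Backward pass through a PSA block. Returns dx and parameter gradients with
# the same structure as psa_init().
psa_backward <- function(dy, params, config, cache) {
  d <- dim(dy)
  L <- d[1L]
  cpg <- config$channels_per_branch
  S <- config$n_branches
  x <- cache$x

  # gradient wrt each branch map and each normalized weight
  dbranch <- vector("list", S)
  dwgt <- vector("list", S)
  for (i in seq_len(S)) {
    cols <- ((i - 1L) * cpg + 1L):(i * cpg)
    dyi <- dy[, cols, , drop = FALSE]
    dbranch[[i]] <- dyi * rep(cache$wgt[[i]], each = L)
    dwgt[[i]] <- matrix(colSums(matrix(dyi * cache$branches[[i]], L)),
                        cpg, d[3L])
  }

  # softmax backward across branches, per (channel slot, batch)
  wm <- do.call(rbind, lapply(cache$wgt, as.vector))    # S x n
  dm <- do.call(rbind, lapply(dwgt, as.vector))
  datt_m <- wm * (dm - rep(colSums(wm * dm), each = S))

  dx <- array(0, dim(x))
  dparams <- list(branches = vector("list", S))
  for (i in seq_len(S)) {
    se <- params$branches[[i]]$se
    branch <- cache$branches[[i]]
    db <- dim(branch)
    z <- matrix(colMeans(matrix(branch, L)), cpg, db[3L])
    h <- pmax(se$W1 %*% z + se$b1, 0)
    a <- cache$att[[i]]
    da <- matrix(datt_m[i, ], cpg, db[3L])
    dpre2 <- da * a * (1 - a)
    dW2 <- tcrossprod(dpre2, h)
    db2 <- rowSums(dpre2)
    dh <- crossprod(se$W2, dpre2) * (h > 0)
    dW1 <- tcrossprod(dh, z)
    db1 <- rowSums(dh)
    dz <- crossprod(se$W1, dh)                      # (cpg, B)
    # attention fed back through the global average pool
    dbranch_tot <- dbranch[[i]] + rep(dz / L, each = L)
    xi <- if (config$split_channels)
      x[, ((i - 1L) * cpg + 1L):(i * cpg), , drop = FALSE]
    else x
    g <- conv1d_bwd(xi, params$branches[[i]]$w, dbranch_tot,
                    groups = config$branch_groups, need_dx = TRUE)
    if (config$split_channels) {
      cols <- ((i - 1L) * cpg + 1L):(i * cpg)
      dx[, cols, ] <- dx[, cols, , drop = FALSE] + g$dx
    } else {
      dx <- dx + g$dx
    }
    dparams$branches[[i]] <- list(w = g$dw,
                                  se = list(W1 = dW1, b1 = db1,
                                            W2 = dW2, b2 = db2))
  }
  list(dx = dx, dparams = dparams)
}
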