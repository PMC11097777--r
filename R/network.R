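#' PSA kernel-size sets used in the ablation study
#'
#' Named kernel quadruples: A `(3,5,7,9)`, B `(1,3,5,7)`, C `(5,7,9,11)`,
#' D `(7,9,11,13)`, E `(9,11,13,15)`.
#' @export
psa_kernel_sets <- list(A = c(3L, 5L, 7L, 9L), B = c(1L, 3L, 5L, 7L),
                        C = c(5L, 7L, 9L, 11L), D = c(7L, 9L, 11L, 13L),
                        E = c(9L, 11L, 13L, 15L))

#' Configure a PSAEEGNet network
#'
#' Defaults reproduce the reference architecture for 62-channel, 250-sample
#' (1 s at 250 Hz) epochs: a temporal convolution of 8 filters and kernel
#' `(1, 125)`, a spatial depthwise convolution over all electrodes with depth
#' multiplier 2 (16 feature channels), a PSA block with kernels `(3,5,7,9)`
#' in the spatial stage and `(1,3,5,7)` in the deep temporal stage, two
#' average pools of width 8 reducing 250 to 31 and 31 to 4 samples, dropout
#' 0.5, and a two-unit softmax classifier over the 64 flattened features.
#'
#' @param n_channels,n_samples Epoch geometry (electrodes x samples).
#' @param temporal_filters Number of temporal filters `F1`.
#' @param temporal_kernel Temporal kernel length of the first convolution.
#' @param depth_multiplier Spatial depthwise multiplier `D`; the spatial stage
#'   outputs `F2 = F1 * D` channels.
#' @param separable_kernel Depthwise temporal kernel length in the deep stage.
#' @param pool_size Width of both average pools.
#' @param pool_out_lengths Integer pair of pooled lengths, or `NULL` to derive
#'   them (`floor` for the first pool, `ceiling` with a right-padded partial
#'   window for the second, matching the reference 31 and 4).
#' @param dropout_p Dropout probability after each pooled stage.
#' @param psa_psfe,psa_dtfe [psa_config()] for the spatial and deep temporal
#'   stages, or `NULL` to disable that attention block.
#' @param n_classes Number of output units (2 for target/non-target).
#' @param precision `"single"` (default) runs the dominant temporal
#'   convolution GEMMs in single precision, the usual choice for this model
#'   family; `"double"` computes everything in double (used e.g. by the
#'   finite-difference gradient checks). All other arithmetic is double
#'   either way.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_channels = 62L, n_samples = 250L,
                           temporal_filters = 8L, temporal_kernel = 125L,
                           depth_multiplier = 2L, separable_kernel = 16L,
                           pool_size = 8L, pool_out_lengths = NULL,
                           dropout_p = 0.5,
                           psa_psfe = psa_config(temporal_filters * depth_multiplier,
                                                 psa_kernel_sets$A),
                           psa_dtfe = psa_config(temporal_filters * depth_multiplier,
                                                 psa_kernel_sets$B),
                           n_classes = 2L,
                           precision = c("single", "double")) {
  precision <- match.arg(precision)
  f2 <- temporal_filters * depth_multiplier
  if (is.null(pool_out_lengths)) {
    p1 <- n_samples %/% pool_size
    p2 <- as.integer(ceiling(p1 / pool_size))
    pool_out_lengths <- c(p1, p2)
  }
  if (length(pool_out_lengths) != 2L || any(pool_out_lengths < 1L))
    stop("pool_out_lengths must be two positive integers")
  if ((pool_out_lengths[1L] - 1L) * pool_size >= n_samples)
    stop("first pool output length incompatible with n_samples")
  if ((pool_out_lengths[2L] - 1L) * pool_size >= pool_out_lengths[1L])
    stop("second pool output length incompatible with the first")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  for (blk in list(psa_psfe, psa_dtfe))
    if (!is.null(blk) && blk$n_channels != f2)
      stop("PSA blocks must be configured for ", f2, " channels")
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 temporal_filters = as.integer(temporal_filters),
                 temporal_kernel = as.integer(temporal_kernel),
                 depth_multiplier = as.integer(depth_multiplier),
                 n_feature_channels = as.integer(f2),
                 separable_kernel = as.integer(separable_kernel),
                 pool_size = as.integer(pool_size),
                 pool_out_lengths = as.integer(pool_out_lengths),
                 dropout_p = dropout_p,
                 psa_psfe = psa_psfe, psa_dtfe = psa_dtfe,
                 n_classes = as.integer(n_classes),
                 precision = precision,
                 n_flat = as.integer(f2 * pool_out_lengths[2L])),
            class = "network_config")
}

#' Describe an ablation variant
#'
#' The four attention-count variants are `"A+A"` (PSA in both the spatial and
#' deep temporal stages), `"A+0"` (spatial only), `"0+A"` (deep temporal
#' only) and `"EEGNet"` (no attention, the blank control). The kernel sweep
#' keeps the first block at set A and varies the second block over sets A-E;
#' the shipped default network is `A+B`.
#'
#' @param name One of `"A+A"`, `"A+0"`, `"0+A"`, `"EEGNet"`.
#' @param second_psa_kernels Kernel set letter `"A"`..`"E"` for the deep
#'   temporal PSA block (ignored when that block is disabled).
#' @return An object of class `ablation_spec`.
#' @export
ablation_spec <- function(name = c("A+A", "A+0", "0+A", "EEGNet"),
                          second_psa_kernels = "A") {
  name <- match.arg(name)
  if (!second_psa_kernels %in% names(psa_kernel_sets))
    stop("unknown kernel set '", second_psa_kernels, "'")
  structure(list(name = name, second_psa_kernels = second_psa_kernels),
            class = "ablation_spec")
}

#' Apply an ablation variant to a network configuration
#'
#' @param config A [network_config()].
#' @param spec An [ablation_spec()].
#' @return The modified configuration.
#' @export
apply_ablation <- function(config, spec) {
  f2 <- config$n_feature_channels
  first <- psa_config(f2, psa_kernel_sets$A)
  second <- psa_config(f2, psa_kernel_sets[[spec$second_psa_kernels]])
  config$psa_psfe <- switch(spec$name, "A+A" = first, "A+0" = first,
                            "0+A" = NULL, "EEGNet" = NULL)
  config$psa_dtfe <- switch(spec$name, "A+A" = second, "0+A" = second,
                            "A+0" = NULL, "EEGNet" = NULL)
  config
}

#' Build (initialize) a PSAEEGNet network
#'
#' Allocates all trainable parameters (truncated-normal fan-in initialization
#' drawn from the current R RNG state; batch-norm scales 1, offsets 0;
#' classifier bias 0) and the batch-norm running statistics.
#'
#' @param config A [network_config()].
#' @return An object of class `psa_network`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  f1 <- config$temporal_filters
  f2 <- config$n_feature_channels
  d <- config$depth_multiplier
  params <- list(
    ptfe_w = array(init_truncnorm(config$temporal_kernel * f1,
                                  config$temporal_kernel),
                   c(config$temporal_kernel, 1L, f1)),
    bn1_gamma = rep(1, f1), bn1_beta = numeric(f1),
    spat_w = array(init_truncnorm(config$n_channels * d * f1,
                                  config$n_channels),
                   c(config$n_channels, d, f1)),
    bn2_gamma = rep(1, f2), bn2_beta = numeric(f2)
  )
  if (!is.null(config$psa_psfe)) {
    params$psa1 <- psa_init(config$psa_psfe)
    params$bn3_gamma <- rep(1, f2)
    params$bn3_beta <- numeric(f2)
  }
  params$dtfe_w <- array(init_truncnorm(config$separable_kernel * f2,
                                        config$separable_kernel),
                         c(config$separable_kernel, 1L, f2))
  if (!is.null(config$psa_dtfe)) params$psa2 <- psa_init(config$psa_dtfe)
  params$point_w <- array(init_truncnorm(f2 * f2, f2), c(1L, f2, f2))
  params$bn4_gamma <- rep(1, f2)
  params$bn4_beta <- numeric(f2)
  params$fc_w <- matrix(init_truncnorm(config$n_classes * config$n_flat,
                                       config$n_flat),
                        config$n_classes, config$n_flat)
  params$fc_b <- numeric(config$n_classes)

  running <- list(
    bn1 = list(mean = numeric(f1), var = rep(1, f1)),
    bn2 = list(mean = numeric(f2), var = rep(1, f2)),
    bn3 = list(mean = numeric(f2), var = rep(1, f2)),
    bn4 = list(mean = numeric(f2), var = rep(1, f2))
  )
  structure(list(config = config, params = params, running = running),
            class = "psa_network")
}

# Convert an (trials x channels x samples) epoch array to the internal
# (time, electrode, batch) layout.
epochs_to_internal <- function(epochs, config) {
  d <- dim(epochs)
  if (length(d) != 3L)
    stop("epochs must be a 3-d array (trials x channels x samples)")
  if (d[2L] != config$n_channels)
    stop("epoch channel axis has ", d[2L], " channels; the network expects ",
         config$n_channels)
  if (d[3L] != config$n_samples)
    stop("epoch sample axis has ", d[3L], " samples; the network expects ",
         config$n_samples)
  aperm(epochs, c(3L, 2L, 1L))
}

#' Forward pass through a PSAEEGNet network
#'
#' @param net A [build_network()] object (possibly trained).
#' @param epochs Numeric array `(trials, channels, samples)` or an
#'   [epoch_set()].
#' @param mode `"eval"` (deterministic: dropout off, running batch-norm
#'   statistics) or `"train"` (batch statistics, dropout active, requires
#'   batch size >= 2).
#' @param want_cache,want_stages Internal: keep backward-pass intermediates /
#'   record per-stage output shapes.
#' @return Matrix `(trials, 2)` of class probabilities (rows sum to 1), or a
#'   list when caches/stages are requested.
#' @export
network_forward <- function(net, epochs, mode = c("eval", "train"),
                            want_cache = FALSE, want_stages = FALSE) {
  mode <- match.arg(mode)
  if (inherits(epochs, "epoch_set")) epochs <- epochs$epochs
  cfg <- net$config
  # cache-free evaluation of large trial sets runs in blocks to bound the
  # working set (the first stage expands each trial F1-fold)
  if (mode == "eval" && !want_cache && !want_stages &&
      dim(epochs)[1L] > 128L) {
    starts <- seq(1L, dim(epochs)[1L], by = 128L)
    return(do.call(rbind, lapply(starts, function(s) {
      idx <- s:min(s + 127L, dim(epochs)[1L])
      network_forward(net, epochs[idx, , , drop = FALSE], mode = "eval")
    })))
  }
  p <- net$params
  x <- epochs_to_internal(epochs, cfg)
  L <- cfg$n_samples; H <- cfg$n_channels; B <- dim(x)[3L]
  f1 <- cfg$temporal_filters; f2 <- cfg$n_feature_channels
  cache <- list(); stages <- list()
  running <- net$running

  ## -- PTFE: temporal convolution over every electrode series + batch norm
  single <- identical(cfg$precision, "single")
  dim(x) <- c(L, 1L, H * B)
  cache$x_in <- x
  y <- conv1d_fwd(x, p$ptfe_w, groups = 1L, single = single)  # (L, F1, H*B)
  if (want_stages) stages$ptfe_conv <- c(f1, H, L)
  bn1 <- bn_fwd(y, p$bn1_gamma, p$bn1_beta, running$bn1, mode)
  running$bn1 <- bn1$running
  cache$bn1 <- bn1$cache
  y <- bn1$y
  dim(y) <- c(L, f1, H, B)

  ## -- PSFE: spatial depthwise conv + BN + ELU (+ PSA + BN + ELU) + pool
  cache$x_spat <- y
  y <- spatial_dw_fwd(y, p$spat_w)                    # (L, F2, B)
  if (want_stages) stages$spatial_dw <- c(f2, 1L, L)
  bn2 <- bn_fwd(y, p$bn2_gamma, p$bn2_beta, running$bn2, mode)
  running$bn2 <- bn2$running
  cache$bn2 <- bn2$cache
  e1 <- elu_fwd(bn2$y); cache$elu1 <- e1$cache; y <- e1$y
  if (!is.null(cfg$psa_psfe)) {
    ps <- psa_forward(y, p$psa1, cfg$psa_psfe, want_cache = TRUE)
    cache$psa1 <- ps$cache
    if (want_stages) stages$psa_psfe <- c(f2, 1L, L)
    bn3 <- bn_fwd(ps$y, p$bn3_gamma, p$bn3_beta, running$bn3, mode)
    running$bn3 <- bn3$running
    cache$bn3 <- bn3$cache
    e2 <- elu_fwd(bn3$y); cache$elu2 <- e2$cache; y <- e2$y
  }
  p1 <- pool_fwd(y, cfg$pool_size, cfg$pool_out_lengths[1L])
  cache$pool1 <- p1$cache; y <- p1$y                  # (P1, F2, B)
  if (want_stages) stages$pool1 <- c(f2, 1L, cfg$pool_out_lengths[1L])
  d1 <- dropout_fwd(y, cfg$dropout_p, mode)
  cache$drop1 <- d1$cache; y <- d1$y

  ## -- DTFE: separable conv (depthwise + PSA + pointwise) + BN + ELU + pool
  cache$x_dtfe <- y
  y <- conv1d_fwd(y, p$dtfe_w, groups = f2)           # depthwise (1, K)
  if (want_stages) stages$dtfe_dw <- c(f2, 1L, cfg$pool_out_lengths[1L])
  if (!is.null(cfg$psa_dtfe)) {
    ps2 <- psa_forward(y, p$psa2, cfg$psa_dtfe, want_cache = TRUE)
    cache$psa2 <- ps2$cache
    cache$x_point_in <- ps2$y
    y <- ps2$y
    if (want_stages) stages$psa_dtfe <- c(f2, 1L, cfg$pool_out_lengths[1L])
  } else cache$x_point_in <- y
  y <- conv1d_fwd(y, p$point_w, groups = 1L)          # pointwise (1, 1)
  bn4 <- bn_fwd(y, p$bn4_gamma, p$bn4_beta, running$bn4, mode)
  running$bn4 <- bn4$running
  cache$bn4 <- bn4$cache
  e3 <- elu_fwd(bn4$y); cache$elu3 <- e3$cache; y <- e3$y
  p2 <- pool_fwd(y, cfg$pool_size, cfg$pool_out_lengths[2L])
  cache$pool2 <- p2$cache; y <- p2$y                  # (P2, F2, B)
  if (want_stages) stages$pool2 <- c(f2, 1L, cfg$pool_out_lengths[2L])
  d2 <- dropout_fwd(y, cfg$dropout_p, mode)
  cache$drop2 <- d2$cache; y <- d2$y

  ## -- classifier
  dim(y) <- c(cfg$n_flat, B)
  if (want_stages) stages$flatten <- cfg$n_flat
  lin <- linear_fwd(y, p$fc_w, p$fc_b)
  cache$lin <- lin$cache
  probs <- softmax_cols(lin$y)                        # (2, B)
  if (want_stages) stages$output <- cfg$n_classes
  cache$probs <- probs

  out <- t(probs)
  colnames(out) <- c("nontarget", "target")[seq_len(min(2L, cfg$n_classes))]
  if (!want_cache && !want_stages) return(out)
  res <- list(probs = out)
  if (want_cache) {
    res$cache <- cache
    res$running <- running
  }
  if (want_stages) res$stages <- stages
  res
}

# Backward pass: takes dlogits (n_classes x B) and the forward cache,
# returns gradients with the same structure as net$params.
network_backward <- function(net, dlogits, cache) {
  cfg <- net$config
  p <- net$params
  g <- list()

  lb <- linear_bwd(dlogits, cache$lin)
  g$fc_w <- lb$dw; g$fc_b <- lb$db
  y <- lb$dx
  B <- ncol(y)
  f2 <- cfg$n_feature_channels
  dim(y) <- c(cfg$pool_out_lengths[2L], f2, B)

  y <- dropout_bwd(y, cache$drop2)
  y <- pool_bwd(y, cache$pool2)
  y <- elu_bwd(y, cache$elu3)
  b4 <- bn_bwd(y, cache$bn4)
  g$bn4_gamma <- b4$dgamma; g$bn4_beta <- b4$dbeta
  pb <- conv1d_bwd(cache$x_point_in, p$point_w, b4$dx, groups = 1L)
  g$point_w <- pb$dw
  y <- pb$dx
  if (!is.null(cfg$psa_dtfe)) {
    ps2 <- psa_backward(y, p$psa2, cfg$psa_dtfe, cache$psa2)
    g$psa2 <- ps2$dparams
    y <- ps2$dx
  }
  db <- conv1d_bwd(cache$x_dtfe, p$dtfe_w, y, groups = f2)
  g$dtfe_w <- db$dw
  y <- db$dx

  y <- dropout_bwd(y, cache$drop1)
  y <- pool_bwd(y, cache$pool1)
  if (!is.null(cfg$psa_psfe)) {
    y <- elu_bwd(y, cache$elu2)
    b3 <- bn_bwd(y, cache$bn3)
    g$bn3_gamma <- b3$dgamma; g$bn3_beta <- b3$dbeta
    ps1 <- psa_backward(b3$dx, p$psa1, cfg$psa_psfe, cache$psa1)
    g$psa1 <- ps1$dparams
    y <- ps1$dx
  }
  y <- elu_bwd(y, cache$elu1)
  b2 <- bn_bwd(y, cache$bn2)
  g$bn2_gamma <- b2$dgamma; g$bn2_beta <- b2$dbeta
  sb <- spatial_dw_bwd(cache$x_spat, p$spat_w, b2$dx, need_dx = TRUE)
  g$spat_w <- sb$dw
  y <- sb$dx

  L <- cfg$n_samples; H <- cfg$n_channels
  dim(y) <- c(L, cfg$temporal_filters, H * dim(cache$x_spat)[4L])
  b1 <- bn_bwd(y, cache$bn1)
  g$bn1_gamma <- b1$dgamma; g$bn1_beta <- b1$dbeta
  cb <- conv1d_bwd(cache$x_in, p$ptfe_w, b1$dx, groups = 1L, need_dx = FALSE,
                   single = identical(cfg$precision, "single"))
  g$ptfe_w <- cb$dw
  g
}

#' Symbolic layer-by-layer shape walk
#'
#' Returns, without running any data, the ordered list of layers and output
#' shapes the configuration produces; with the defaults this reproduces the
#' reference architecture table, including the pooled lengths 31 and 4 and
#' the 64-unit flattened classifier input.
#'
#' @param config A [network_config()].
#' @return Data frame with columns `module`, `layer` and `output` (shapes as
#'   printed strings), plus a `shapes` attribute holding the numeric shapes.
#' @export
stage_shapes <- function(config) {
  stopifnot(inherits(config, "network_config"))
  L <- config$n_samples; H <- config$n_channels
  f1 <- config$temporal_filters; f2 <- config$n_feature_channels
  p1 <- config$pool_out_lengths[1L]; p2 <- config$pool_out_lengths[2L]
  rows <- list()
  add <- function(module, layer, shape)
    rows[[length(rows) + 1L]] <<- list(module = module, layer = layer,
                                       shape = shape)
  add(1L, "Input", c(H, L))
  add(1L, "Reshape", c(1L, H, L))
  add(1L, "Conv2D", c(f1, H, L))
  add(1L, "BatchNorm", c(f1, H, L))
  add(2L, "DepthwiseConv2D", c(f2, 1L, L))
  add(2L, "BatchNorm", c(f2, 1L, L))
  add(2L, "Activation", c(f2, 1L, L))
  if (!is.null(config$psa_psfe)) {
    add(2L, "PSA", c(f2, 1L, L))
    add(2L, "BatchNorm", c(f2, 1L, L))
    add(2L, "Activation", c(f2, 1L, L))
  }
  add(2L, "AveragePooling2D", c(f2, 1L, p1))
  add(2L, "Dropout", c(f2, 1L, p1))
  add(3L, "DepthwiseConv2D", c(f2, 1L, p1))
  if (!is.null(config$psa_dtfe)) add(3L, "PSA", c(f2, 1L, p1))
  add(3L, "PointwiseConv2D", c(f2, 1L, p1))
  add(3L, "BatchNorm", c(f2, 1L, p1))
  add(3L, "Activation", c(f2, 1L, p1))
  add(3L, "AveragePooling2D", c(f2, 1L, p2))
  add(3L, "Dropout", c(f2, 1L, p2))
  add(4L, "Flatten", f2 * p2)
  add(4L, "Linear", config$n_classes)
  add(4L, "Softmax", config$n_classes)
  out <- data.frame(
    module = vapply(rows, function(r) r$module, integer(1)),
    layer = vapply(rows, function(r) r$layer, character(1)),
    output = vapply(rows, function(r)
      if (length(r$shape) == 1L) as.character(r$shape)
      else paste0("(", paste(r$shape, collapse = ", "), ")"), character(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "shapes") <- lapply(rows, function(r) r$shape)
  out
}

#' Count trainable parameters
#'
#' Batch-norm running statistics are not trainable and are excluded.
#'
#' @param net A `psa_network`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(net) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) for (el in x) walk(el) else n <<- n + length(x)
  }
  walk(net$params)
  n
}

#' Save / load a network checkpoint
#'
#' A checkpoint is a single R serialization holding a format version, the
#' full configuration and every named parameter array plus batch-norm running
#' statistics, so a network reloads without re-specifying its configuration.
#'
#' @param net A `psa_network`.
#' @param path File path.
#' @return `load_network` returns the restored `psa_network`.
#' @export
save_network <- function(net, path) {
  saveRDS(list(format = "psaeegnet-checkpoint-1", config = net$config,
               params = net$params, running = net$running), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "psaeegnet-checkpoint-1"))
    stop("not a psaeegnet checkpoint: ", path)
  structure(list(config = obj$config, params = obj$params,
                 running = obj$running), class = "psa_network")
}
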