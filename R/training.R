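#' Training protocol configuration
#'
#' Defaults follow the reference protocol: Adam at learning rate 0.001
#' (moments 0.9/0.999, epsilon 1e-8), batch size 64, class-weighted
#' cross-entropy, the learning rate halved after 5 consecutive epochs without
#' a decrease in validation loss, early stopping after 20 such epochs with
#' restoration of the best-validation weights. The validation set is a
#' stratified 20% carve-out of the training data; test folds are never seen.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Hard epoch cap (early stopping usually fires first).
#' @param lr_factor,lr_patience Plateau schedule: multiply the rate by
#'   `lr_factor` after `lr_patience` consecutive non-improving epochs.
#' @param early_stop_patience Stop after this many consecutive non-improving
#'   epochs; must exceed `lr_patience`.
#' @param class_weighting `"balanced"` (weights inversely proportional to
#'   class frequency), `"none"`, or an explicit numeric pair
#'   `(w_nontarget, w_target)`.
#' @param seed Integer seed controlling the split, initial shuffling order and
#'   dropout; fits are bit-reproducible given the seed.
#' @param validation_fraction Stratified fraction of the training data held
#'   out to monitor validation loss (in (0, 0.5)).
#' @param min_delta Smallest decrease in validation loss that counts as an
#'   improvement.
#' @param lr_floor Lower bound on the learning rate.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         max_epochs = 500L, lr_factor = 0.5,
                         lr_patience = 5L, early_stop_patience = 20L,
                         class_weighting = "balanced", seed = 1L,
                         validation_fraction = 0.2, min_delta = 1e-5,
                         lr_floor = 1e-6) {
  if (lr_patience < 1L || early_stop_patience < 1L)
    stop("patience values must be >= 1")
  if (early_stop_patience <= lr_patience)
    stop("early_stop_patience must exceed lr_patience")
  if (validation_fraction <= 0 || validation_fraction >= 0.5)
    stop("validation_fraction must be in (0, 0.5)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 class_weighting = class_weighting, seed = seed,
                 validation_fraction = validation_fraction,
                 min_delta = min_delta, lr_floor = lr_floor),
            class = "train_config")
}

#' Balanced class weights
#'
#' `w_c = n_total / (2 n_c)`: inversely proportional to class frequency,
#' averaging 1 when the classes are balanced.
#'
#' @param labels 0/1 label vector containing both classes.
#' @return Numeric pair `(w_nontarget, w_target)`.
#' @export
class_weights <- function(labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n0 == 0L || n1 == 0L)
    stop("class weights require both classes to be present")
  n <- n0 + n1
  c(n / (2 * n0), n / (2 * n1))
}

#' Class-weighted cross-entropy
#'
#' Mean over trials of `-w[y_i] log p_i(y_i)`, with the probability floored
#' at 1e-12 inside the logarithm.
#'
#' @param probs Matrix `(trials, 2)` of class probabilities, column 1 the
#'   non-target class.
#' @param labels 0/1 vector.
#' @param weights Numeric pair of class weights (default unweighted).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, weights = c(1, 1)) {
  p_true <- probs[cbind(seq_along(labels), labels + 1L)]
  mean(-weights[labels + 1L] * log(pmax(p_true, 1e-12)))
}

## ---- plateau learning-rate schedule with early stopping ----

#' Plateau scheduler state machine
#'
#' `plateau_scheduler()` creates the state; `scheduler_step()` feeds it one
#' validation loss per epoch. An improvement is a strict decrease by more
#' than `min_delta` over the best loss so far. After `lr_patience`
#' consecutive non-improving epochs the rate is multiplied by `factor`
#' (never below `lr_floor`) and the plateau counter restarts; after
#' `stop_patience` such epochs `stop` is set. The learning-rate trajectory is
#' therefore non-increasing and piecewise constant.
#'
#' @param lr Initial learning rate.
#' @param factor,lr_patience,stop_patience,min_delta,lr_floor See
#'   [train_config()].
#' @return A scheduler state list; `scheduler_step` returns it updated with
#'   fields `lr`, `epoch`, `best`, `best_epoch`, `improved`, `halved`,
#'   `stop`.
#' @export
plateau_scheduler <- function(lr, factor = 0.5, lr_patience = 5L,
                              stop_patience = 20L, min_delta = 1e-5,
                              lr_floor = 1e-6) {
  list(lr = lr, factor = factor, lr_patience = lr_patience,
       stop_patience = stop_patience, min_delta = min_delta,
       lr_floor = lr_floor, best = Inf, best_epoch = 0L, epoch = 0L,
       stale = 0L, stale_lr = 0L, improved = FALSE, halved = FALSE,
       stop = FALSE)
}

#' @rdname plateau_scheduler
#' @param state Scheduler state.
#' @param val_loss Validation loss of the epoch just finished.
#' @export
scheduler_step <- function(state, val_loss) {
  state$epoch <- state$epoch + 1L
  state$halved <- FALSE
  if (val_loss < state$best - state$min_delta) {
    state$best <- val_loss
    state$best_epoch <- state$epoch
    state$stale <- 0L
    state$stale_lr <- 0L
    state$improved <- TRUE
  } else {
    state$stale <- state$stale + 1L
    state$stale_lr <- state$stale_lr + 1L
    state$improved <- FALSE
    if (state$stale_lr >= state$lr_patience) {
      new_lr <- max(state$lr * state$factor, state$lr_floor)
      state$halved <- new_lr < state$lr
      state$lr <- new_lr
      state$stale_lr <- 0L
    }
    if (state$stale >= state$stop_patience) state$stop <- TRUE
  }
  state
}

## ---- parameter tree <-> flat vector (for the optimizer) ----

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  i <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- flat[(i + 1L):(i + n)]
    i <<- i + n
    attributes(out) <- attributes(s)
    out
  }
  rec(skeleton)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

## ---- the fitting loop ----

#' Fit a PSAEEGNet network
#'
#' Implements the full optimization protocol: a stratified validation
#' carve-out for monitoring, Adam on class-weighted cross-entropy, per-epoch
#' reshuffled mini-batches, plateau learning-rate halving, early stopping and
#' best-weight restoration. A trailing mini-batch of size 1 is dropped
#' (training-mode batch normalization needs at least 2 trials).
#'
#' @param net A [build_network()] network.
#' @param epochs An [epoch_set()] or `(trials, channels, samples)` array.
#' @param labels 0/1 labels (taken from the epoch set when omitted).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return The trained network with elements `history` (data frame: epoch,
#'   train_loss, val_loss, lr), `best_epoch` and `class_weights` added.
#' @export
fit_network <- function(net, epochs, labels = NULL, config = train_config(),
                        verbose = FALSE) {
  if (inherits(epochs, "epoch_set")) {
    if (is.null(labels)) labels <- epochs$labels
    epochs <- epochs$epochs
  }
  labels <- as.integer(labels)
  n <- dim(epochs)[1L]
  if (length(labels) != n) stop("labels length must match trial count")
  if (!all(c(0L, 1L) %in% labels))
    stop("training requires at least one trial of each class")
  if (!is.null(config$seed)) set.seed(config$seed)

  w <- switch(as.character(config$class_weighting[1L]),
              balanced = class_weights(labels),
              none = c(1, 1),
              as.numeric(config$class_weighting))
  if (length(w) != 2L || any(!is.finite(w)))
    stop("class_weighting must be 'balanced', 'none' or two numeric weights")

  ## stratified validation carve-out
  val_idx <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(config$validation_fraction * length(idx)))
    if (n_val >= length(idx))
      stop("class ", cl, " too small for a stratified validation split")
    sample(idx, n_val)
  }))
  train_idx <- setdiff(seq_len(n), val_idx)
  if (!all(c(0L, 1L) %in% labels[train_idx]))
    stop("training portion lost a class during the validation split")
  x_val <- epochs[val_idx, , , drop = FALSE]
  y_val <- labels[val_idx]

  theta <- flatten_params(net$params)
  skeleton <- net$params
  opt <- adam_init(length(theta))
  sched <- plateau_scheduler(config$learning_rate, config$lr_factor,
                             config$lr_patience, config$early_stop_patience,
                             config$min_delta, config$lr_floor)
  best <- list(params = net$params, running = net$running,
               val = Inf, epoch = 0L)
  history <- list()

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    starts <- seq(1L, length(ord), by = config$batch_size)
    losses <- numeric(0)
    for (s in starts) {
      bi <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      if (length(bi) < 2L) next
      xb <- epochs[bi, , , drop = FALSE]
      yb <- labels[bi]
      fw <- network_forward(net, xb, mode = "train", want_cache = TRUE)
      net$running <- fw$running
      probs <- fw$probs                                 # (B, 2)
      losses <- c(losses, weighted_cross_entropy(probs, yb, w))
      # d(mean -w_y log p_y)/dlogits = w_y (p - onehot) / B
      onehot <- matrix(0, 2L, length(bi))
      onehot[cbind(yb + 1L, seq_along(bi))] <- 1
      dlogits <- (t(probs) - onehot) *
        rep(w[yb + 1L] / length(bi), each = 2L)
      grads <- network_backward(net, dlogits, fw$cache)
      grads <- grads[names(skeleton)]
      gflat <- flatten_params(grads)
      stopifnot(length(gflat) == length(theta))
      upd <- adam_step(theta, gflat, opt, sched$lr)
      theta <- upd$theta
      opt <- upd$state
      net$params <- unflatten_params(theta, skeleton)
    }
    val_probs <- network_forward(net, x_val, mode = "eval")
    val_loss <- weighted_cross_entropy(val_probs, y_val, w)
    sched <- scheduler_step(sched, val_loss)
    if (sched$improved)
      best <- list(params = net$params, running = net$running,
                   val = val_loss, epoch = epoch)
    history[[epoch]] <- c(epoch = epoch, train_loss = mean(losses),
                          val_loss = val_loss, lr = sched$lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2g",
                      epoch, mean(losses), val_loss, sched$lr))
    if (sched$stop) break
  }

  net$params <- best$params
  net$running <- best$running
  net$history <- as.data.frame(do.call(rbind, history))
  net$best_epoch <- best$epoch
  net$class_weights <- w
  net
}

## ---- the modelling interface ----

#' Fit PSAEEGNet to labelled single-trial epochs
#'
#' The top-level modelling function: builds the configured network
#' (seed-controlled initialization) and trains it with the reference
#' protocol. Returns a fitted model with the usual methods
#' ([predict.psaeegnet()], `print`, `summary`, `coef`, `plot`,
#' `fitted`, `residuals`).
#'
#' @param x An [epoch_set()] or `(trials, channels, samples)` array.
#' @param y 0/1 labels; taken from the epoch set when omitted.
#' @param network A [network_config()]; geometry must match `x`.
#' @param training A [train_config()].
#' @param variant Optional [ablation_spec()] applied to `network`.
#' @param verbose Print per-epoch progress.
#' @param keep_fitted Compute resubstitution probabilities for the training
#'   set (`fitted`, `residuals`, `summary`); disable to skip one full
#'   forward pass when only `predict` on new data is needed.
#' @return Object of class `psaeegnet`.
#' @export
psaeegnet <- function(x, y = NULL, network = NULL,
                      training = train_config(), variant = NULL,
                      verbose = FALSE, keep_fitted = TRUE) {
  if (inherits(x, "epoch_set")) {
    if (is.null(y)) y <- x$labels
    epochs <- x$epochs
  } else epochs <- x
  d <- dim(epochs)
  if (is.null(network))
    network <- network_config(n_channels = d[2L], n_samples = d[3L])
  if (!is.null(variant)) network <- apply_ablation(network, variant)
  if (!is.null(training$seed)) set.seed(training$seed)
  net <- build_network(network)
  net <- fit_network(net, epochs, y, training, verbose = verbose)
  fitted_probs <- if (keep_fitted) network_forward(net, epochs, mode = "eval")
                  else NULL
  structure(list(net = net, config = network, training = training,
                 variant = variant, labels = as.integer(y),
                 fitted = fitted_probs, call = match.call()),
            class = "psaeegnet")
}

#' Predict from a fitted PSAEEGNet
#'
#' @param object A [psaeegnet()] fit.
#' @param newdata An [epoch_set()] or epoch array; defaults to the training
#'   epochs' fitted values.
#' @param type `"prob"` (matrix of class probabilities), `"score"`
#'   (target-class probability vector) or `"class"` (0/1 at threshold 0.5).
#' @param ... Unused.
#' @export
predict.psaeegnet <- function(object, newdata = NULL,
                              type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata) && is.null(object$fitted))
    stop("model was fitted with keep_fitted = FALSE; supply newdata")
  probs <- if (is.null(newdata)) object$fitted
           else network_forward(object$net, newdata, mode = "eval")
  switch(type,
         prob = probs,
         score = probs[, 2L],
         class = as.integer(probs[, 2L] > 0.5))
}

#' @export
fitted.psaeegnet <- function(object, ...) object$fitted[, 2L]

#' @export
residuals.psaeegnet <- function(object, ...) {
  object$labels - object$fitted[, 2L]
}

#' @export
coef.psaeegnet <- function(object, ...) object$net$params

#' @export
print.psaeegnet <- function(x, ...) {
  cfg <- x$config
  cat("PSAEEGNet fit:", cfg$n_channels, "channels x", cfg$n_samples,
      "samples,", parameter_count(x$net), "parameters\n")
  cat("  PSA blocks:",
      if (is.null(cfg$psa_psfe)) "-" else
        paste0("(", paste(cfg$psa_psfe$kernel_sizes, collapse = ","), ")"),
      "/",
      if (is.null(cfg$psa_dtfe)) "-" else
        paste0("(", paste(cfg$psa_dtfe$kernel_sizes, collapse = ","), ")"),
      "\n")
  h <- x$net$history
  cat("  trained", nrow(h), "epochs; best validation loss",
      format(min(h$val_loss), digits = 5), "at epoch", x$net$best_epoch, "\n")
  invisible(x)
}

#' @export
summary.psaeegnet <- function(object, ...) {
  scored <- scored_predictions(object$fitted[, 2L], object$labels)
  rep <- evaluate_scores(scored)
  out <- list(fit = object, train_metrics = rep)
  class(out) <- "summary.psaeegnet"
  out
}

#' @export
print.summary.psaeegnet <- function(x, ...) {
  print(x$fit)
  cat("Training-set metrics (resubstitution; use run_cv() for honest ones):\n")
  print(x$train_metrics)
  invisible(x)
}

#' @export
plot.psaeegnet <- function(x, ...) {
  h <- x$net$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "weighted cross-entropy", ...)
  graphics::abline(v = x$net$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
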