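test_that("class_weights follows the balanced inverse-frequency formula", {
  expect_equal(class_weights(rep(c(0L, 1L), 25)), c(1, 1))
  expect_equal(class_weights(c(rep(0L, 90), rep(1L, 10))),
               c(100 / 180, 100 / 20))
  expect_error(class_weights(rep(1L, 10)), "both classes")
})

test_that("weighting raises the loss of an all-majority predictor on imbalanced data", {
  set.seed(61)
  labels <- rbinom(400, 1L, 0.05)
  labels[1] <- 1L
  # a predictor that always calls the majority class with 90% confidence
  probs <- matrix(rep(c(0.9, 0.1), each = 400), ncol = 2)
  w <- class_weights(labels)
  expect_gt(weighted_cross_entropy(probs, labels, w),
            weighted_cross_entropy(probs, labels))
})

test_that("weighted_cross_entropy reproduces hand arithmetic", {
  perfect <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)[, 2:1]
  expect_lte(weighted_cross_entropy(cbind(c(1, 0), c(0, 1)), c(0L, 1L)),
             1e-10)
  uniform <- matrix(0.5, 4, 2)
  expect_equal(weighted_cross_entropy(uniform, c(0L, 1L, 0L, 1L)), log(2))

  set.seed(62)
  probs <- t(apply(matrix(runif(10), 5), 1, function(r) r / sum(r)))
  y <- c(0L, 1L, 1L, 0L, 1L)
  w <- c(0.7, 2.1)
  manual <- mean(sapply(1:5, function(i) -w[y[i] + 1] * log(probs[i, y[i] + 1])))
  expect_equal(weighted_cross_entropy(probs, y, w), manual, tolerance = 1e-12)
})

test_that("plateau scheduler halves after 5 stale epochs and stops after 20", {
  st <- plateau_scheduler(0.001, 0.5, 5L, 20L)
  lrs <- numeric(0)
  stopped_at <- NA
  for (e in 1:30) {
    st <- scheduler_step(st, 1.0)       # constant validation loss
    lrs[e] <- st$lr
    if (st$stop) { stopped_at <- e; break }
  }
  # best is epoch 1; first halving lands at epoch 6 = lr_patience + 1
  expect_equal(lrs[5], 0.001)
  expect_equal(lrs[6], 0.0005)
  expect_equal(lrs[10], 0.0005)
  expect_equal(lrs[11], 0.00025)
  # training stops 20 epochs after the best epoch: history length 21
  expect_equal(stopped_at, 21)
  # trajectory is non-increasing, drops are exact halvings
  expect_true(all(diff(lrs[1:21]) <= 0))
  drops <- which(diff(lrs) < 0) + 1L
  expect_true(all(lrs[drops] == lrs[drops - 1L] / 2))
})

test_that("scheduler respects the learning-rate floor and strict-improvement rule", {
  st <- plateau_scheduler(4e-6, 0.5, 2L, 8L, lr_floor = 1e-6)
  for (e in 1:8) st <- scheduler_step(st, 1.0)
  expect_gte(st$lr, 1e-6)
  # sub-min_delta decreases do not count as improvement
  st2 <- plateau_scheduler(0.001, 0.5, 2L, 4L, min_delta = 1e-5)
  st2 <- scheduler_step(st2, 0.5)
  st2 <- scheduler_step(st2, 0.5 - 1e-6)
  expect_false(st2$improved)
  st2 <- scheduler_step(st2, 0.4)
  expect_true(st2$improved)
  expect_equal(st2$best_epoch, 3L)
})

test_that("fit_network learns separable data and restores the best epoch", {
  es <- tiny_epochs(n = 120, amplitude = 3, seed = 63)
  set.seed(64)
  net <- build_network(tiny_network_config())
  tc <- train_config(batch_size = 16L, max_epochs = 30L, seed = 65)
  fit <- fit_network(net, es, config = tc)
  h <- fit$history
  expect_lte(nrow(h), 30L)
  expect_equal(min(h$val_loss), h$val_loss[fit$best_epoch])
  # learning-rate column is non-increasing
  expect_true(all(diff(h$lr) <= 0))
  # resubstitution separation on clearly separable data
  probs <- network_forward(fit, es$epochs)
  a <- auc(scored_predictions(probs[, 2], es$labels))
  expect_gte(a, 0.95)
})

test_that("fits are bit-reproducible given the seed", {
  es <- tiny_epochs(n = 60, amplitude = 2, seed = 66)
  tc <- train_config(batch_size = 16L, max_epochs = 4L, seed = 67)
  fit1 <- psaeegnet(es, training = tc)
  fit2 <- psaeegnet(es, training = tc)
  expect_identical(psaeegnet:::flatten_params(fit1$net$params),
                   psaeegnet:::flatten_params(fit2$net$params))
  expect_identical(fit1$net$history, fit2$net$history)
  # a different seed changes the fit
  fit3 <- psaeegnet(es, training = train_config(batch_size = 16L,
                                                max_epochs = 4L, seed = 68))
  expect_false(identical(psaeegnet:::flatten_params(fit1$net$params),
                         psaeegnet:::flatten_params(fit3$net$params)))
})

test_that("fit_network validates labels and degenerate splits", {
  es <- tiny_epochs(n = 20, seed = 69)
  net <- build_network(tiny_network_config())
  expect_error(fit_network(net, es$epochs, rep(1L, 20)), "each class")
  expect_error(fit_network(net, es$epochs, es$labels[1:5]), "length")
  # a class with a single trial cannot be split stratified
  labs <- c(rep(0L, 19), 1L)
  expect_error(fit_network(net, es$epochs, labs, train_config()),
               "stratified")
})

test_that("the model object supports the standard methods", {
  es <- tiny_epochs(n = 50, amplitude = 3, seed = 70)
  fit <- psaeegnet(es, training = train_config(batch_size = 16L,
                                               max_epochs = 5L, seed = 71))
  expect_s3_class(fit, "psaeegnet")
  expect_output(print(fit), "PSAEEGNet fit")
  expect_output(print(summary(fit)), "Metrics report")
  expect_type(coef(fit), "list")
  p <- predict(fit, es$epochs[1:4, , , drop = FALSE])
  expect_equal(dim(p), c(4L, 2L))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-9)
  cls <- predict(fit, es$epochs[1:4, , , drop = FALSE], type = "class")
  expect_true(all(cls %in% c(0L, 1L)))
  expect_length(fitted(fit), 50L)
  expect_equal(residuals(fit), es$labels - fitted(fit), tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
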