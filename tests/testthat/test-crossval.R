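test_that("stratified folds are disjoint, covering and class-balanced to +/- 1", {
  labels <- c(rep(1L, 20), rep(0L, 80))
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  expect_length(folds, 5L)
  test_sets <- lapply(folds, `[[`, "test")
  # exact coverage and disjointness by set algebra
  expect_identical(sort(unlist(test_sets)), 1:100)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(test_sets[[i]], test_sets[[j]]), 0L)
  # 20 positives / 5 folds divide exactly
  pos_counts <- sapply(test_sets, function(ts) sum(labels[ts]))
  expect_true(all(pos_counts == 4L))
  neg_counts <- sapply(test_sets, function(ts) sum(labels[ts] == 0L))
  expect_true(all(neg_counts == 16L))
  # train/test complementarity
  for (f in folds)
    expect_identical(sort(c(f$train, f$test)), 1:100)
})

test_that("splits are deterministic per seed and warn in the pigeonhole case", {
  labels <- rbinom(1000, 1L, 0.05)
  f1 <- stratified_kfold(labels, 5, seed = 9)
  f2 <- stratified_kfold(labels, 5, seed = 9)
  expect_identical(f1, f2)
  f3 <- stratified_kfold(labels, 5, seed = 10)
  expect_false(identical(f1, f3))

  sparse <- c(rep(1L, 4), rep(0L, 96))
  expect_warning(folds <- stratified_kfold(sparse, 5, seed = 2),
                 "fewer positives")
  pos_counts <- sort(sapply(folds, function(f) sum(sparse[f$test])))
  expect_identical(pos_counts, c(0L, 1L, 1L, 1L, 1L))

  expect_error(stratified_kfold(c(0L, 1L), k = 5), "exceeds")
})

test_that("run_cv produces per-fold reports without leakage", {
  es <- tiny_epochs(n = 40, amplitude = 3, seed = 80)
  tc <- train_config(batch_size = 8L, max_epochs = 3L, seed = 81)
  res <- run_cv(es, tiny_network_config(), tc, k = 2, seed = 82)
  expect_s3_class(res, "cv_result")
  expect_length(res$reports, 2L)
  for (r in res$reports) {
    expect_s3_class(r, "metrics_report")
    expect_true(r$acc >= 0 && r$acc <= 1)
  }
  expect_equal(res$summary$n_folds, rep(2L, 5))
  expect_output(print(res), "Cross-validation")
})

test_that("the aggregate mean is the arithmetic mean of fold metrics", {
  es <- tiny_epochs(n = 40, amplitude = 3, seed = 83)
  tc <- train_config(batch_size = 8L, max_epochs = 2L, seed = 84)
  res <- run_cv(es, tiny_network_config(), tc, k = 2, seed = 85)
  for (m in c("acc", "tpr", "fpr", "f1", "auc")) {
    v <- sapply(res$reports, `[[`, m)
    expect_equal(res$summary$mean[res$summary$metric == m],
                 mean(v, na.rm = TRUE), tolerance = 1e-12)
  }
})

test_that("aggregate_cv reproduces hand-computed cross-subject statistics", {
  mk <- function(vals, variant = "v") {
    reports <- lapply(vals, function(v) {
      r <- list(acc = v, tpr = v, fpr = v, f1 = v, auc = v)
      class(r) <- "metrics_report"
      r
    })
    structure(list(variant = variant, reports = reports,
                   summary = psaeegnet:::summarize_reports(reports),
                   notes = character(0)),
              class = "cv_result")
  }
  one <- aggregate_cv(mk(c(0.6, 0.8)))
  expect_true(all(one$mean == 0.7))

  two <- aggregate_cv(list(mk(c(0.6, 0.8)), mk(c(0.4, 0.6))))
  acc_row <- two[two$metric == "acc", ]
  expect_equal(acc_row$mean, mean(c(0.7, 0.5)))
  expect_equal(acc_row$sd, sd(c(0.7, 0.5)))
  expect_equal(acc_row$n_subjects, 2L)

  expect_error(aggregate_cv(list()), "no results")
})

test_that("undefined AUC folds are excluded with a note, not zeroed", {
  reports <- lapply(c(0.9, NA, 0.7), function(v) {
    r <- list(acc = 0.8, tpr = 0.5, fpr = 0.1, f1 = 0.4, auc = v)
    class(r) <- "metrics_report"
    r
  })
  s <- psaeegnet:::summarize_reports(reports)
  auc_row <- s[s$metric == "auc", ]
  expect_equal(auc_row$mean, 0.8)
  expect_equal(auc_row$n_folds, 2L)
  expect_equal(s$n_folds[s$metric == "acc"], 3L)
})

test_that("ablation variants share byte-identical folds and pair deterministically", {
  es <- tiny_epochs(n = 36, amplitude = 2, seed = 86)
  tc <- train_config(batch_size = 8L, max_epochs = 1L, seed = 87)
  res <- run_ablation(es, list(ablation_spec("EEGNet"),
                               ablation_spec("EEGNet"),
                               ablation_spec("0+A", "B")),
                      tiny_network_config(), tc, k = 2, seed = 88)
  expect_length(res, 3L)
  # byte-identical folds across variants
  expect_identical(res[[1]]$folds, res[[2]]$folds)
  expect_identical(res[[1]]$folds, res[[3]]$folds)
  # identical variant listed twice gives identical metric rows
  t1 <- cv_metrics_table(list(res[[1]]))
  t2 <- cv_metrics_table(list(res[[2]]))
  expect_identical(t1$value, t2$value)
  expect_error(run_ablation(es, list()), "no variants")
})

test_that("cv_metrics_table exports tidy long-format rows", {
  es <- tiny_epochs(n = 30, amplitude = 2, seed = 89)
  tc <- train_config(batch_size = 8L, max_epochs = 1L, seed = 90)
  res <- run_cv(es, tiny_network_config(), tc, k = 2, seed = 91)
  tab <- cv_metrics_table(res)
  expect_identical(names(tab),
                   c("subject", "variant", "fold", "metric", "value"))
  expect_equal(nrow(tab), 2L * 5L)
})
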