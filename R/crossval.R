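#' Stratified k-fold splits
#'
#' Shuffles each class separately (seeded) and deals trials round-robin to
#' folds, so per-fold class counts differ by at most one within each class:
#' stratification is exact up to integer rounding. Folds are disjoint and
#' cover every trial exactly once as test.
#'
#' @param labels 0/1 vector.
#' @param k Number of folds (default 5).
#' @param seed RNG seed making the split deterministic.
#' @return List of `k` fold splits, each with `fold`, `train` and `test`
#'   index vectors.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("k (", k, ") exceeds the number of trials (", n, ")")
  if (sum(labels == 1L) < k)
    warning("fewer positives (", sum(labels == 1L), ") than folds (", k,
            "); some folds will lack positives")
  set.seed(seed)
  assign_fold <- integer(n)
  for (cl in c(0L, 1L)) {
    idx <- sample(which(labels == cl))
    if (length(idx))
      assign_fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f)
    list(fold = f, train = which(assign_fold != f),
         test = which(assign_fold == f)))
}

#' Per-subject stratified cross-validation
#'
#' For each fold: fit on the training portion (which internally carves out
#' its own stratified validation sub-split; the test fold is never touched
#' during fitting), score the test fold in eval mode, and compute the metric
#' suite. A test fold containing a single class gets `NA` AUC, which is
#' excluded from the AUC mean with a logged note.
#'
#' @param epochs An [epoch_set()].
#' @param net_config A [network_config()] (default built from the epoch
#'   geometry).
#' @param train_cfg A [train_config()].
#' @param k Number of folds.
#' @param seed Seed for the fold split (the fit seed comes from `train_cfg`).
#' @param folds Optional precomputed [stratified_kfold()] splits (used by
#'   [run_ablation()] so variants share byte-identical folds).
#' @param variant Optional variant label stored in the result.
#' @return Object of class `cv_result`: per-fold reports, a per-metric
#'   summary (mean, sd, n folds used) and the fold definitions.
#' @export
run_cv <- function(epochs, net_config = NULL, train_cfg = train_config(),
                   k = 5L, seed = 1L, folds = NULL, variant = "default") {
  stopifnot(inherits(epochs, "epoch_set"))
  labels <- epochs$labels
  if (is.null(folds)) folds <- stratified_kfold(labels, k, seed)
  d <- dim(epochs$epochs)
  if (is.null(net_config))
    net_config <- network_config(n_channels = d[2L], n_samples = d[3L])

  reports <- vector("list", length(folds))
  notes <- character(0)
  for (fs in folds) {
    stopifnot(length(intersect(fs$train, fs$test)) == 0L)   # no leakage
    fit <- psaeegnet(epochs$epochs[fs$train, , , drop = FALSE],
                     labels[fs$train], network = net_config,
                     training = train_cfg, keep_fitted = FALSE)
    scores <- predict(fit, epochs$epochs[fs$test, , , drop = FALSE],
                      type = "score")
    y_test <- labels[fs$test]
    sp <- scored_predictions(scores, y_test)
    counts <- confusion(sp)
    bm <- basic_metrics(counts)
    a <- if (length(unique(y_test)) == 2L) auc(sp) else {
      notes <- c(notes, paste0("fold ", fs$fold,
                               ": single-class test fold, AUC undefined"))
      NA_real_
    }
    reports[[fs$fold]] <- structure(
      c(bm, list(auc = a, counts = counts, threshold = sp$threshold,
                 tie_policy = "half")),
      class = "metrics_report")
  }
  structure(list(variant = variant, folds = folds, reports = reports,
                 summary = summarize_reports(reports), notes = notes),
            class = "cv_result")
}

# Mean/sd per metric over folds, NA metrics excluded with their count
# reported.
summarize_reports <- function(reports) {
  metrics <- c("acc", "tpr", "fpr", "f1", "auc")
  do.call(rbind, lapply(metrics, function(m) {
    v <- vapply(reports, function(r) r[[m]], numeric(1))
    ok <- !is.na(v)
    data.frame(metric = m, mean = mean(v[ok]),
               sd = if (sum(ok) > 1L) stats::sd(v[ok]) else NA_real_,
               n_folds = sum(ok))
  }))
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation (", length(x$reports), " folds), variant ",
      x$variant, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Paired ablation sweep
#'
#' Runs [run_cv()] once per variant on byte-identical fold splits (one
#' shared seed), so variant comparisons are paired.
#'
#' @param epochs An [epoch_set()].
#' @param variants List of [ablation_spec()]s (or a character vector of
#'   variant names).
#' @param net_config,train_cfg,k,seed As in [run_cv()].
#' @return Named list of `cv_result`s, one per variant, class
#'   `ablation_table`.
#' @export
run_ablation <- function(epochs, variants, net_config = NULL,
                         train_cfg = train_config(), k = 5L, seed = 1L) {
  if (length(variants) == 0L) stop("no variants given")
  if (is.character(variants))
    variants <- lapply(variants, ablation_spec)
  d <- dim(epochs$epochs)
  if (is.null(net_config))
    net_config <- network_config(n_channels = d[2L], n_samples = d[3L])
  folds <- stratified_kfold(epochs$labels, k, seed)
  out <- lapply(variants, function(v) {
    label <- paste0(v$name, if (!is.null(v$second_psa_kernels) &&
                                !is.null(apply_ablation(net_config, v)$psa_dtfe))
      paste0(" [", v$second_psa_kernels, "]") else "")
    run_cv(epochs, apply_ablation(net_config, v), train_cfg,
           folds = folds, variant = label)
  })
  names(out) <- vapply(out, function(r) r$variant, character(1))
  class(out) <- "ablation_table"
  out
}

#' @export
print.ablation_table <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Aggregate cross-validation results across subjects
#'
#' Computes, per variant and metric, the cross-subject mean and standard
#' deviation of the per-subject fold means (the usual "mean +/- sd over
#' subjects" reporting). Metrics undefined in every fold of a subject are
#' excluded with their count reported.
#'
#' @param results List of `cv_result`s (one per subject) sharing a variant
#'   label, or a plain list of them.
#' @return Data frame `variant, metric, mean, sd, n_subjects`.
#' @export
aggregate_cv <- function(results) {
  if (inherits(results, "cv_result")) results <- list(results)
  if (length(results) == 0L) stop("no results to aggregate")
  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    s <- results[[i]]$summary
    s$variant <- results[[i]]$variant
    s$subject <- i
    s
  }))
  out <- do.call(rbind, lapply(split(rows, rows[c("variant", "metric")]),
                               function(g) {
    ok <- g$n_folds > 0L & !is.na(g$mean)
    data.frame(variant = g$variant[1L], metric = g$metric[1L],
               mean = mean(g$mean[ok]),
               sd = if (sum(ok) > 1L) stats::sd(g$mean[ok]) else NA_real_,
               n_subjects = sum(ok))
  }))
  rownames(out) <- NULL
  out
}

#' Tidy per-fold metric table
#'
#' Long-format export (`subject, variant, fold, metric, value`) suitable for
#' CSV serialization or external statistical testing.
#'
#' @param results A `cv_result`, an `ablation_table`, or a list of
#'   `cv_result`s (interpreted as subjects).
#' @return Data frame in long format.
#' @export
cv_metrics_table <- function(results) {
  if (inherits(results, "cv_result")) results <- list(results)
  metrics <- c("acc", "tpr", "fpr", "f1", "auc")
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    do.call(rbind, lapply(seq_along(r$reports), function(f)
      data.frame(subject = i, variant = r$variant, fold = f,
                 metric = metrics,
                 value = vapply(metrics, function(m) r$reports[[f]][[m]],
                                numeric(1)),
                 row.names = NULL)))
  }))
}
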