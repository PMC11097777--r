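# Epoch-file round trips, config files, and result export.

#' Save / load an epoch set
#'
#' Epoch files use R's native serialization (datasets `epochs`, `labels`,
#' attribute `sampling_rate`, format version tag) with an optional JSON
#' sidecar describing provenance; they round-trip bit-exactly.
#'
#' @param x An [epoch_set()].
#' @param path Destination file.
#' @param sidecar Optional list (e.g. a [sim_config()]) written as
#'   `<path>.json`.
#' @return `load_epochs` returns the restored [epoch_set()].
#' @export
save_epochs <- function(x, path, sidecar = NULL) {
  stopifnot(inherits(x, "epoch_set"))
  saveRDS(list(format = "psaeegnet-epochs-1", epochs = x$epochs,
               labels = x$labels, sampling_rate = x$sampling_rate), path)
  if (!is.null(sidecar))
    jsonlite::write_json(unclass(sidecar), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "psaeegnet-epochs-1"))
    stop("not a psaeegnet epoch file: ", path)
  epoch_set(obj$epochs, obj$labels, obj$sampling_rate)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized blocks: `preprocessing` (`keep_channels`, `band_hz`,
#' `filter_order`, `window_ms`), `network` (`temporal_filters`,
#' `temporal_kernel`, `depth_multiplier`, `separable_kernel`, `pool_size`,
#' `dropout`, `psa_psfe.kernels`, `psa_dtfe.kernels`, `variant`), `training`
#' (fields of [train_config()]), `crossval` (`k`, `seed`, `variants`) and
#' `simulate` (fields of [sim_config()]). Missing blocks get defaults.
#'
#' @param path YAML file.
#' @return List with elements `preprocessing`, `network`, `training`,
#'   `crossval`, `simulate`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  pre <- raw$preprocessing
  preprocessing <- list(
    keep_channels = pre$keep_channels %||% default_keep_channels(),
    filter = filter_spec(low_hz = (pre$band_hz %||% c(2, 30))[1L],
                         high_hz = (pre$band_hz %||% c(2, 30))[2L],
                         order = pre$filter_order %||% 4L),
    window_ms = pre$window_ms %||% c(0, 1000)
  )

  nw <- raw$network
  f1 <- nw$temporal_filters %||% 8L
  dm <- nw$depth_multiplier %||% 2L
  f2 <- f1 * dm
  psa1 <- if (!is.null(nw$psa_psfe) && isFALSE(nw$psa_psfe$enabled)) NULL
          else psa_config(f2, unlist(nw$psa_psfe$kernels %||% psa_kernel_sets$A))
  psa2 <- if (!is.null(nw$psa_dtfe) && isFALSE(nw$psa_dtfe$enabled)) NULL
          else psa_config(f2, unlist(nw$psa_dtfe$kernels %||% psa_kernel_sets$B))
  network <- network_config(
    n_channels = nw$n_channels %||% 62L,
    n_samples = nw$n_samples %||% 250L,
    temporal_filters = f1,
    temporal_kernel = nw$temporal_kernel %||% 125L,
    depth_multiplier = dm,
    separable_kernel = nw$separable_kernel %||% 16L,
    pool_size = nw$pool_size %||% 8L,
    dropout_p = nw$dropout %||% 0.5,
    psa_psfe = psa1, psa_dtfe = psa2)
  if (!is.null(nw$variant))
    network <- apply_ablation(network, ablation_spec(nw$variant,
      nw$second_psa_kernels %||% "B"))

  tr <- raw$training %||% list()
  training <- do.call(train_config,
                      tr[intersect(names(tr), names(formals(train_config)))])

  cv <- raw$crossval
  crossval <- list(k = cv$k %||% 5L, seed = cv$seed %||% 1L,
                   variants = cv$variants)

  sm <- raw$simulate %||% list()
  simulate <- do.call(sim_config,
                      sm[intersect(names(sm), names(formals(sim_config)))])

  list(preprocessing = preprocessing, network = network,
       training = training, crossval = crossval, simulate = simulate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a metrics report to JSON / CSV row
#'
#' @param report A [evaluate_scores()] report.
#' @param subject,fold,variant Provenance columns.
#' @return One-row data frame `subject, fold, variant, acc, tpr, fpr, f1,
#'   auc`.
#' @export
report_row <- function(report, subject = 1L, fold = 1L,
                       variant = "default") {
  data.frame(subject = subject, fold = fold, variant = variant,
             acc = report$acc, tpr = report$tpr, fpr = report$fpr,
             f1 = report$f1, auc = report$auc)
}

# Run manifest: one JSON per artifact-producing command.
write_manifest <- function(path, command, config, seed, inputs = character(0),
                           outputs = character(0), status = "ok") {
  digest_file <- function(f)
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("psaeegnet")),
    seed = seed,
    config = config,
    inputs = if (length(inputs))
      stats::setNames(lapply(inputs, digest_file), inputs) else list(),
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = status)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
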