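# End-to-end orchestration: simulate a two-block session, extract the
# configured features (train-block statistics applied to the test block),
# train decoders on block 1, evaluate on block 2, and summarise quality.

.feature_kinds <- c("lf_mwp", "mf_mwp", "hf_mwp", "tc", "lfp", "mua")

#' Session experiment configuration
#'
#' A fully serializable description of one simulated session run: the task,
#' array size, feature kinds, simulation / extraction / decoder parameters
#' and the master seed. Persisting a config (see [write_run_config()])
#' reproduces the run bit-identically.
#'
#' @param task_id `"Task1"` or `"Task2"`.
#' @param n_channels Array size (default 96).
#' @param features Feature kinds to extract and decode (default all six).
#' @param day_index Chronic day index (default 0).
#' @param seed Master seed (default 1).
#' @param sim Named list of [simulation_params()] overrides.
#' @param extraction Named list of [feature_config()] overrides.
#' @param decoder Named list: `cost`, `gamma` (see [train_decoders()]).
#' @param lag Labeling lag in s (default 0).
#' @param quality Also compute an SNR summary of block 1 (default TRUE).
#' @return An object of class `run_config`.
#' @export
run_config <- function(task_id = "Task2", n_channels = 96,
                       features = .feature_kinds, day_index = 0, seed = 1,
                       sim = list(), extraction = list(), decoder = list(),
                       lag = 0, quality = TRUE) {
  task_id <- match.arg(task_id, names(.task_movements))
  bad <- setdiff(features, .feature_kinds)
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  structure(list(task_id = task_id, n_channels = n_channels,
                 features = features, day_index = day_index, seed = seed,
                 sim = sim, extraction = extraction,
                 decoder = utils::modifyList(list(cost = 1, gamma = NULL),
                                             decoder),
                 lag = lag, quality = quality),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `path` (write) or a [run_config()] (read).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j[!vapply(j, is.null, logical(1))])
}

#' Run a full simulated session experiment
#'
#' Simulates two blocks of the configured task, extracts every configured
#' feature kind (standardization statistics fitted on block 1 and applied
#' unchanged to block 2), trains per-movement decoders on block 1, predicts
#' block 2, and computes decoding metrics per feature kind plus an SNR
#' summary of block 1. The three MWP bands share one wavelet decomposition
#' and one post-processing pass per block.
#'
#' @param config A [run_config()].
#' @return An object of class `session_report`: `metrics` (named list of
#'   [compute_metrics()] results per feature kind), `accuracy` (data frame
#'   `feature`, `overall_accuracy`), `quality` (SNR means of block 1 or
#'   `NULL`), plus the `config` and the two schedules.
#' @export
run_session_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  fcfg <- do.call(feature_config, config$extraction)
  params <- do.call(simulation_params,
                    utils::modifyList(list(n_channels = config$n_channels,
                                           seed = config$seed), config$sim))
  session <- simulate_session(config$task_id, n_blocks = 2,
                              day_index = config$day_index, params = params)
  b1 <- session[[1]]; b2 <- session[[2]]

  feats1 <- list(); feats2 <- list()
  mwp_bands <- sub("_mwp$", "", grep("_mwp$", config$features, value = TRUE))
  if (length(mwp_bands)) {
    map <- scale_band_map(b1$recording$fs, fcfg$n_scales)
    sc1 <- mwp_scale_series(b1$recording, fcfg)
    sc2 <- mwp_scale_series(b2$recording, fcfg)
    p1 <- .postprocess(sc1, fcfg, source_block = "block1")
    p2 <- .postprocess(sc2, fcfg, stats = p1$stats)
    for (band in mwp_bands) {
      kind <- paste0(band, "_mwp")
      feats1[[kind]] <- .feature_extract(combine_scales(p1$series, band, map),
                                         p1$stats,
                                         combine_scales(sc1, band, map), kind)
      feats2[[kind]] <- .feature_extract(combine_scales(p2$series, band, map),
                                         p1$stats,
                                         combine_scales(sc2, band, map), kind)
    }
  }
  tc1 <- NULL
  if ("tc" %in% config$features || isTRUE(config$quality))
    tc1 <- detect_threshold_crossings(b1$recording, fcfg)
  if ("tc" %in% config$features) {
    f1 <- tc_feature_series(tc1, fcfg)
    tc2 <- detect_threshold_crossings(b2$recording, fcfg)
    feats1$tc <- f1
    feats2$tc <- tc_feature_series(tc2, fcfg, stats = f1$stats)
  }
  if ("lfp" %in% config$features) {
    f1 <- extract_lfp(b1$recording, fcfg)
    feats1$lfp <- f1
    feats2$lfp <- extract_lfp(b2$recording, fcfg, stats = f1$stats)
  }
  if ("mua" %in% config$features) {
    f1 <- extract_mua(b1$recording, fcfg)
    feats1$mua <- f1
    feats2$mua <- extract_mua(b2$recording, fcfg, stats = f1$stats)
  }

  labels1 <- label_bins(b1$schedule, n_bins(feats1[[1]]$series),
                        fcfg$bin_width, config$lag)
  labels2 <- label_bins(b2$schedule, n_bins(feats2[[1]]$series),
                        fcfg$bin_width, config$lag)
  metrics <- list()
  for (kind in config$features) {
    bundle <- train_decoders(feats1[[kind]], labels1,
                             cost = config$decoder$cost,
                             gamma = config$decoder$gamma)
    metrics[[kind]] <- compute_metrics(predict(bundle, feats2[[kind]]),
                                       labels2)
  }
  accuracy <- data.frame(
    feature = config$features,
    overall_accuracy = vapply(metrics, function(m) m$overall_accuracy,
                              numeric(1)))
  qual <- if (isTRUE(config$quality))
    snr_summary(b1$recording, tc1, fcfg)$means else NULL
  structure(list(config = config, metrics = metrics, accuracy = accuracy,
                 quality = qual,
                 schedules = list(b1$schedule, b2$schedule),
                 features_block1 = feats1, features_block2 = feats2),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %s, %d channels, seed %s\n",
              x$config$task_id, x$config$n_channels, x$config$seed))
  acc <- x$accuracy[order(-x$accuracy$overall_accuracy), ]
  print(acc, row.names = FALSE, digits = 4)
  if (!is.null(x$quality))
    cat(sprintf("block-1 SNR %.2f dB, p2p %.1f uV, noise RMS %.1f uV\n",
                x$quality$snr_db, x$quality$p2p_uv, x$quality$rms_noise_uv))
  invisible(x)
}
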