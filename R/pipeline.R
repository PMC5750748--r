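# End-to-end orchestration: segments -> TFD -> 2D MRA -> features ->
# cross-validated classification -> report.

#' Time-frequency image of a segment at the analysis resolution
#'
#' Computes the quadratic TFD of the segment and resizes it (bilinear) to a
#' fixed square grid so decomposition shapes are independent of segment
#' length.
#'
#' @param seg An [eeg_segment()].
#' @param tfd_spec A [tfd_kernel()].
#' @param mra_size Side of the square analysis image (default 64).
#' @return Real `mra_size x mra_size` matrix.
#' @export
segment_tf_image <- function(seg, tfd_spec = tfd_kernel("swvd"), mra_size = 64) {
  tf <- compute_tfd(seg, tfd_spec)
  resize_image(tf$values, mra_size, mra_size)
}

features_from_tf <- function(img, method, n_gray_levels = 8) {
  switch(method,
    curvelet = curvelet_feature_vector(
      select_subbands(fdct_wrapping(img, n_scales = 5, n_angles_scale2 = 8)),
      n_gray_levels),
    wavelet2d = wavelet_feature_vector(dwt2(img, levels = 4), n_gray_levels),
    stop("unknown MRA method: ", method)
  )
}

#' Extract per-segment feature tables for one or more MRA methods
#'
#' Runs the TFD and (for the 2D methods) the multi-resolution decomposition
#' for every segment. When several methods are requested the TF image of
#' each segment is computed once and shared, which is how the method
#' comparison grid avoids recomputing the expensive stage.
#'
#' @param segments List of [eeg_segment()] (or a `labeled_dataset`).
#' @param methods Character vector from `"curvelet"`, `"wavelet2d"`,
#'   `"dwt1d"`.
#' @param tfd_spec A [tfd_kernel()] (ignored by `"dwt1d"`, which works on
#'   the raw segment).
#' @param mra_size Analysis image side (default 64).
#' @param n_gray_levels GLCM gray levels (default 8).
#' @return Named list of numeric feature matrices (rows = segments), one
#'   per method.
#' @export
extract_features <- function(segments, methods = "curvelet",
                             tfd_spec = tfd_kernel("swvd"),
                             mra_size = 64, n_gray_levels = 8) {
  if (inherits(segments, "labeled_dataset")) segments <- segments$segments
  methods <- match.arg(methods, c("curvelet", "wavelet2d", "dwt1d"),
                       several.ok = TRUE)
  need_tf <- intersect(methods, c("curvelet", "wavelet2d"))
  out <- lapply(methods, function(m) vector("list", length(segments)))
  names(out) <- methods
  for (i in seq_along(segments)) {
    if (length(need_tf) > 0) {
      img <- segment_tf_image(segments[[i]], tfd_spec, mra_size)
      for (m in need_tf) out[[m]][[i]] <- features_from_tf(img, m, n_gray_levels)
    }
    if ("dwt1d" %in% methods)
      out[["dwt1d"]][[i]] <- dwt1d_baseline_features(segments[[i]])
  }
  lapply(out, function(rows) do.call(rbind, rows))
}

#' Assemble a pipeline run configuration
#'
#' A flat, JSON-serializable record of every stage parameter. `synth = NULL`
#' with an `input_path` reads a recording from disk instead of generating
#' data.
#'
#' @param synth List of [synth_config()] overrides (empty list for
#'   defaults), or `NULL` when reading from `input_path`.
#' @param input_path,input_format,channel,labels_path Recording input
#'   (used when `synth` is `NULL`): file, format, channel, and a CSV of
#'   per-segment labels with a `label` column.
#' @param window_s Segment length in seconds.
#' @param highpass_hz High-pass cut-off applied to file-input recordings
#'   before segmentation (0 disables); synthetic trials are generated
#'   drift-free and are not filtered.
#' @param tfd_kind,window_len TFD kernel selection ([tfd_kernel()]);
#'   `window_len = NULL` means `floor(fs/4)`.
#' @param mra_method `"curvelet"`, `"wavelet2d"`, or `"dwt1d"`.
#' @param mra_size Analysis image side.
#' @param n_gray_levels GLCM gray levels.
#' @param model_kind,svm_c,svm_gamma Model selection ([model_spec()]).
#' @param k_folds CV folds.
#' @param pca_components Principal components kept before classification
#'   (0 = no PCA).
#' @param seed Seed for data generation and fold assignment.
#' @param out_dir Optional output directory for report files.
#' @return Object of class `run_config` (a named list).
#' @export
pipeline_config <- function(synth = list(), input_path = NULL,
                            input_format = "auto", channel = 1,
                            labels_path = NULL,
                            window_s = 1, highpass_hz = 0.5,
                            tfd_kind = "swvd", window_len = NULL,
                            mra_method = "curvelet", mra_size = 64,
                            n_gray_levels = 8,
                            model_kind = "svm_rbf", svm_c = 10,
                            svm_gamma = "auto",
                            k_folds = 10, pca_components = 0,
                            seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as JSON
#'
#' The JSON round-trip is lossless, so a report's embedded configuration
#' can be replayed exactly.
#'
#' @param cfg A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   restored `run_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config()
  for (nm in names(base)) {
    if (nm %in% names(cfg)) base[nm] <- list(cfg[[nm]])  # keeps NULL (file input)
  }
  if (!is.null(base$synth)) base$synth <- as.list(base$synth)
  base
}

pipeline_segments <- function(cfg) {
  if (!is.null(cfg$synth)) {
    sargs <- cfg$synth
    sargs$seed <- cfg$seed
    sc <- do.call(synth_config, sargs)
    ds <- synth_dataset(sc)
    # The high-pass stage removes slow electrode drift from continuous
    # recordings before segmentation; synthetic trials are generated
    # independently and drift-free, so the filter (whose time constant is
    # on the order of one trial) is not applied to them.
    list(segments = ds$segments, labels = ds$labels,
         participant_id = ds$participant_id)
  } else {
    rec <- read_signal(cfg$input_path, cfg$input_format, channel = cfg$channel)
    if (cfg$highpass_hz > 0) rec <- highpass_filter(rec, cfg$highpass_hz)
    segments <- make_segments(rec, cfg$channel, cfg$window_s)
    labels <- NULL
    if (!is.null(cfg$labels_path)) {
      lab <- read.csv(cfg$labels_path)
      labels <- factor(lab$label[seq_along(segments)])
    }
    list(segments = segments, labels = labels, participant_id = NULL)
  }
}

#' Run the full artifact-identification pipeline
#'
#' Executes data acquisition (synthetic or file), preprocessing, TFD,
#' multi-resolution feature extraction, optional PCA, and stratified k-fold
#' cross-validation, returning a report that embeds the exact configuration
#' used. If `cfg$out_dir` is set, writes `config.json`, `features.csv`,
#' `confusion.csv`, and `metrics.json` there.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages (default TRUE).
#' @return Object of class `pipeline_report`: `config`, `features`,
#'   `labels`, `cv` (a `cv_result`), `pca` (or `NULL`), `timings` (seconds
#'   per stage).
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()
  dat <- pipeline_segments(cfg)
  if (is.null(dat$labels)) stop("pipeline requires labelled segments")
  timings["data"] <- tic() - t0
  say("data: %d segments", length(dat$segments))

  t0 <- tic()
  spec <- tfd_kernel(cfg$tfd_kind, window_len = cfg$window_len)
  feats <- extract_features(dat$segments, cfg$mra_method, spec,
                            cfg$mra_size, cfg$n_gray_levels)[[cfg$mra_method]]
  timings["features"] <- tic() - t0
  say("features: %d x %d", nrow(feats), ncol(feats))

  pca <- NULL
  x <- feats
  if (cfg$pca_components > 0) {
    t0 <- tic()
    red <- pca_reduce(feats, cfg$pca_components)
    pca <- red$model
    x <- red$reduced
    timings["pca"] <- tic() - t0
  }

  t0 <- tic()
  model <- model_spec(cfg$model_kind, svm_c = cfg$svm_c,
                      svm_gamma = cfg$svm_gamma)
  cv <- run_cv(x, dat$labels, model, cfg$k_folds, seed = cfg$seed)
  timings["classify"] <- tic() - t0
  say("classify: accuracy %.2f%%", cv$total_accuracy)

  report <- structure(list(config = cfg, features = feats,
                           labels = dat$labels,
                           participant_id = dat$participant_id,
                           cv = cv, pca = pca, timings = timings),
                      class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_config(report$config, file.path(dir, "config.json"))
  df <- as.data.frame(report$features)
  df$label <- as.character(report$labels)
  write.csv(df, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(as.data.frame.matrix(report$cv$confusion),
            file.path(dir, "confusion.csv"))
  metrics <- list(
    total_accuracy = report$cv$total_accuracy,
    per_class_sensitivity = as.list(report$cv$per_class_sensitivity),
    per_class_specificity = as.list(report$cv$per_class_specificity),
    timings_s = as.list(report$timings))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s + %s + %s: accuracy %.2f%%\n",
              x$config$tfd_kind, x$config$mra_method, x$config$model_kind,
              x$cv$total_accuracy))
  invisible(x)
}

#' Compare MRA feature methods on one dataset
#'
#' Computes TF images once, extracts curvelet, 2D-wavelet, and (optionally)
#' 1D-DWT baseline features from the same segments, and cross-validates the
#' same model on each feature set.
#'
#' @param dataset A `labeled_dataset` (or list with `segments` and
#'   `labels`).
#' @param methods Feature methods to compare.
#' @param tfd_spec A [tfd_kernel()].
#' @param model A [model_spec()].
#' @param mra_size Analysis image side.
#' @param k_folds CV folds.
#' @param seed Fold seed.
#' @return List per method: `cv` (a `cv_result`) and `accuracy`.
#' @export
compare_mra_methods <- function(dataset,
                                methods = c("curvelet", "wavelet2d", "dwt1d"),
                                tfd_spec = tfd_kernel("swvd"),
                                model = model_spec("svm_rbf"),
                                mra_size = 64, k_folds = 10, seed = 1) {
  feats <- extract_features(dataset$segments, methods, tfd_spec, mra_size)
  lapply(feats, function(x) {
    cv <- run_cv(x, dataset$labels, model, k_folds, seed = seed)
    list(cv = cv, accuracy = cv$total_accuracy)
  })
}

#' Run an accuracy comparison grid
#'
#' Cross-validated accuracy for every combination of TFD kernel, MRA
#' feature method, and classifier on one dataset. Feature tables are
#' computed once per (kernel, method) pair and reused across classifiers,
#' and TF images are shared between the 2D methods.
#'
#' @param dataset A `labeled_dataset`.
#' @param tfd_kinds Character vector of [tfd_kernel()] kinds.
#' @param mra_methods Feature methods (`"curvelet"`, `"wavelet2d"`,
#'   `"dwt1d"`).
#' @param model_kinds Classifier kinds ([model_spec()]).
#' @param mra_size Analysis image side.
#' @param k_folds,seed Cross-validation settings.
#' @return Data frame with columns `tfd`, `mra`, `model`, `accuracy` (%).
#' @export
run_grid <- function(dataset, tfd_kinds = "swvd",
                     mra_methods = c("curvelet", "wavelet2d"),
                     model_kinds = "svm_rbf",
                     mra_size = 64, k_folds = 10, seed = 1) {
  rows <- list()
  for (tk in tfd_kinds) {
    feats <- extract_features(dataset$segments, mra_methods,
                              tfd_kernel(tk), mra_size)
    for (mm in mra_methods) for (mk in model_kinds) {
      cv <- run_cv(feats[[mm]], dataset$labels, model_spec(mk),
                   k_folds, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        tfd = tk, mra = mm, model = mk, accuracy = cv$total_accuracy)
    }
  }
  do.call(rbind, rows)
}
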