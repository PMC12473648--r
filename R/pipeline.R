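#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end pipeline. Written/read as YAML by the
#' command-line tools.
#'
#' @param window_length,stride,min_overlap_frames windowing settings.
#' @param gloria a [gloria_config()].
#' @param classifier a [classifier_config()].
#' @param fps frame rate assumed for PNG frame directories (containers would
#'   carry their own; the three public fall corpora use 18/25/30).
#' @param downscale optional integer factor by which frames are spatially
#'   downscaled (with anti-alias smoothing) before motion extraction.
#' @param grayscale collapse color input to luminance before extraction.
#' @param normalization window normalization method (see
#'   [normalize_windows()]).
#' @param threshold detection decision threshold.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_length = 150L, stride = window_length,
                            min_overlap_frames = 8L,
                            gloria = gloria_config(),
                            classifier = classifier_config(window_length = window_length),
                            fps = 25, downscale = NULL, grayscale = FALSE,
                            normalization = "per_channel_z",
                            threshold = 0.5, seed = 1L) {
  structure(list(window_length = as.integer(window_length),
                 stride = as.integer(stride),
                 min_overlap_frames = as.integer(min_overlap_frames),
                 gloria = gloria, classifier = classifier, fps = fps,
                 downscale = downscale, grayscale = isTRUE(grayscale),
                 normalization = normalization, threshold = threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  digest::digest(unclass(config), algo = "md5")
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[gloriafall %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Read a video as a list of frames
#'
#' Reads a directory of PNG frames (lexicographic order = temporal order)
#' into `[0, 1]` intensity arrays. AVI/MP4 containers are not decodable in
#' this environment; decode them to PNG frames externally first.
#'
#' @param path directory of `.png` files.
#' @param grayscale collapse color to Rec.601 luminance.
#' @param downscale optional integer downscale factor.
#' @param fps frame rate to attach (PNG directories carry none).
#' @return list with `frames` (list of arrays), `fps`, `n_frames`.
#' @export
read_video <- function(path, grayscale = FALSE, downscale = NULL, fps = 25) {
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      stop("container decoding (AVI/MP4) is unavailable; supply a PNG frame directory")
    }
    stop("video path does not exist: ", path)
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG frames found in ", path)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    if (grayscale && dim(img)[3] == 3L) {
      lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
      dim(lum) <- c(dim(lum), 1L)
      img <- lum
    }
    if (!is.null(downscale) && downscale > 1) img <- downscale_frame(img, downscale)
    img
  })
  list(frames = frames, fps = fps, n_frames = length(frames))
}

downscale_frame <- function(frame, factor) {
  factor <- as.integer(factor)
  sm <- gauss_blur_frame(frame, factor / 2)
  rows <- seq(1L, dim(frame)[1], by = factor)
  cols <- seq(1L, dim(frame)[2], by = factor)
  sm[rows, cols, , drop = FALSE]
}

#' Write frames as a PNG directory
#'
#' @param frames list of frames with values in `[0, 1]` (clipped).
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    f <- pmin(pmax(frames[[i]], 0), 1)
    if (dim(f)[3] == 1L) f <- f[, , 1]
    png::writePNG(f, file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}

#' Extract per-pair motion parameters from a video to CSV
#'
#' One row per consecutive frame pair: 0-based pair index, the six motion
#' parameters, the condition number and the residual RMS.
#'
#' @param video path to a PNG frame directory, or a `read_video()` result.
#' @param out optional CSV path; when `NULL` the data frame is only returned.
#' @param config a [pipeline_config()].
#' @return the motion data frame, invisibly when written.
#' @export
cmd_extract <- function(video, out = NULL, config = pipeline_config()) {
  vid <- if (is.character(video)) {
    read_video(video, grayscale = config$grayscale,
               downscale = config$downscale, fps = config$fps)
  } else video
  ms <- motion_sequence(vid$frames, config$gloria)
  df <- data.frame(pair = seq_along(ms) - 1L,
                   t(motion_matrix(ms)),
                   condition_number = vapply(ms, attr, numeric(1), "condition_number"),
                   residual_rms = vapply(ms, attr, numeric(1), "residual_rms"))
  if (!is.null(out)) {
    utils::write.csv(df, out, row.names = FALSE)
    pipeline_log("extract: %d pairs -> %s (config %s)", nrow(df), out,
                 config_fingerprint(config))
    return(invisible(df))
  }
  df
}

motion_df_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as_motion_params(as.numeric(df[i, PARAM_NAMES])))
}

#' Train a fall classifier from labeled windows
#'
#' Stratified, seeded 90/10 split; the classifier trains on the 90% and the
#' returned report evaluates the held-out 10%. Normalization statistics are
#' computed on the training split only and stored with the model.
#'
#' @param data either a window-CSV path (see [write_windows_csv()]) or a
#'   list with `windows` and `labels`.
#' @param architecture `"cnn"` or `"cnn_bilstm"`.
#' @param config a [pipeline_config()].
#' @param model_out optional RDS path for the trained model artifact.
#' @param report_out optional JSON path for the held-out evaluation report.
#' @param verbose print training progress.
#' @return list with `model` (trained), `report` (held-out
#'   [evaluation_report()]) and `split` (the index sets).
#' @export
cmd_train <- function(data, architecture = c("cnn", "cnn_bilstm"),
                      config = pipeline_config(), model_out = NULL,
                      report_out = NULL, verbose = FALSE) {
  architecture <- match.arg(architecture)
  if (is.character(data)) data <- read_windows_csv(data)
  arr <- windows_array(data$windows)
  labels <- factor(as.character(data$labels), levels = CLASS_LEVELS)
  if (length(unique(labels)) < 2L) stop("training data must contain both classes")
  n <- dim(arr)[3]

  split <- with_seed(config$seed, {
    test_idx <- integer(0)
    for (cl in CLASS_LEVELS) {
      cl_idx <- which(labels == cl)
      n_test <- max(1L, round(length(cl_idx) * 0.1))
      test_idx <- c(test_idx, sample(cl_idx, n_test))
    }
    test_idx <- sort(test_idx)
    list(train = setdiff(seq_len(n), test_idx), test = test_idx)
  })

  train_w <- arr[, , split$train, drop = FALSE]
  norm <- config$normalization
  if (norm != "none") {
    train_w <- normalize_windows(train_w, norm)
    stats <- attr(train_w, "norm_stats")
  } else stats <- NULL

  ccfg <- config$classifier
  ccfg$architecture <- architecture
  ccfg$window_length <- dim(arr)[2]
  ccfg$seed <- config$seed
  model <- build_model(ccfg)
  model <- train_classifier(model, train_w, labels[split$train], verbose = verbose)
  if (!is.null(stats)) model$norm_stats <- stats

  test_w <- arr[, , split$test, drop = FALSE]
  pred <- predict(model, test_w, threshold = config$threshold)
  report <- evaluation_report(labels[split$test], pred$probabilities[, "fall"],
                              threshold = config$threshold)
  if (!is.null(model_out)) {
    saveRDS(model, model_out)
    pipeline_log("train: model (%s, %d params, seed %d) -> %s", architecture,
                 count_parameters(model), config$seed, model_out)
  }
  if (!is.null(report_out)) {
    jsonlite::write_json(report_to_list(report), report_out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(model = model, report = report, split = split)
}

#' Detect fall events in a video
#'
#' Extraction, windowing, normalization with the model's stored training
#' statistics, and classification; windows whose fall probability reaches the
#' threshold are emitted as detection events with frame indices and
#' timestamps.
#'
#' @param video PNG frame directory or `read_video()` result.
#' @param model a trained `gloria_model` or an RDS path to one.
#' @param config a [pipeline_config()].
#' @param threshold decision threshold (default from config).
#' @param out optional JSON output path.
#' @return data frame of events: `start_frame`, `end_frame` (0-based frame
#'   indices of the window span), `probability`, `t_start`, `t_end`
#'   (seconds).
#' @export
cmd_detect <- function(video, model, config = pipeline_config(),
                       threshold = config$threshold, out = NULL) {
  if (is.character(model)) model <- readRDS(model)
  stopifnot(inherits(model, "gloria_model"), model$trained)
  if (model$input_shape[2] != config$window_length) {
    stop(sprintf("model expects windows of length %d but config requests %d",
                 model$input_shape[2], config$window_length))
  }
  vid <- if (is.character(video)) {
    read_video(video, grayscale = config$grayscale,
               downscale = config$downscale, fps = config$fps)
  } else video
  ms <- motion_sequence(vid$frames, config$gloria)
  windows <- make_windows(ms, config$window_length, config$stride)
  arr <- windows_array(windows)
  pred <- predict(model, arr, threshold = threshold)
  p_fall <- pred$probabilities[, "fall"]
  hit <- pred$labels == "fall"
  starts <- vapply(windows, function(w) w$start_frame, numeric(1))
  events <- data.frame(start_frame = starts[hit],
                       end_frame = starts[hit] + config$window_length,
                       probability = p_fall[hit])
  events$t_start <- events$start_frame / vid$fps
  events$t_end <- events$end_frame / vid$fps
  if (!is.null(out)) {
    jsonlite::write_json(events, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pipeline_log("detect: %d event(s) -> %s", nrow(events), out)
  }
  events
}

#' Evaluate predictions against ground truth
#'
#' @param pred fall probabilities (numeric vector), or a data frame with a
#'   `probability` column, or a CSV/JSON path to one.
#' @param truth binary labels aligned with `pred` (vector or CSV path with a
#'   `label` column).
#' @param threshold decision threshold.
#' @param out optional JSON path for the report.
#' @return an [evaluation_report()].
#' @export
cmd_evaluate <- function(pred, truth, threshold = 0.5, out = NULL) {
  if (is.character(pred)) {
    pred <- if (grepl("\\.json$", pred)) jsonlite::read_json(pred, simplifyVector = TRUE)
            else utils::read.csv(pred)
  }
  if (is.data.frame(pred)) pred <- pred$probability
  if (is.character(truth)) truth <- utils::read.csv(truth)$label
  report <- evaluation_report(truth, as.numeric(pred), threshold)
  if (!is.null(out)) {
    jsonlite::write_json(report_to_list(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

#' Generate synthetic fixtures from the command line
#'
#' Writes a labeled window set as CSV and, optionally, a rendered synthetic
#' video as a PNG frame directory.
#'
#' @param n_windows number of windows to simulate.
#' @param out_csv window CSV path.
#' @param video_dir optional PNG directory for a rendered sequence.
#' @param video_frames length of the rendered sequence (frames).
#' @param seed integer seed.
#' @return `out_csv`, invisibly.
#' @export
cmd_simulate <- function(n_windows = 100L, out_csv = "windows.csv",
                         video_dir = NULL, video_frames = 151L, seed = 1L) {
  ds <- simulate_motion_dataset(motion_dataset_spec(n_windows, seed = seed))
  write_windows_csv(ds$windows, out_csv, ds$labels)
  if (!is.null(video_dir)) {
    sched <- simulate_motion_schedule(video_frames - 1L,
                                      onsets = max(1L, (video_frames - 1L) %/% 2L),
                                      seed = seed)
    seq <- render_sequence(scene_spec(96, 96, schedule = sched$schedule,
                                      texture_seed = seed))
    write_frames(seq$frames, video_dir)
  }
  invisible(out_csv)
}
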