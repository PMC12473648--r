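#' Cut a motion sequence into fixed-length windows
#'
#' Splits the per-pair motion vectors into `6 x window_length` windows — the
#' classifier's input unit. A window holds `window_length` motion *vectors*
#' (drawn from `window_length + 1` frames), so 151 frames yield exactly one
#' 6 x 150 window. Windows start at 0, `stride`, `2 * stride`, ...; the
#' default stride equals the window length (non-overlapping subdivisions) and
#' any trailing remainder shorter than one window is dropped.
#'
#' @param seq a list of [motion_params()] or a 6 x T matrix.
#' @param window_length vectors per window (default 150, minimum 16).
#' @param stride step between window starts (default `window_length`).
#' @return list of `motion_window` objects: each has `values` (6 x N matrix),
#'   `start_frame` (0-based index of its first frame pair) and `label`
#'   (`NA` until [label_windows()] assigns one).
#' @export
make_windows <- function(seq, window_length = 150L, stride = window_length) {
  m <- motion_matrix(seq)
  window_length <- as.integer(window_length); stride <- as.integer(stride)
  if (window_length < 16L) stop("window_length must be at least 16")
  if (stride < 1L) stop("stride must be positive")
  n <- ncol(m)
  if (n < window_length) {
    stop(sprintf("sequence of %d motion vectors is shorter than one window (%d)",
                 n, window_length))
  }
  starts <- seq.int(0L, n - window_length, by = stride)
  lapply(starts, function(s) {
    structure(list(values = m[, (s + 1L):(s + window_length), drop = FALSE],
                   start_frame = s, label = NA_character_),
              class = "motion_window")
  })
}

#' Fall-interval annotation
#'
#' @param intervals a 2-column matrix or data frame of `(start_frame,
#'   end_frame)` pairs, 0-based half-open, in frame indices; may be empty.
#' @return object of class `fall_annotation`.
#' @export
fall_annotation <- function(intervals = NULL) {
  if (is.null(intervals) || NROW(intervals) == 0L) {
    m <- matrix(numeric(0), ncol = 2)
  } else {
    m <- as.matrix(intervals)[, 1:2, drop = FALSE]
  }
  colnames(m) <- c("start", "end")
  if (nrow(m) > 0) {
    if (any(m[, 1] >= m[, 2])) stop("annotation intervals must satisfy start < end")
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2])) {
      stop("annotation intervals must be non-overlapping")
    }
  }
  structure(list(intervals = m), class = "fall_annotation")
}

#' Label windows from fall-interval annotations
#'
#' A window spanning frame pairs `[start, start + N)` is labeled `fall` iff
#' its span overlaps any annotated interval by at least `min_overlap_frames`
#' frames; otherwise `no_fall`.
#'
#' @param windows output of [make_windows()].
#' @param annotation a [fall_annotation()].
#' @param min_overlap_frames minimum overlap to count as a fall (default 8).
#' @return the windows with `label` filled in.
#' @export
label_windows <- function(windows, annotation, min_overlap_frames = 8L) {
  stopifnot(inherits(annotation, "fall_annotation"))
  iv <- annotation$intervals
  lapply(windows, function(w) {
    n <- ncol(w$values)
    w_start <- w$start_frame; w_end <- w$start_frame + n
    overlap <- 0
    if (nrow(iv) > 0) {
      overlap <- max(pmax(0, pmin(w_end, iv[, 2]) - pmax(w_start, iv[, 1])))
    }
    w$label <- if (overlap >= min_overlap_frames) "fall" else "no_fall"
    w
  })
}

#' Stack a window list into a 6 x N x n array
#'
#' @param windows list of `motion_window` objects (or an array already).
#' @return `6 x N x n_windows` numeric array.
#' @export
windows_array <- function(windows) {
  if (is.array(windows) && length(dim(windows)) == 3L) return(windows)
  stopifnot(length(windows) > 0)
  n <- ncol(windows[[1]]$values)
  arr <- array(0, c(6, n, length(windows)))
  for (i in seq_along(windows)) arr[, , i] <- windows[[i]]$values
  dimnames(arr) <- list(PARAM_NAMES, NULL, NULL)
  arr
}

window_labels <- function(windows) {
  factor(vapply(windows, function(w) w$label, character(1)), levels = CLASS_LEVELS)
}

#' Per-channel statistics of a window set
#'
#' @param windows window list or 6 x N x n array.
#' @return list with `mean` and `sd`, length-6 each (one entry per motion
#'   parameter channel).
#' @export
window_stats <- function(windows) {
  arr <- windows_array(windows)
  mean6 <- apply(arr, 1, mean)
  sd6 <- apply(arr, 1, stats::sd)
  list(mean = mean6, sd = sd6)
}

#' Normalize motion windows with training-set statistics
#'
#' Standardization must use *training-set* statistics only — pass the `stats`
#' computed on the training windows when transforming validation or test
#' data, otherwise information leaks across the split.
#'
#' @param windows window list or 6 x N x n array.
#' @param method `"none"` (identity), `"per_channel_z"` (per-channel
#'   standardization) or `"global_scale"` (divide all channels by the global
#'   sd).
#' @param stats statistics from [window_stats()]; when `NULL` they are
#'   computed from `windows` (training-set case) and attached to the result
#'   as attribute `norm_stats`.
#' @return windows in the same container as the input, transformed; attribute
#'   `norm_stats` records the statistics and method used.
#' @export
normalize_windows <- function(windows, method = c("per_channel_z", "none", "global_scale"),
                              stats = NULL) {
  method <- match.arg(method)
  if (method == "none") return(windows)
  is_list <- !is.array(windows)
  arr <- windows_array(windows)
  if (is.null(stats)) stats <- window_stats(arr)
  if (method == "per_channel_z") {
    if (any(stats$sd <= 0)) {
      stop("zero-variance channel: per-channel standardization undefined")
    }
    for (ch in 1:6) arr[ch, , ] <- (arr[ch, , ] - stats$mean[ch]) / stats$sd[ch]
  } else {
    g <- sqrt(mean(stats$sd^2))
    if (g <= 0) stop("zero global variance: scaling undefined")
    arr <- arr / g
  }
  out <- if (is_list) {
    lapply(seq_along(windows), function(i) {
      w <- windows[[i]]; w$values <- arr[, , i]; w
    })
  } else arr
  attr(out, "norm_stats") <- c(stats, list(method = method))
  out
}

#' Write/read a labeled window set as CSV
#'
#' One row per window: the label, then the 6 x N values in row-major channel
#' order (channel 1's N values first).
#'
#' @param windows window list or array.
#' @param labels factor/character labels (`no_fall` / `fall`); when `NULL`,
#'   taken from the window list.
#' @param path output file.
#' @return `path`, invisibly (writer); list with `windows` array and `labels`
#'   (reader).
#' @export
write_windows_csv <- function(windows, path, labels = NULL) {
  arr <- windows_array(windows)
  if (is.null(labels)) labels <- window_labels(windows)
  n <- dim(arr)[3]
  flat <- t(vapply(seq_len(n), function(i) as.numeric(t(arr[, , i])),
                   numeric(6 * dim(arr)[2])))
  df <- data.frame(label = as.character(labels), flat, check.names = FALSE)
  names(df) <- c("label", paste0("v", seq_len(ncol(flat))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- factor(df$label, levels = CLASS_LEVELS)
  flat <- as.matrix(df[, -1, drop = FALSE])
  n_len <- ncol(flat) / 6
  if (n_len != floor(n_len)) stop("window CSV width is not a multiple of 6")
  arr <- array(0, c(6, n_len, nrow(flat)))
  for (i in seq_len(nrow(flat))) {
    arr[, , i] <- matrix(flat[i, ], nrow = 6, byrow = TRUE)
  }
  dimnames(arr) <- list(PARAM_NAMES, NULL, NULL)
  list(windows = arr, labels = labels)
}
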