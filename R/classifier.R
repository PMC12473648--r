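#' Configuration of the fall classifier
#'
#' Defaults follow the published training regime: Adam with learning rate
#' 0.001, mini-batches of 32, up to 16 epochs, L2 regularization 0.001, a
#' dense head of 64 units with dropout, softmax output over
#' \{no_fall, fall\}. Convolutions act along the time axis only (kernels of
#' height 1), preserving the six-parameter vertical structure of the
#' `6 x 150` input; the hybrid variant feeds the final feature maps' time
#' axis through a bidirectional LSTM before the dense head.
#'
#' @param architecture `"cnn"` or `"cnn_bilstm"`.
#' @param conv_blocks list of `c(filters, kernel_width, pool_width)` triples;
#'   `pool_width = 1` disables pooling for that block. The third block is
#'   optional (`use_third_block`).
#' @param use_third_block include the refinement block (default `TRUE`).
#' @param third_block the `c(filters, kernel_width, pool_width)` triple of the
#'   optional refinement block.
#' @param dense_units width of the dense head (default 64).
#' @param dropout_rate dropout probability in the head (default 0.5).
#' @param lstm_units hidden units per LSTM direction (default 64).
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size mini-batch size (default 32).
#' @param max_epochs training epoch cap (default 16).
#' @param l2_weight L2 penalty coefficient on weights (default 0.001).
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @param validation_fraction held-out fraction monitored during training
#'   (stratified; default 0.1, may be 0).
#' @param window_length expected window length (default 150).
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(architecture = c("cnn", "cnn_bilstm"),
                              conv_blocks = list(c(16, 7, 2), c(32, 5, 2)),
                              use_third_block = TRUE,
                              third_block = c(64, 3, 1),
                              dense_units = 64L,
                              dropout_rate = 0.5,
                              lstm_units = 64L,
                              learning_rate = 0.001,
                              batch_size = 32L,
                              max_epochs = 16L,
                              l2_weight = 0.001,
                              seed = 1L,
                              validation_fraction = 0.1,
                              window_length = 150L) {
  architecture <- match.arg(architecture)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(architecture = architecture, conv_blocks = conv_blocks,
                 use_third_block = isTRUE(use_third_block),
                 third_block = third_block,
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 lstm_units = as.integer(lstm_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 l2_weight = l2_weight, seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 window_length = as.integer(window_length)),
            class = "classifier_config")
}

#' Build an untrained fall classifier
#'
#' Assembles the layer stack for the chosen architecture and initializes its
#' parameters (seeded). Pooling configurations that would exhaust the time
#' axis are rejected at build time.
#'
#' @param config a [classifier_config()].
#' @return an object of class `gloria_model`.
#' @export
build_model <- function(config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  blocks <- config$conv_blocks
  if (config$use_third_block) blocks <- c(blocks, list(config$third_block))
  with_seed(config$seed, {
    layers <- list()
    T_cur <- config$window_length
    C_cur <- 1L
    for (bi in seq_along(blocks)) {
      bl <- blocks[[bi]]
      filters <- as.integer(bl[1]); k <- as.integer(bl[2]); p <- as.integer(bl[3])
      T_next <- T_cur - k + 1L
      if (T_next < 1L) {
        stop(sprintf("conv block %d (kernel %d) exhausts the time axis (length %d)",
                     bi, k, T_cur))
      }
      layers <- c(layers, list(make_conv_time(k, C_cur, filters),
                               make_batchnorm(filters),
                               nn_layer("relu")))
      T_cur <- T_next; C_cur <- filters
      if (p > 1L) {
        T_pool <- T_cur %/% p
        if (T_pool < 1L) {
          stop(sprintf("pooling in block %d exhausts the time axis", bi))
        }
        layers <- c(layers, list(nn_layer("pool_time", meta = list(p = p))))
        T_cur <- T_pool
      }
    }
    if (config$architecture == "cnn") {
      layers <- c(layers, list(nn_layer("flatten")))
      d_head <- 6L * T_cur * C_cur
    } else {
      # the BiLSTM is an *addition* to the stack: its last hidden states are
      # concatenated with the flattened conv features before the dense head
      bl <- make_bilstm(6L * C_cur, config$lstm_units)
      bl$type <- "flatten_bilstm"
      layers <- c(layers, list(bl))
      d_head <- 6L * T_cur * C_cur + 2L * config$lstm_units
    }
    layers <- c(layers,
                list(make_dense(d_head, config$dense_units),
                     nn_layer("relu"),
                     nn_layer("dropout", meta = list(rate = config$dropout_rate)),
                     make_dense(config$dense_units, 2L)))
    structure(list(config = config, layers = layers,
                   input_shape = c(6L, config$window_length),
                   classes = CLASS_LEVELS, trained = FALSE,
                   norm_stats = NULL, history = NULL),
              class = "gloria_model")
  })
}

#' Layer manifest of a model
#'
#' @param model a `gloria_model`.
#' @return data frame with one row per layer: type and trainable parameter
#'   count.
#' @export
model_manifest <- function(model) {
  data.frame(layer = seq_along(model$layers),
             type = vapply(model$layers, function(l) l$type, character(1)),
             n_params = vapply(model$layers, function(l) {
               sum(vapply(l$params, length, integer(1)))
             }, numeric(1)))
}

#' Number of trainable parameters
#' @param model a `gloria_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) nn_count_params(model$layers)

#' @export
print.gloria_model <- function(x, ...) {
  cat(sprintf("<gloria_model> %s, input 6 x %d, %d trainable parameters%s\n",
              x$config$architecture, x$config$window_length,
              count_parameters(x), if (x$trained) " (trained)" else ""))
  invisible(x)
}

check_windows_input <- function(model, windows) {
  arr <- windows_array(windows)
  d <- dim(arr)
  if (d[1] != 6L || d[2] != model$input_shape[2]) {
    stop(sprintf("window shape %d x %d does not match model input 6 x %d",
                 d[1], d[2], model$input_shape[2]))
  }
  arr
}

#' Train the fall classifier
#'
#' Minimizes softmax cross-entropy with an L2 weight penalty using Adam, on
#' shuffled mini-batches, for up to `max_epochs` epochs, monitoring a
#' stratified validation split each epoch. Fully seeded: two runs with the
#' same seed and inputs give identical parameters.
#'
#' @param model an untrained (or trained) `gloria_model` from [build_model()].
#' @param windows training windows: window list or `6 x N x n` array,
#'   normalized per [normalize_windows()] (any attached `norm_stats` are
#'   stored with the model so prediction-time inputs can be transformed
#'   identically).
#' @param labels factor/character labels (`no_fall` / `fall`); both classes
#'   must be present.
#' @param verbose print per-epoch progress.
#' @return the trained model, with `history` (per-epoch loss/accuracy).
#' @export
train_classifier <- function(model, windows, labels, verbose = FALSE) {
  stopifnot(inherits(model, "gloria_model"))
  cfg <- model$config
  arr <- check_windows_input(model, windows)
  ns <- attr(windows, "norm_stats")
  y <- factor(as.character(labels), levels = CLASS_LEVELS)
  if (anyNA(y)) stop("labels must be 'no_fall' or 'fall'")
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  n <- dim(arr)[3]
  if (length(y) != n) stop("length(labels) must equal the number of windows")
  y_int <- as.integer(y) - 1L  # 0 = no_fall, 1 = fall

  with_seed(cfg$seed + 1L, {
    # stratified validation split
    val_idx <- integer(0)
    if (cfg$validation_fraction > 0) {
      for (cl in 0:1) {
        cl_idx <- which(y_int == cl)
        n_val <- floor(length(cl_idx) * cfg$validation_fraction)
        if (n_val > 0) val_idx <- c(val_idx, sample(cl_idx, n_val))
      }
      val_idx <- sort(val_idx)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    layers <- model$layers
    state <- adam_init(layers)
    step <- 0L
    hist <- data.frame()
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        bidx <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        Xb <- arr[, , bidx, drop = FALSE]
        res <- nn_loss_grads(layers, Xb, y_int[bidx], l2 = cfg$l2_weight,
                             training = TRUE)
        if (!is.finite(res$loss)) {
          stop(sprintf("non-finite loss at epoch %d (batch starting %d); ",
                       epoch, b0),
               "inspect input scaling / learning rate")
        }
        layers <- res$layers
        step <- step + 1L
        upd <- adam_step(layers, res$grads, state, step, cfg$learning_rate)
        layers <- upd$layers; state <- upd$state
        ep_loss <- ep_loss + res$loss * length(bidx)
        ep_correct <- ep_correct + sum(max.col(res$probs) - 1L == y_int[bidx])
      }
      row <- data.frame(epoch = epoch,
                        train_loss = ep_loss / length(ord),
                        train_acc = ep_correct / length(ord),
                        val_loss = NA_real_, val_acc = NA_real_)
      if (length(val_idx) > 0) {
        ev <- nn_loss_grads_eval(layers, arr[, , val_idx, drop = FALSE], y_int[val_idx])
        row$val_loss <- ev$loss; row$val_acc <- ev$acc
      }
      hist <- rbind(hist, row)
      if (verbose) {
        message(sprintf("epoch %2d  loss %.4f  acc %.3f  val_acc %s", epoch,
                        row$train_loss, row$train_acc,
                        ifelse(is.na(row$val_acc), "-", sprintf("%.3f", row$val_acc))))
      }
    }
    model$layers <- layers
  })
  model$trained <- TRUE
  model$history <- hist
  if (!is.null(ns)) model$norm_stats <- ns
  model
}

# loss/accuracy without gradients, inference mode (running BN stats, no dropout)
nn_loss_grads_eval <- function(layers, X, y_int) {
  fwd <- nn_forward(layers, X, training = FALSE)
  probs <- softmax_rows(fwd$logits)
  p_true <- probs[cbind(seq_len(nrow(probs)), y_int + 1L)]
  list(loss = -mean(log(pmax(p_true, 1e-12))),
       acc = mean(max.col(probs) - 1L == y_int))
}

#' Predict fall probabilities for motion windows
#'
#' @param object a trained `gloria_model`.
#' @param windows window list or `6 x N x n` array. When the model stores
#'   normalization statistics and the input carries none, the stored
#'   transform is applied first.
#' @param threshold decision threshold on the fall probability (default 0.5).
#'   `threshold <= 0` labels everything `fall`; `threshold >= 1` labels
#'   nothing `fall` — useful for ROC sweeps.
#' @param ... unused.
#' @return list with `probabilities` (n x 2 matrix, columns `no_fall`,
#'   `fall`) and `labels` (factor).
#' @export
predict.gloria_model <- function(object, windows, threshold = 0.5, ...) {
  if (!is.null(object$norm_stats) && is.null(attr(windows, "norm_stats"))) {
    windows <- normalize_windows(windows, object$norm_stats$method,
                                 stats = object$norm_stats)
  }
  arr <- check_windows_input(object, windows)
  probs <- softmax_rows(nn_forward(object$layers, arr, training = FALSE)$logits)
  colnames(probs) <- CLASS_LEVELS
  p_fall <- probs[, "fall"]
  is_fall <- if (threshold <= 0) rep(TRUE, length(p_fall))
             else if (threshold >= 1) rep(FALSE, length(p_fall))
             else p_fall >= threshold
  list(probabilities = probs,
       labels = factor(ifelse(is_fall, "fall", "no_fall"), levels = CLASS_LEVELS))
}
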