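# Shared fixture builders. Everything is generated in code, seeded.

# small textured frame for solver tests
fixture_texture <- function(size = 64, seed = 7, n_channels = 1L, smooth = 2) {
  render_texture(scene_spec(size, size, n_channels = n_channels,
                            texture_seed = seed, texture_smoothness = smooth,
                            schedule = list(motion_params())))
}

# warp a texture by one pure-generator motion and return the pair
fixture_pair <- function(gen, amplitude, size = 64, seed = 7, n_channels = 1L) {
  pl <- list(amplitude); names(pl) <- gen
  spec <- scene_spec(size, size, n_channels = n_channels, texture_seed = seed,
                     schedule = list(do.call(motion_params, pl)))
  seq <- render_sequence(spec)
  list(a = seq$frames[[1]], b = seq$frames[[2]], truth = seq$truth[[1]])
}

# independent least-squares oracle: build the full design matrix of the
# linearized brightness-constancy system and solve via SVD pseudo-inverse
# (minimum-norm), never touching assemble_normal_system / solve_motion.
oracle_pinv_solve <- function(frame_a, frame_b, config = gloria_config()) {
  g <- spatial_gradients(frame_a, frame_b, config$smooth_sigma)
  h <- g$height; w <- g$width
  keep <- matrix(FALSE, h, w); keep[3:(h - 2), 3:(w - 2)] <- TRUE
  cx <- (w + 1) / 2; cy <- (h + 1) / 2; s <- max(h, w) / 2
  X <- matrix(rep((seq_len(w) - cx) / s, each = h), h, w)[keep]
  Y <- matrix(rep((seq_len(h) - cy) / s, times = w), h, w)[keep]
  D <- NULL; rhs <- NULL
  for (c in seq_len(g$n_channels)) {
    gx <- g$gx[, , c][keep]; gy <- g$gy[, , c][keep]
    D <- rbind(D, cbind(gx, gy, X * gx + Y * gy, Y * gx - X * gy,
                        X * gy, Y * gx))
    rhs <- c(rhs, -g$gt[, , c][keep])
  }
  sv <- svd(D)
  pos <- sv$d > max(sv$d) * 1e-10
  as.numeric(sv$v[, pos, drop = FALSE] %*%
               ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos]))
}

# sub-pixel horizontal shift between two single-channel frames by lag
# cross-correlation over a fixed interior region with parabolic peak
# interpolation (independent of the gradient-based solver)
oracle_xcorr_shift_x <- function(a, b) {
  A <- a[, , 1]; B <- b[, , 1]
  A <- A - mean(A); B <- B - mean(B)
  W <- ncol(A)
  xr <- 3:(W - 3)
  cc <- function(d) sum(B[, xr] * A[, xr - d])
  lags <- -2:2
  pk <- lags[which.max(vapply(lags, cc, numeric(1)))]
  y1 <- cc(pk - 1); y2 <- cc(pk); y3 <- cc(pk + 1)
  pk + 0.5 * (y1 - y3) / (y1 - 2 * y2 + y3)
}

# tiny, fast classifier config for unit tests (not the published regime)
tiny_classifier_config <- function(architecture = "cnn", seed = 1L,
                                   window_length = 30L) {
  classifier_config(architecture = architecture,
                    conv_blocks = list(c(8, 5, 2), c(12, 3, 2)),
                    use_third_block = FALSE,
                    dense_units = 16L, dropout_rate = 0.2, lstm_units = 6L,
                    max_epochs = 12L, batch_size = 16L, seed = seed,
                    validation_fraction = 0,
                    window_length = window_length)
}

tiny_dataset <- function(n = 60, window_length = 30L, seed = 5L) {
  simulate_motion_dataset(motion_dataset_spec(n, window_length = window_length,
                                              transient_duration = 6L,
                                              seed = seed))
}
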