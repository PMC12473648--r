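#' Coerce an object to a frame array
#'
#' A frame is an `H x W x Nc` numeric array of finite intensities (one image of
#' a video, grayscale or multi-channel). A plain matrix is promoted to a
#' single-channel frame.
#'
#' @param x numeric matrix (`H x W`) or array (`H x W x Nc`).
#' @param min_dim minimum allowed height/width in pixels.
#' @return an `H x W x Nc` array.
#' @export
as_frame <- function(x, min_dim = 8L) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x)) {
    stop("a frame must be a numeric H x W matrix or H x W x Nc array")
  }
  d <- dim(x)
  if (d[1] < min_dim || d[2] < min_dim) {
    stop(sprintf("frame dimensions %d x %d below the minimum of %d pixels",
                 d[1], d[2], min_dim))
  }
  if (!all(is.finite(x))) stop("frame contains non-finite values")
  x
}

frame_dims <- function(frame) {
  d <- dim(frame)
  list(h = d[1], w = d[2], nc = d[3])
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("frame shapes differ: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}

# Map out-of-range 1-based indices into 1..n under a boundary rule.
# "constant" clamps; callers that need true zero-fill must mask separately.
fold_index <- function(i, n, mode = c("reflect", "wrap", "constant")) {
  mode <- match.arg(mode)
  if (mode == "wrap") return(((i - 1L) %% n) + 1L)
  if (mode == "constant") return(pmin.int(pmax.int(i, 1L), n))
  if (n == 1L) return(rep.int(1L, length(i)))
  # reflect through the edge pixels: ... 3 2 |1 2 3 ... n| n-1 n-2 ...
  p <- (i - 1L) %% (2L * n - 2L)
  p <- ifelse(p >= n, 2L * n - 2L - p, p)
  p + 1L
}

# Separable Gaussian blur of a matrix with reflected boundaries.
gauss_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n_row <- nrow(m); n_col <- ncol(m)
  out <- matrix(0, n_row, n_col)
  for (d in -r:r) {  # along rows (vertical)
    out <- out + k[d + r + 1] * m[fold_index(seq_len(n_row) + d, n_row, "reflect"), , drop = FALSE]
  }
  m2 <- matrix(0, n_row, n_col)
  for (d in -r:r) {  # along columns (horizontal)
    m2 <- m2 + k[d + r + 1] * out[, fold_index(seq_len(n_col) + d, n_col, "reflect"), drop = FALSE]
  }
  m2
}

gauss_blur_frame <- function(frame, sigma) {
  if (sigma <= 0) return(frame)
  for (c in seq_len(dim(frame)[3])) {
    frame[, , c] <- gauss_blur_matrix(frame[, , c], sigma)
  }
  frame
}

# Bilinear sampling of one channel at fractional (row, col) positions.
# ys, xs are numeric vectors of equal length; returns a vector of samples.
bilinear_sample <- function(channel, ys, xs, mode = c("reflect", "wrap", "constant")) {
  mode <- match.arg(mode)
  n_row <- nrow(channel); n_col <- ncol(channel)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  iy0 <- fold_index(as.integer(y0), n_row, mode)
  iy1 <- fold_index(as.integer(y0) + 1L, n_row, mode)
  ix0 <- fold_index(as.integer(x0), n_col, mode)
  ix1 <- fold_index(as.integer(x0) + 1L, n_col, mode)
  v00 <- channel[cbind(iy0, ix0)]
  v01 <- channel[cbind(iy0, ix1)]
  v10 <- channel[cbind(iy1, ix0)]
  v11 <- channel[cbind(iy1, ix1)]
  if (mode == "constant") {
    in_y0 <- y0 >= 1 & y0 <= n_row;  in_y1 <- (y0 + 1) >= 1 & (y0 + 1) <= n_row
    in_x0 <- x0 >= 1 & x0 <= n_col;  in_x1 <- (x0 + 1) >= 1 & (x0 + 1) <= n_col
    v00 <- v00 * (in_y0 & in_x0); v01 <- v01 * (in_y0 & in_x1)
    v10 <- v10 * (in_y1 & in_x0); v11 <- v11 * (in_y1 & in_x1)
  }
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Catmull-Rom (cubic convolution, a = -0.5) sampling of one channel at
# fractional (row, col) positions. Exact on constant and linear fields and an
# order more accurate than bilinear on smooth textures, which keeps warp
# round-trip errors within the tolerances the recovery tests need.
cubic_sample <- function(channel, ys, xs, mode = c("reflect", "wrap", "constant")) {
  mode <- match.arg(mode)
  n_row <- nrow(channel); n_col <- ncol(channel)
  y0 <- floor(ys); x0 <- floor(xs)
  ty <- ys - y0; tx <- xs - x0
  wcat <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    list(-0.5 * t3 + t2 - 0.5 * t,
         1.5 * t3 - 2.5 * t2 + 1,
         -1.5 * t3 + 2 * t2 + 0.5 * t,
         0.5 * t3 - 0.5 * t2)
  }
  wy <- wcat(ty); wx <- wcat(tx)
  out <- numeric(length(ys))
  for (dy in -1:2) {
    iy_raw <- as.integer(y0) + dy
    iy <- fold_index(iy_raw, n_row, mode)
    my <- if (mode == "constant") (iy_raw >= 1 & iy_raw <= n_row) else TRUE
    for (dx in -1:2) {
      ix_raw <- as.integer(x0) + dx
      ix <- fold_index(ix_raw, n_col, mode)
      mx <- if (mode == "constant") (ix_raw >= 1 & ix_raw <= n_col) else TRUE
      out <- out + wy[[dy + 2]] * wx[[dx + 2]] * channel[cbind(iy, ix)] * my * mx
    }
  }
  out
}
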