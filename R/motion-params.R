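#' Construct a global motion parameter vector
#'
#' Holds the six amplitudes of the global linear non-homogeneous motion group
#' for one frame transition: translations (pixels/frame) and dilation,
#' rotation, shear1, shear2 (rates per frame in the normalized generator
#' frame). Solver diagnostics, when present, are kept as attributes.
#'
#' @param tx,ty translation rates, pixels per frame.
#' @param dilation,rotation,shear1,shear2 group rates per frame (normalized
#'   coordinates).
#' @param condition_number condition number of the 6x6 normal system.
#' @param residual_rms root-mean-square brightness-constancy residual.
#' @param degenerate logical; `TRUE` when the structural tensor had no usable
#'   image structure and the solve returned zeros.
#' @return an object of class `motion_params`: a named numeric 6-vector.
#' @export
motion_params <- function(tx = 0, ty = 0, dilation = 0, rotation = 0,
                          shear1 = 0, shear2 = 0,
                          condition_number = NA_real_,
                          residual_rms = NA_real_,
                          degenerate = FALSE) {
  a <- c(tx = tx, ty = ty, dilation = dilation, rotation = rotation,
         shear1 = shear1, shear2 = shear2)
  if (!all(is.finite(a))) stop("motion parameters must be finite")
  structure(a, class = "motion_params",
            condition_number = condition_number,
            residual_rms = residual_rms,
            degenerate = isTRUE(degenerate))
}

#' @export
print.motion_params <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  cat("Global motion parameters (per frame):\n")
  print(signif(v, 4))
  if (!is.na(attr(x, "condition_number"))) {
    cat(sprintf("  cond(S) = %.3g, residual RMS = %.3g%s\n",
                attr(x, "condition_number"), attr(x, "residual_rms"),
                if (isTRUE(attr(x, "degenerate"))) " [degenerate]" else ""))
  }
  invisible(x)
}

as_motion_params <- function(x) {
  if (inherits(x, "motion_params")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L) stop("a motion parameter vector has exactly 6 entries")
  do.call(motion_params, as.list(stats::setNames(x, PARAM_NAMES)))
}

#' Stack motion parameter vectors into a 6 x T matrix
#'
#' @param x a `motion_params` object, a list of them, or a 6 x T matrix.
#' @return numeric matrix with rows `tx, ty, dilation, rotation, shear1, shear2`.
#' @export
motion_matrix <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != 6L) stop("motion matrix must have 6 rows")
    rownames(x) <- PARAM_NAMES
    return(x)
  }
  if (inherits(x, "motion_params")) x <- list(x)
  m <- vapply(x, function(p) as.numeric(as_motion_params(p)), numeric(6))
  m <- matrix(m, nrow = 6L, dimnames = list(PARAM_NAMES, NULL))
  m
}
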