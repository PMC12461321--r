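#' Fit a feature/label normaliser
#'
#' Two transforms are supported besides the identity:
#' standardisation \eqn{z' = (z - \langle z\rangle)/s_z} and
#' log-standardisation \eqn{z' = (\log z - \langle\log z\rangle)/s_{\log z}}.
#' Because sigma-profile descriptors legitimately contain zeros (empty bins,
#' empty slots), the log transform operates on \eqn{z + 10^{-3}}: the small
#' buffer keeps zero entries finite without materially moving nonzero ones.
#'
#' Moments use the sample standard deviation (divisor \eqn{n-1}). A constant
#' dimension would have \eqn{s = 0}; its scale is substituted by 1 so the
#' dimension maps to exactly 0 instead of NaN.
#'
#' @param values Numeric vector or matrix (columns are dimensions).
#' @param mode `"none"`, `"standardize"` or `"log_standardize"`.
#' @param buffer Additive buffer used in log mode.
#' @return A `des_normalizer` with per-dimension `center` and `scale`.
#' @export
#' @examples
#' nz <- fit_normalizer(c(1, 2, 3), "standardize")
#' apply_normalizer(nz, c(1, 2, 3))   # -1 0 1
fit_normalizer <- function(values, mode = c("none", "standardize", "log_standardize"),
                           buffer = 1e-3) {
  mode <- match.arg(mode)
  x <- as.matrix(values)
  if (!length(x)) abort("cannot fit a normalizer on empty data.",
                        class = "desgp_validation_error")
  if (mode == "log_standardize") {
    if (any(x < 0, na.rm = TRUE)) {
      abort("log-standardization requires nonnegative data (zeros are buffered).",
            class = "desgp_domain_error")
    }
    x <- log(x + buffer)
  }
  if (mode == "none") {
    center <- rep(0, ncol(x))
    scale <- rep(1, ncol(x))
  } else {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  structure(
    list(mode = mode, center = center, scale = scale, buffer = buffer,
         d = ncol(x)),
    class = "des_normalizer"
  )
}

#' @rdname fit_normalizer
#' @param norm A fitted `des_normalizer`.
#' @export
apply_normalizer <- function(norm, values) {
  stopifnot(inherits(norm, "des_normalizer"))
  was_vec <- is.null(dim(values))
  x <- as.matrix(values)
  if (ncol(x) != norm$d) {
    if (was_vec && norm$d == 1L) x <- matrix(as.numeric(values), ncol = 1)
    else abort("dimension mismatch between normalizer and data.",
               class = "desgp_shape_error")
  }
  if (norm$mode == "log_standardize") {
    if (any(x < 0, na.rm = TRUE)) {
      abort("negative value given to a log-standardizing normalizer.",
            class = "desgp_domain_error")
    }
    x <- log(x + norm$buffer)
  }
  if (norm$mode != "none") {
    x <- sweep(sweep(x, 2, norm$center, "-"), 2, norm$scale, "/")
  }
  if (was_vec) drop(x) else x
}

#' @rdname fit_normalizer
#' @export
invert_normalizer <- function(norm, values) {
  stopifnot(inherits(norm, "des_normalizer"))
  was_vec <- is.null(dim(values))
  x <- as.matrix(values)
  if (ncol(x) != norm$d && was_vec && norm$d == 1L) {
    x <- matrix(as.numeric(values), ncol = 1)
  }
  if (norm$mode != "none") {
    x <- sweep(sweep(x, 2, norm$scale, "*"), 2, norm$center, "+")
  }
  if (norm$mode == "log_standardize") x <- exp(x) - norm$buffer
  if (was_vec) drop(x) else x
}

#' @export
print.des_normalizer <- function(x, ...) {
  cat(sprintf("<normalizer: %s, %d dimension(s)>\n", x$mode, x$d))
  invisible(x)
}
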