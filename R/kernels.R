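#' Kernel configuration
#'
#' The covariance functions are isotropic functions of the Euclidean distance
#' \eqn{d = \lVert x_i - x_j\rVert} with a single shared length scale:
#' \describe{
#'   \item{RBF}{\eqn{\sigma^2 \exp(-d^2 / 2\ell^2)}}
#'   \item{RQ}{\eqn{\sigma^2 (1 + d^2 / 2\alpha\ell^2)^{-\alpha}} (tends to
#'     RBF as \eqn{\alpha \to \infty})}
#'   \item{M32}{Matern 3/2, \eqn{\sigma^2 (1 + \sqrt3 d/\ell)
#'     \exp(-\sqrt3 d/\ell)}}
#' }
#' An index-diagonal White-noise term \eqn{\sigma_W^2 \delta(i,j)} models
#' observation noise; it is added only between identical observation indices,
#' never between distinct points that happen to coincide.
#'
#' @param family `"RBF"`, `"RQ"` or `"M32"`.
#' @param variance Signal variance \eqn{\sigma^2 > 0}.
#' @param length_scale Length scale \eqn{\ell > 0}.
#' @param alpha RQ shape \eqn{\alpha > 0} (ignored by other families).
#' @param white_variance Observation-noise variance \eqn{\sigma_W^2 \ge 0}.
#' @return A `des_kernel` list.
#' @export
kernel_config <- function(family = c("M32", "RBF", "RQ"), variance = 1,
                          length_scale = 1, alpha = 1, white_variance = 0) {
  family <- match.arg(family)
  if (variance <= 0 || length_scale <= 0 || white_variance < 0 ||
      (family == "RQ" && alpha <= 0)) {
    abort("kernel hyperparameters out of range.", class = "desgp_validation_error")
  }
  structure(
    list(family = family, variance = variance, length_scale = length_scale,
         alpha = alpha, white_variance = white_variance),
    class = "des_kernel"
  )
}

#' @export
print.des_kernel <- function(x, ...) {
  extra <- if (x$family == "RQ") sprintf(", alpha %.4g", x$alpha) else ""
  cat(sprintf("<%s kernel: variance %.4g, length scale %.4g%s, white %.4g>\n",
              x$family, x$variance, x$length_scale, extra, x$white_variance))
  invisible(x)
}

# pairwise Euclidean distances between rows of X and X2
euclid_dist <- function(X, X2) {
  X <- as.matrix(X); X2 <- as.matrix(X2)
  if (ncol(X) != ncol(X2)) {
    abort("feature dimensionality mismatch.", class = "desgp_shape_error")
  }
  d2 <- outer(rowSums(X^2), rowSums(X2^2), "+") - 2 * tcrossprod(X, X2)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

kernel_from_dist <- function(config, D) {
  s2 <- config$variance
  l <- config$length_scale
  switch(config$family,
    RBF = s2 * exp(-D^2 / (2 * l^2)),
    RQ  = s2 * (1 + D^2 / (2 * config$alpha * l^2))^(-config$alpha),
    M32 = {
      a <- sqrt(3) * D / l
      s2 * (1 + a) * exp(-a)
    }
  )
}

#' Evaluate a kernel on two point sets
#'
#' @param config A [kernel_config()].
#' @param X,X2 Feature matrices (rows are points); `X2` defaults to `X`.
#' @param include_white Add the \eqn{\sigma_W^2} diagonal? Only meaningful
#'   when `X` and `X2` are the same observation set; the White term is
#'   index-based, so coincident but distinct points get no noise covariance.
#' @return Covariance matrix `nrow(X)` x `nrow(X2)`.
#' @export
#' @examples
#' X <- matrix(rnorm(10), 5)
#' kernel_eval(kernel_config("RBF", variance = 2.5), X, X)[1, 1]  # 2.5
kernel_eval <- function(config, X, X2 = X, include_white = FALSE) {
  stopifnot(inherits(config, "des_kernel"))
  X <- as.matrix(X); X2 <- as.matrix(X2)
  K <- kernel_from_dist(config, euclid_dist(X, X2))
  if (include_white && config$white_variance > 0) {
    if (nrow(X) != nrow(X2)) {
      abort("include_white requires X and X2 to be the same observation set.",
            class = "desgp_shape_error")
    }
    K <- K + diag(config$white_variance, nrow(X))
  }
  K
}

# dK/d(log theta) for each free hyperparameter, as a named list of matrices.
# Used by the LML gradient; log-parameterization keeps positivity implicit.
kernel_grads_log <- function(config, D, K_main) {
  s2 <- config$variance; l <- config$length_scale
  out <- list()
  out$log_variance <- K_main  # dK/dlog s2 = K
  out$log_length_scale <- switch(config$family,
    RBF = K_main * D^2 / l^2,
    RQ = {
      u <- D^2 / (2 * config$alpha * l^2)
      K_main * (config$alpha * 2 * u / (1 + u))   # dK/dl * l
    },
    M32 = {
      a <- sqrt(3) * D / l
      s2 * a^2 * exp(-a)
    }
  )
  if (config$family == "RQ") {
    u <- D^2 / (2 * config$alpha * l^2)
    out$log_alpha <- K_main * config$alpha * (-log1p(u) + u / (1 + u))
  }
  out
}
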