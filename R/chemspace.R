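#' Probabilistic PCA of the DES sigma-profile space
#'
#' Fits the Tipping-Bishop latent-variable model
#' \eqn{x = W z + \mu + \epsilon}, \eqn{z \sim N(0, I_q)},
#' \eqn{\epsilon \sim N(0, \sigma^2 I_d)}, to the 183-entry DES descriptors,
#' giving a 2-D map of the chemical space. The maximum-likelihood solution
#' is closed-form: \eqn{W = U_q (\Lambda_q - \sigma^2 I)^{1/2}} with
#' \eqn{U_q, \Lambda_q} the leading eigenvectors/values of the sample
#' covariance and \eqn{\sigma^2} the mean of the discarded eigenvalues
#' (`method = "eig"`, the default). An EM route is kept for cross-checking
#' (`method = "em"`); both pin the sign of each component so that its
#' largest-magnitude loading is positive, making maps reproducible.
#'
#' @param X Feature matrix (n x d, rows are DES descriptors; temperature is
#'   never included).
#' @param n_components Latent dimension (2 for maps).
#' @param method `"eig"` (closed form) or `"em"`.
#' @param seed Seed for the EM initialisation.
#' @param tol EM convergence tolerance on the log-likelihood change.
#' @param max_iter EM iteration cap.
#' @return A `des_ppca` with `mean`, loading matrix `W` (d x q), orthonormal
#'   `components` (d x q), `sigma2`, per-component `explained_variance` and
#'   the fitted `log_likelihood`.
#' @export
fit_ppca <- function(X, n_components = 2, method = c("eig", "em"), seed = 1L,
                     tol = 1e-8, max_iter = 1000) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X); q <- as.integer(n_components)
  if (n < 3) abort("PPCA needs at least 3 rows.", class = "desgp_validation_error")
  if (q < 1 || q >= d) abort("n_components must be in [1, d-1].",
                             class = "desgp_validation_error")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S_trace <- sum(Xc^2) / n
  if (S_trace < .Machine$double.eps) {
    warn("all rows identical: degenerate PPCA model with zero loadings.")
    W <- matrix(0, d, q)
    return(new_ppca(mu, W, 0, rep(0, q), -Inf, method))
  }

  if (method == "eig") {
    # eigendecomposition via SVD of the centered data (d can exceed n)
    sv <- svd(Xc, nu = 0)
    ev_all <- c(sv$d^2 / n, rep(0, max(0, d - length(sv$d))))
    lambda <- ev_all[seq_len(q)]
    sigma2 <- if (d > q) mean(ev_all[(q + 1):d]) else 0
    U <- sv$v[, seq_len(q), drop = FALSE]
    W <- U %*% diag(sqrt(pmax(lambda - sigma2, 0)), q)
    ll <- if (sigma2 > 0) ppca_loglik(Xc, W, sigma2) else NA_real_
  } else {
    em <- ppca_em(Xc, q, seed = seed, tol = tol, max_iter = max_iter)
    W <- em$W; sigma2 <- em$sigma2; ll <- em$loglik
    # rotate W to the orthogonalized, variance-ordered solution
    sw <- svd(W)
    U <- sw$u
    lambda <- sw$d^2 + sigma2
    W <- U %*% diag(sw$d, q)
  }

  # sign convention: largest-magnitude loading of each component positive
  flip <- apply(U, 2, function(u) sign(u[which.max(abs(u))]))
  flip[flip == 0] <- 1
  U <- sweep(U, 2, flip, "*")
  W <- sweep(W, 2, flip, "*")
  new_ppca(mu, W, sigma2, lambda, ll, method, U)
}

new_ppca <- function(mu, W, sigma2, lambda, ll, method, U = NULL) {
  structure(
    list(mean = mu, W = W, sigma2 = sigma2,
         components = if (is.null(U)) W else U,
         explained_variance = lambda, log_likelihood = ll, method = method,
         format_version = "desgp-ppca-1"),
    class = "des_ppca"
  )
}

#' @export
print.des_ppca <- function(x, ...) {
  cat(sprintf("<des_ppca: %d -> %d dims, sigma2 = %.4g, EV = %s>\n",
              nrow(x$W), ncol(x$W), x$sigma2,
              paste(signif(x$explained_variance, 4), collapse = ", ")))
  invisible(x)
}

# marginal log-likelihood of centered data under PPCA(W, sigma2)
ppca_loglik <- function(Xc, W, sigma2) {
  n <- nrow(Xc); d <- ncol(Xc); q <- ncol(W)
  M <- crossprod(W) + diag(sigma2, q)
  # log det C and trace(C^-1 S) via Woodbury; C = W W' + sigma2 I
  logdetC <- determinant(M, logarithm = TRUE)$modulus +
    (d - q) * log(sigma2)
  Minv <- solve(M)
  XW <- Xc %*% W
  trCinvS <- (sum(Xc^2) - sum((XW %*% Minv) * XW)) / (n * sigma2)
  as.numeric(-n / 2 * (d * log(2 * pi) + logdetC + trCinvS))
}

# EM for PPCA (Tipping & Bishop); returns W, sigma2 and the loglik trace
ppca_em <- function(Xc, q, seed = 1L, tol = 1e-8, max_iter = 1000) {
  n <- nrow(Xc); d <- ncol(Xc)
  withr::with_seed(as.integer(seed), {
    W <- matrix(rnorm(d * q, sd = 0.1), d, q)
  })
  sigma2 <- mean(Xc^2)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    M <- crossprod(W) + diag(sigma2, q)
    Minv <- solve(M)
    # E-step sufficient statistics
    XW <- Xc %*% W                      # n x q
    Ez <- XW %*% Minv                   # posterior means
    sumEzz <- n * sigma2 * Minv + crossprod(Ez)
    # M-step
    W_new <- crossprod(Xc, Ez) %*% solve(sumEzz)
    sigma2_new <- (sum(Xc^2) - 2 * sum((Xc %*% W_new) * Ez) +
                     sum(sumEzz * crossprod(W_new))) / (n * d)
    W <- W_new; sigma2 <- max(sigma2_new, 1e-12)
    ll <- ppca_loglik(Xc, W, sigma2)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(W = W, sigma2 = sigma2, loglik = ll, loglik_trace = ll_trace)
}

#' Project descriptors onto the PPCA map
#'
#' Returns data-scale coordinates: the posterior-mean latent positions
#' \eqn{M^{-1} W^\top (x - \mu)} rescaled by the component standard
#' deviations, so that in the zero-noise limit the coordinates coincide with
#' classical PCA scores. Duplicate inputs map to identical points, and the
#' temperature entry is never part of the projected vector (maps are built
#' from the 183-entry composition descriptor only).
#'
#' @param model A `des_ppca`.
#' @param X Matrix of descriptors (n x d).
#' @return Tibble with columns `PC1`, `PC2`, ...
#' @export
project_ppca <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$W)) {
    abort("descriptor dimensionality does not match the PPCA model.",
          class = "desgp_shape_error")
  }
  q <- ncol(model$W)
  Xc <- sweep(X, 2, model$mean)
  if (all(model$W == 0)) {
    coords <- matrix(0, nrow(X), q,
                     dimnames = list(NULL, paste0("PC", seq_len(q))))
    return(tibble::as_tibble(coords))
  }
  M <- crossprod(model$W) + diag(model$sigma2, q)
  Z <- Xc %*% model$W %*% solve(M)          # posterior means
  coords <- Z %*% diag(sqrt(model$explained_variance), q)
  colnames(coords) <- paste0("PC", seq_len(q))
  tibble::as_tibble(coords)
}

#' Map PPCA coordinates back to descriptor space
#' @param model A `des_ppca`.
#' @param coords Matrix/tibble of coordinates as returned by
#'   [project_ppca()].
#' @return Reconstructed descriptor matrix.
#' @export
reconstruct_ppca <- function(model, coords) {
  coords <- as.matrix(coords)
  q <- ncol(model$W)
  Z <- coords %*% diag(1 / sqrt(model$explained_variance), q)
  sweep(Z %*% t(model$W), 2, model$mean, "+")
}

#' @export
tidy.des_ppca <- function(x, ...) {
  q <- ncol(x$W)
  tibble::tibble(
    component = rep(seq_len(q), each = nrow(x$W)),
    dimension = rep(seq_len(nrow(x$W)), q),
    loading = as.vector(x$components)
  )
}

#' @export
glance.des_ppca <- function(x, ...) {
  tibble::tibble(
    d = nrow(x$W), q = ncol(x$W), sigma2 = x$sigma2,
    explained_variance_1 = x$explained_variance[1],
    explained_variance_2 = if (ncol(x$W) > 1) x$explained_variance[2] else NA_real_,
    log_likelihood = x$log_likelihood, method = x$method
  )
}

#' Grid a predicted property over the 2-D map
#'
#' Produces the data behind property-surface maps: the scattered
#' (coordinate, value) points plus a regular grid interpolated by
#' inverse-distance weighting. The grid spans exactly the bounding box of
#' the coordinates; a grid node coinciding with an input point takes that
#' point's value exactly.
#'
#' @param coords n x 2 coordinates (e.g. from [project_ppca()]).
#' @param values Numeric property values, length n.
#' @param n_grid Grid resolution per axis.
#' @param power IDW exponent.
#' @return List with `points` (tibble x, y, value) and `grid` (long tibble
#'   x, y, value).
#' @export
export_surface <- function(coords, values, n_grid = 50, power = 2) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(values)) {
    abort("coords and values lengths differ.", class = "desgp_shape_error")
  }
  if (nrow(coords) < 3) {
    abort("need at least 3 points to build a surface.",
          class = "desgp_data_error")
  }
  xs <- seq(min(coords[, 1]), max(coords[, 1]), length.out = n_grid)
  ys <- seq(min(coords[, 2]), max(coords[, 2]), length.out = n_grid)
  gg <- as.matrix(expand.grid(x = xs, y = ys))
  D <- euclid_dist(gg, coords)
  val <- numeric(nrow(gg))
  hit <- D < 1e-12
  exact <- rowSums(hit) > 0
  val[exact] <- vapply(which(exact),
                       function(i) values[which(hit[i, ])[1]], numeric(1))
  if (any(!exact)) {
    Wt <- 1 / D[!exact, , drop = FALSE]^power
    val[!exact] <- drop(Wt %*% values) / rowSums(Wt)
  }
  list(
    points = tibble::tibble(x = coords[, 1], y = coords[, 2], value = values),
    grid = tibble::tibble(x = gg[, 1], y = gg[, 2], value = val)
  )
}
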