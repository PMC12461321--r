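#' Log marginal likelihood of a zero-mean GP
#'
#' With a null mean function the training labels are jointly Gaussian,
#' \eqn{Y \sim N(0, \Sigma + \sigma_W^2 I)}, and the log marginal likelihood
#' is \deqn{\log p(Y) = -\tfrac12 Y^\top \Sigma_f^{-1} Y
#'   - \tfrac12 \log\lvert\Sigma_f\rvert - \tfrac{n}{2}\log 2\pi.}
#' A jitter is added to the diagonal before the Cholesky factorisation and
#' escalated tenfold (up to `max_jitter`) if the factorisation fails.
#'
#' @param kernel A [kernel_config()] (its White term is always included here).
#' @param X Feature matrix (normalised space).
#' @param Y Label vector (normalised space, zero mean assumed).
#' @param jitter Initial diagonal jitter, relative to the mean diagonal.
#' @param max_jitter Upper bound for jitter escalation.
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(kernel, X, Y, jitter = 1e-8,
                                    max_jitter = 1e-2) {
  f <- gp_factorize(kernel, as.matrix(X), as.numeric(Y), jitter, max_jitter)
  f$lml
}

# Cholesky of K + jitter*I with escalation; returns L, alpha = K^-1 Y, lml.
# `absolute = TRUE` takes jitter as-is (used when reloading archives so the
# factorization is bit-identical to the saved session's).
gp_factorize <- function(kernel, X, Y, jitter = 1e-8, max_jitter = 1e-2,
                         absolute = FALSE) {
  n <- nrow(X)
  K <- kernel_eval(kernel, X, X, include_white = TRUE)
  scale <- mean(diag(K))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  j <- if (absolute) jitter else jitter * scale
  repeat {
    L <- tryCatch(chol(K + diag(j, n)), error = function(e) NULL)
    if (!is.null(L)) break
    if (j >= max_jitter * scale) {
      abort("covariance factorization failed even at maximum jitter.",
            class = "desgp_numerical_error")
    }
    j <- j * 10
  }
  alpha <- backsolve(L, forwardsolve(t(L), Y))
  lml <- -0.5 * sum(Y * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  list(L = L, alpha = alpha, lml = lml, jitter = j, K = K)
}

# LML and its gradient w.r.t. log-hyperparameters (theta layout per family)
lml_with_grad <- function(theta, family, D, Y, jitter) {
  cfg <- theta_to_kernel(theta, family)
  n <- length(Y)
  K_main <- kernel_from_dist(cfg, D)
  K <- K_main + diag(cfg$white_variance + jitter, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = -Inf, grad = rep(0, length(theta))))
  alpha <- backsolve(L, forwardsolve(t(L), Y))
  lml <- -0.5 * sum(Y * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  # dLML/dtheta_k = 0.5 tr((alpha alpha' - K^-1) dK/dtheta_k)
  Kinv <- chol2inv(L)
  A <- tcrossprod(alpha) - Kinv
  grads <- kernel_grads_log(cfg, D, K_main)
  g <- vapply(grads, function(dK) 0.5 * sum(A * dK), numeric(1))
  g_white <- 0.5 * sum(diag(A)) * cfg$white_variance  # dK/dlog sW2 = sW2 I
  list(value = lml, grad = c(g, log_white_variance = g_white))
}

theta_to_kernel <- function(theta, family) {
  e <- exp(theta)
  if (family == "RQ") {
    kernel_config(family, variance = e[1], length_scale = e[2], alpha = e[3],
                  white_variance = e[4])
  } else {
    kernel_config(family, variance = e[1], length_scale = e[2],
                  white_variance = e[3])
  }
}

kernel_to_theta <- function(cfg) {
  th <- c(log_variance = log(cfg$variance),
          log_length_scale = log(cfg$length_scale))
  if (cfg$family == "RQ") th <- c(th, log_alpha = log(cfg$alpha))
  c(th, log_white_variance = log(max(cfg$white_variance, 1e-12)))
}

#' Train a Gaussian-process property model
#'
#' Fits the full model used for DES property prediction: feature and label
#' normalisers are computed from the training data only, hyperparameters
#' (\eqn{\sigma^2, \ell, [\alpha], \sigma_W^2}) are optimised by maximising
#' the log marginal likelihood with a bounded quasi-Newton method (L-BFGS-B)
#' in log-hyperparameter space, with multiple restarts drawn log-uniformly
#' within the bounds under a fixed seed, and the best solution's Cholesky
#' factorisation is cached for prediction.
#'
#' @param X_raw Feature matrix in original units (e.g. from
#'   [featurize_dataset()]).
#' @param Y_raw Label vector in original units.
#' @param family Kernel family, see [kernel_config()].
#' @param feature_mode,label_mode Normaliser modes, see [fit_normalizer()].
#' @param n_restarts Number of random restarts after the default start.
#' @param seed Integer seed controlling restart draws.
#' @param bounds Length-2 positive bounds applied to every hyperparameter.
#' @param init Optional [kernel_config()] used as the first start.
#' @param optimize If `FALSE`, keep `init` as-is (no hyperparameter fit).
#' @param jitter Relative diagonal jitter for the factorisation.
#' @param property Optional property tag carried into predictions
#'   (`"density"`, `"viscosity"`, `"melting_temperature"`).
#' @return A `des_gp` model object.
#' @export
train_gp <- function(X_raw, Y_raw, family = c("M32", "RBF", "RQ"),
                     feature_mode = "log_standardize",
                     label_mode = "log_standardize",
                     n_restarts = 5, seed = 1L, bounds = c(1e-6, 1e6),
                     init = NULL, optimize = TRUE, jitter = 1e-8,
                     property = NULL) {
  family <- match.arg(family)
  X_raw <- as.matrix(X_raw)
  Y_raw <- as.numeric(Y_raw)
  if (nrow(X_raw) < 2 || nrow(X_raw) != length(Y_raw)) {
    abort("training needs >= 2 rows and matching X/Y sizes.",
          class = "desgp_validation_error")
  }
  fnorm <- fit_normalizer(X_raw, feature_mode)
  lnorm <- fit_normalizer(Y_raw, label_mode)
  Xn <- apply_normalizer(fnorm, X_raw)
  Yn <- as.numeric(apply_normalizer(lnorm, Y_raw))
  D <- euclid_dist(Xn, Xn)

  if (is.null(init)) {
    med <- stats::median(D[upper.tri(D)])
    if (!is.finite(med) || med <= 0) med <- 1
    init <- kernel_config(family, variance = max(var(Yn), 1e-3),
                          length_scale = med, alpha = 1, white_variance = 0.1)
  }
  cfg <- init
  lml_init <- log_marginal_likelihood(cfg, Xn, Yn, jitter)
  lml_best <- lml_init

  if (optimize) {
    lb <- log(bounds[1]); ub <- log(bounds[2])
    theta0 <- pmin(pmax(kernel_to_theta(init), lb), ub)
    starts <- list(theta0)
    withr::with_seed(as.integer(seed), {
      for (r in seq_len(n_restarts)) {
        starts[[r + 1]] <- runif(length(theta0), min = log(1e-3), max = log(1e3))
      }
    })
    best <- NULL
    for (th in starts) {
      fit <- tryCatch(
        optim(th,
              fn = function(t) -lml_with_grad(t, family, D, Yn, jitter)$value,
              gr = function(t) -lml_with_grad(t, family, D, Yn, jitter)$grad,
              method = "L-BFGS-B", lower = lb, upper = ub,
              control = list(maxit = 200)),
        error = function(e) NULL
      )
      if (!is.null(fit) && is.finite(fit$value) &&
          (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) {
      abort("all optimizer restarts failed.", class = "desgp_numerical_error")
    }
    if (-best$value >= lml_init) {
      cfg <- theta_to_kernel(best$par, family)
      lml_best <- -best$value
    }
  }

  fac <- gp_factorize(cfg, Xn, Yn, jitter)
  structure(
    list(kernel = cfg, feature_normalizer = fnorm, label_normalizer = lnorm,
         X_train = Xn, Y_train = Yn, L = fac$L, alpha = fac$alpha,
         jitter = fac$jitter, lml = fac$lml, lml_initial = lml_init,
         seed = as.integer(seed), property = property,
         format_version = "desgp-gp-1"),
    class = "des_gp"
  )
}

#' @export
print.des_gp <- function(x, ...) {
  cat(sprintf("<des_gp: %s kernel, n = %d, d = %d, LML = %.3f%s>\n",
              x$kernel$family, nrow(x$X_train), ncol(x$X_train), x$lml,
              if (!is.null(x$property)) paste0(", property = ", x$property) else ""))
  invisible(x)
}

#' Predict DES properties from a trained GP
#'
#' Computes the Gaussian posterior at new inputs,
#' \eqn{\mu' = \Sigma_*^\top \Sigma^{-1} Y} and
#' \eqn{\Sigma' = \Sigma_{**} - \Sigma_*^\top \Sigma^{-1} \Sigma_*},
#' in normalised space, then maps back to label units. By default
#' \eqn{\Sigma_{**}} includes the White-noise variance, so the reported
#' uncertainty is predictive (what a new measurement would scatter by), not
#' the latent-function uncertainty; set `include_noise = FALSE` for the
#' latter.
#'
#' Back-transformation depends on the label normaliser. For the identity and
#' standardise modes the posterior stays Gaussian, so `.pred` is the
#' posterior mean and `.pred_var` the exact variance in label units. Under
#' log-standardisation the label posterior is log-normal; `.pred` is then its
#' median \eqn{\exp(\mu)} (buffer-corrected) and the 95% interval
#' `.pred_lower`/`.pred_upper` is the multiplicative band
#' \eqn{\exp(\mu \pm 1.96 s)}, with `.pred_var` the exact log-normal
#' variance.
#'
#' @param object A `des_gp`.
#' @param X_new Feature matrix in original units; rows are query points.
#' @param include_noise Include \eqn{\sigma_W^2} in the predictive variance?
#' @param level Coverage of the reported interval.
#' @param ... Unused.
#' @return A tibble with columns `.pred`, `.pred_var`, `.pred_lower`,
#'   `.pred_upper` plus the normalised-space `.mu_norm`, `.var_norm`.
#' @export
predict.des_gp <- function(object, X_new, include_noise = TRUE, level = 0.95,
                           ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(object$X_train)) {
    abort("query dimensionality does not match the training features.",
          class = "desgp_shape_error")
  }
  Xn <- apply_normalizer(object$feature_normalizer, X_new)
  Ks <- kernel_eval(object$kernel, object$X_train, Xn)
  mu <- drop(crossprod(Ks, object$alpha))
  V <- forwardsolve(t(object$L), Ks)
  kss <- object$kernel$variance +
    if (include_noise) object$kernel$white_variance else 0
  varn <- pmax(kss - colSums(V^2), 0)

  z <- stats::qnorm(1 - (1 - level) / 2)
  ln <- object$label_normalizer
  lo_n <- mu - z * sqrt(varn)
  hi_n <- mu + z * sqrt(varn)
  if (ln$mode == "log_standardize") {
    s <- ln$scale; m <- ln$center; b <- ln$buffer
    pred <- exp(mu * s + m) - b
    lower <- exp(lo_n * s + m) - b
    upper <- exp(hi_n * s + m) - b
    # exact variance of the log-normal exp(N(m + s*mu, s^2*varn)) - b
    vlog <- s^2 * varn
    pvar <- (exp(vlog) - 1) * exp(2 * (m + s * mu) + vlog)
  } else {
    pred <- drop(invert_normalizer(ln, mu))
    pvar <- varn * ln$scale^2
    lower <- drop(invert_normalizer(ln, lo_n))
    upper <- drop(invert_normalizer(ln, hi_n))
  }
  tibble::tibble(
    .pred = pred, .pred_var = pvar, .pred_lower = lower, .pred_upper = upper,
    .mu_norm = mu, .var_norm = varn
  )
}

#' @export
tidy.des_gp <- function(x, ...) {
  cfg <- x$kernel
  tb <- tibble::tibble(
    term = c("variance", "length_scale", "white_variance"),
    estimate = c(cfg$variance, cfg$length_scale, cfg$white_variance)
  )
  if (cfg$family == "RQ") {
    tb <- dplyr::add_row(tb, term = "alpha", estimate = cfg$alpha, .after = 2)
  }
  tb
}

#' @export
glance.des_gp <- function(x, ...) {
  tibble::tibble(
    kernel = x$kernel$family,
    n = nrow(x$X_train),
    d = ncol(x$X_train),
    feature_norm = x$feature_normalizer$mode,
    label_norm = x$label_normalizer$mode,
    log_marginal_likelihood = x$lml,
    jitter = x$jitter
  )
}

#' Save / load a trained GP as a plain-text archive
#'
#' The archive is a directory holding the kernel configuration, normaliser
#' parameters and training matrices (full `%.17g` precision) plus a format
#' version string; loading rebuilds the Cholesky cache, so a load/predict
#' cycle reproduces the saved session's predictions bit-for-bit.
#'
#' @param model A `des_gp`.
#' @param dir Archive directory.
#' @export
save_gp <- function(model, dir) {
  stopifnot(inherits(model, "des_gp"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  num <- function(x) sprintf("%.17g", x)
  # doubles as %.17g strings: exact round trip regardless of JSON writer
  ser_norm <- function(nz) list(mode = nz$mode, center = num(nz$center),
                                scale = num(nz$scale), buffer = num(nz$buffer),
                                d = nz$d)
  meta <- list(
    format_version = model$format_version,
    property = model$property,
    seed = model$seed,
    kernel = list(family = model$kernel$family,
                  variance = num(model$kernel$variance),
                  length_scale = num(model$kernel$length_scale),
                  alpha = num(model$kernel$alpha),
                  white_variance = num(model$kernel$white_variance)),
    jitter = num(model$jitter),
    feature_normalizer = ser_norm(model$feature_normalizer),
    label_normalizer = ser_norm(model$label_normalizer)
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(apply(model$X_train, 1, function(r) paste(num(r), collapse = ",")),
             file.path(dir, "X_train.csv"))
  writeLines(num(model$Y_train), file.path(dir, "Y_train.csv"))
  invisible(model)
}

#' @rdname save_gp
#' @export
load_gp <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format_version, "desgp-gp-1")) {
    abort("unrecognized model archive format.", class = "desgp_format_error")
  }
  X <- do.call(rbind, lapply(
    strsplit(readLines(file.path(dir, "X_train.csv")), ","), as.numeric))
  Y <- as.numeric(readLines(file.path(dir, "Y_train.csv")))
  cfg <- kernel_config(meta$kernel$family, as.numeric(meta$kernel$variance),
                       as.numeric(meta$kernel$length_scale),
                       as.numeric(meta$kernel$alpha),
                       as.numeric(meta$kernel$white_variance))
  renorm <- function(l) structure(
    list(mode = l$mode, center = as.numeric(l$center),
         scale = as.numeric(l$scale), buffer = as.numeric(l$buffer),
         d = as.integer(l$d)),
    class = "des_normalizer")
  fac <- gp_factorize(cfg, X, Y, jitter = as.numeric(meta$jitter),
                      absolute = TRUE)
  structure(
    list(kernel = cfg, feature_normalizer = renorm(meta$feature_normalizer),
         label_normalizer = renorm(meta$label_normalizer),
         X_train = X, Y_train = Y, L = fac$L, alpha = fac$alpha,
         jitter = fac$jitter, lml = fac$lml, lml_initial = NA_real_,
         seed = meta$seed, property = meta$property,
         format_version = meta$format_version),
    class = "des_gp"
  )
}
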