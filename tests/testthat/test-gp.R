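test_that("kernels return the signal variance at zero distance", {
  x <- matrix(rnorm(6), 2, 3)
  for (fam in c("RBF", "RQ", "M32")) {
    k <- kernel_config(fam, variance = 2.5, length_scale = 0.7, alpha = 1.3)
    K <- kernel_eval(k, x, x)
    expect_equal(diag(K), rep(2.5, 2))
  }
})

test_that("the White term is index-based, not distance-based", {
  X <- matrix(1, 3, 4)  # three identical points
  k <- kernel_config("RBF", variance = 1, white_variance = 0.3)
  K <- kernel_eval(k, X, X, include_white = TRUE)
  expect_equal(K, matrix(1, 3, 3) + diag(0.3, 3))
  # cross-covariance never carries noise
  expect_equal(kernel_eval(k, X, X, include_white = FALSE), matrix(1, 3, 3))
})

test_that("Matern 3/2 matches its closed form at unit distance", {
  # independent evaluation of sigma^2 (1 + sqrt(3) d / l) exp(-sqrt(3) d / l)
  X <- rbind(0, 1)
  K <- kernel_eval(kernel_config("M32", 1, 1), X, X)
  expect_equal(K[1, 2], (1 + sqrt(3)) * exp(-sqrt(3)), tolerance = 1e-12)
})

test_that("RQ converges to RBF as alpha grows", {
  withr::with_seed(2, X <- matrix(rnorm(60), 20, 3))
  Krbf <- kernel_eval(kernel_config("RBF", 1.2, 0.8), X, X)
  Krq <- kernel_eval(kernel_config("RQ", 1.2, 0.8, alpha = 1e6), X, X)
  expect_lt(max(abs(Krbf - Krq)), 1e-4)
})

test_that("normalizers match hand-computed moments and round-trip", {
  nz <- fit_normalizer(c(1, 2, 3), "standardize")
  expect_equal(nz$center, 2)
  expect_equal(nz$scale, 1)             # sample sd, divisor n-1
  expect_equal(apply_normalizer(nz, c(1, 2, 3)), c(-1, 0, 1))

  # identity mode
  nid <- fit_normalizer(rnorm(5), "none")
  expect_equal(invert_normalizer(nid, apply_normalizer(nid, 1:5)), 1:5)

  withr::with_seed(3, z <- matrix(rexp(60), 20, 3))
  for (mode in c("none", "standardize", "log_standardize")) {
    nz <- fit_normalizer(z, mode)
    zt <- apply_normalizer(nz, z)
    expect_equal(invert_normalizer(nz, zt), z, tolerance = 1e-10)
    if (mode == "standardize") {
      expect_equal(colMeans(zt), rep(0, 3), tolerance = 1e-12)
      expect_equal(apply(zt, 2, sd), rep(1, 3), tolerance = 1e-12)
    }
  }

  # the 1e-3 buffer keeps zeros finite in log mode
  nz0 <- fit_normalizer(c(0, 0, 1, 5), "log_standardize")
  expect_true(all(is.finite(apply_normalizer(nz0, c(0, 2)))))
  expect_error(fit_normalizer(c(-1, 2), "log_standardize"),
               class = "desgp_domain_error")

  # constant dimensions map to zero instead of NaN
  nzc <- fit_normalizer(cbind(rep(4, 6), 1:6), "standardize")
  expect_equal(apply_normalizer(nzc, cbind(rep(4, 3), 1:3))[, 1], rep(0, 3))

  # out-of-range values transform finitely, no clipping
  nzr <- fit_normalizer(1:10, "standardize")
  expect_true(is.finite(apply_normalizer(nzr, 1e4)))
})

test_that("log marginal likelihood matches the n = 1 closed form", {
  k <- kernel_config("RBF", variance = 1.7, white_variance = 0.4)
  y <- 0.83
  kk <- 1.7 + 0.4
  expect_equal(
    log_marginal_likelihood(k, matrix(0, 1, 2), y, jitter = 0),
    -0.5 * log(2 * pi * kk) - y^2 / (2 * kk),
    tolerance = 1e-10
  )
})

test_that("log marginal likelihood is invariant to row permutation", {
  withr::with_seed(8, {
    X <- matrix(rnorm(24), 8, 3); Y <- rnorm(8)
    k <- kernel_config("M32", 1.1, 0.9, white_variance = 0.1)
    l1 <- log_marginal_likelihood(k, X, Y)
    p <- sample(8)
    l2 <- log_marginal_likelihood(k, X[p, ], Y[p])
  })
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("analytic LML gradients agree with finite differences", {
  withr::with_seed(4, {
    X <- matrix(rnorm(40), 8, 5)
    Y <- rnorm(8)
  })
  D <- desgp:::euclid_dist(X, X)
  for (fam in c("RBF", "RQ", "M32")) {
    th <- log(c(1.3, 0.8, if (fam == "RQ") 2.1, 0.3))
    g <- desgp:::lml_with_grad(th, fam, D, Y, 1e-8)
    fd <- vapply(seq_along(th), function(j) {
      h <- 1e-6
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      (desgp:::lml_with_grad(tp, fam, D, Y, 1e-8)$value -
         desgp:::lml_with_grad(tm, fam, D, Y, 1e-8)$value) / (2 * h)
    }, numeric(1))
    expect_equal(unname(g$grad), fd, tolerance = 1e-4)
  }
})

test_that("posterior mean/variance agree with dense-inversion oracle", {
  withr::with_seed(10, {
    for (n in c(5, 20, 50)) {
      X <- matrix(rnorm(n * 4), n, 4)
      Y <- rnorm(n)
      Xq <- matrix(rnorm(6 * 4), 6, 4)
      k <- kernel_config("M32", 1.4, 1.1, white_variance = 0.05)
      # oracle: explicit partitioned-covariance conditioning
      K <- kernel_eval(k, X, X, include_white = TRUE)
      Ks <- kernel_eval(k, X, Xq)
      Kss <- kernel_eval(k, Xq, Xq, include_white = TRUE)
      mu_o <- drop(t(Ks) %*% solve(K) %*% Y)
      var_o <- diag(Kss - t(Ks) %*% solve(K) %*% Ks)

      fit <- train_gp(X, Y, "M32", feature_mode = "none", label_mode = "none",
                      init = k, optimize = FALSE, jitter = 1e-12)
      pr <- predict(fit, Xq)
      expect_equal(pr$.pred, mu_o, tolerance = 1e-8)
      expect_equal(pr$.pred_var, var_o, tolerance = 1e-8)
    }
  })
})

test_that("a noise-free GP interpolates its training data", {
  withr::with_seed(12, {
    X <- matrix(rnorm(30), 10, 3)
    Y <- rnorm(10)
  })
  k <- kernel_config("RBF", 1, 1, white_variance = 0)
  fit <- train_gp(X, Y, "RBF", feature_mode = "none", label_mode = "none",
                  init = k, optimize = FALSE, jitter = 1e-10)
  pr <- predict(fit, X)
  expect_equal(pr$.pred, Y, tolerance = 1e-6)
  expect_true(all(pr$.pred_var < 1e-6))
})

test_that("far from the data the GP reverts to its prior", {
  withr::with_seed(13, {
    X <- matrix(rnorm(20), 10, 2)
    Y <- rnorm(10)
  })
  k <- kernel_config("M32", 1.5, 0.5, white_variance = 0.2)
  fit <- train_gp(X, Y, "M32", feature_mode = "none", label_mode = "none",
                  init = k, optimize = FALSE)
  pr <- predict(fit, matrix(1e4, 1, 2))
  expect_equal(pr$.mu_norm, 0, tolerance = 1e-6)
  expect_equal(pr$.var_norm, 1.5 + 0.2, tolerance = 1e-6)
  # excluding observation noise gives the latent variance only
  pr_lat <- predict(fit, matrix(1e4, 1, 2), include_noise = FALSE)
  expect_equal(pr_lat$.var_norm, 1.5, tolerance = 1e-6)
})

test_that("posterior variance never exceeds prior variance and duplicates only shrink it", {
  withr::with_seed(14, {
    X <- matrix(rnorm(24), 12, 2)
    Y <- rnorm(12)
    Xq <- matrix(rnorm(40), 20, 2)
  })
  k <- kernel_config("RBF", 1.3, 0.8, white_variance = 0.1)
  fit <- train_gp(X, Y, "RBF", feature_mode = "none", label_mode = "none",
                  init = k, optimize = FALSE)
  pr <- predict(fit, Xq)
  expect_true(all(pr$.var_norm <= 1.3 + 0.1 + 1e-10))
  # duplicating a training point (same label) cannot increase variance
  fit2 <- train_gp(rbind(X, X[1, ]), c(Y, Y[1]), "RBF",
                   feature_mode = "none", label_mode = "none",
                   init = k, optimize = FALSE)
  pr2 <- predict(fit2, Xq)
  expect_true(all(pr2$.var_norm <= pr$.var_norm + 1e-8))
})

test_that("training recovers known hyperparameters and generalizes", {
  # data simulated from a known M32 GP over 5-D features with 2-D intrinsic
  # structure (sigma-profile descriptors are likewise high-D but low-rank)
  sim <- m32_recovery_sim(21)
  tr <- 1:100; te <- 101:130
  fit <- train_gp(sim$X[tr, ], sim$y[tr], "M32", feature_mode = "none",
                  label_mode = "none", seed = 42)
  sw2 <- fit$kernel$white_variance
  expect_gt(sw2, 0.01 / 3)
  expect_lt(sw2, 0.01 * 3)
  pr <- predict(fit, sim$X[te, ])
  m <- evaluate_predictions(pr$.pred, sim$f[te], "density")
  expect_gt(m$r2, 0.9)
  expect_gte(fit$lml, fit$lml_initial)
})

test_that("training is deterministic given the seed", {
  withr::with_seed(22, {
    X <- matrix(rnorm(80), 40, 2)
    Y <- sin(X[, 1]) + rnorm(40, sd = 0.1)
  })
  f1 <- train_gp(X, Y, "RBF", feature_mode = "none", label_mode = "standardize",
                 seed = 9)
  f2 <- train_gp(X, Y, "RBF", feature_mode = "none", label_mode = "standardize",
                 seed = 9)
  expect_identical(f1$kernel, f2$kernel)
})

test_that("constant labels predict that constant everywhere", {
  withr::with_seed(23, X <- matrix(rnorm(30), 15, 2))
  fit <- train_gp(X, rep(7.5, 15), "M32", feature_mode = "none",
                  label_mode = "standardize", n_restarts = 1)
  pr <- predict(fit, matrix(rnorm(10), 5, 2))
  expect_equal(pr$.pred, rep(7.5, 5), tolerance = 1e-6)
})

test_that("label-normalizer equivariance: prescaling labels equals normalizing", {
  withr::with_seed(24, {
    X <- matrix(rnorm(60), 30, 2)
    Y <- 3 + 5 * sin(X[, 1]) + rnorm(30, sd = 0.05)
    Xq <- matrix(rnorm(12), 6, 2)
  })
  k <- kernel_config("RBF", 1, 1, white_variance = 0.01)
  m <- mean(Y); s <- sd(Y)
  f_norm <- train_gp(X, Y, "RBF", feature_mode = "none",
                     label_mode = "standardize", init = k, optimize = FALSE)
  f_pre <- train_gp(X, (Y - m) / s, "RBF", feature_mode = "none",
                    label_mode = "none", init = k, optimize = FALSE)
  expect_equal(predict(f_norm, Xq)$.pred,
               predict(f_pre, Xq)$.pred * s + m, tolerance = 1e-8)
})

test_that("model archives round-trip with bit-identical predictions", {
  withr::with_seed(25, {
    X <- matrix(rexp(60), 20, 3)
    Y <- rexp(20) + 0.1
    Xq <- matrix(rexp(15), 5, 3)
  })
  fit <- train_gp(X, Y, "RQ", feature_mode = "log_standardize",
                  label_mode = "log_standardize", n_restarts = 1, seed = 2,
                  property = "viscosity")
  p0 <- predict(fit, Xq)
  dir <- withr::local_tempdir()
  save_gp(fit, dir)
  fit2 <- load_gp(dir)
  expect_identical(predict(fit2, Xq)$.pred, p0$.pred)
  expect_identical(fit2$property, "viscosity")
})

test_that("tidy and glance summarize a fitted GP", {
  withr::with_seed(26, {
    X <- matrix(rnorm(40), 20, 2); Y <- rnorm(20)
  })
  fit <- train_gp(X, Y, "RQ", feature_mode = "none", label_mode = "none",
                  n_restarts = 1)
  td <- tidy(fit)
  expect_setequal(td$term, c("variance", "length_scale", "alpha", "white_variance"))
  gl <- glance(fit)
  expect_equal(gl$kernel, "RQ")
  expect_equal(gl$n, 20)
})
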