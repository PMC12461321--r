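# shared in-code fixtures; everything deterministic

fix_spec <- function(seed = 11, n_compounds = 12) {
  synthetic_spec(n_compounds = n_compounds, seed = seed)
}

fix_profiles <- function(seed = 11, n_compounds = 12) {
  gen_profiles(fix_spec(seed, n_compounds))
}

# a handcrafted Gaussian-bump profile on the canonical grid
bump_profile <- function(id = "bump", center = 0, width = 0.005, area = 100) {
  g <- sigma_grid()
  v <- exp(-(g$centers - center)^2 / (2 * width^2))
  sigma_profile(id, v * area / sum(v), g)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")

# parameter-recovery simulation: known M32 GP (variance 1, length scale 0.5,
# noise variance 0.01) over 5-D features lying on a 2-D latent manifold
m32_recovery_sim <- function(seed, n = 130) {
  withr::with_seed(seed, {
    Tlat <- matrix(runif(n * 2, -1, 1), n, 2)
    A <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
    X <- 0.5 * Tlat %*% t(A)
    k_true <- kernel_config("M32", 1, 0.5, white_variance = 0)
    Kf <- kernel_eval(k_true, X, X) + diag(1e-10, n)
    f <- drop(t(chol(Kf)) %*% rnorm(n))
    y <- f + rnorm(n, sd = 0.1)
  })
  list(X = X, f = f, y = y)
}
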