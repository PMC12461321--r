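#' Specification for the synthetic fixture generator
#'
#' The generator emulates the shape of real COSMO-RS sigma profiles and of
#' experimental DES property data closely enough that every stage of the
#' pipeline (featurisation, splitting, GP training, screening, mapping) can
#' be exercised with known ground truth. Profiles are sums of Gaussian bumps
#' on the 61-bin grid, with the dominant mass near \eqn{\sigma = 0} and
#' smaller polar wings, as in real compound libraries; total cavity areas
#' fall in the 40-250 A^2 range typical of small organic molecules. Labels
#' come from a documented latent function of the mixture descriptor plus
#' Gaussian noise — additive in log10 space for viscosity, so synthetic
#' viscosities span several orders of magnitude like experimental ones.
#'
#' @param n_compounds Number of synthetic precursors.
#' @param n_bumps Range (min, max) of Gaussian bumps per profile beyond the
#'   dominant central one.
#' @param center_range Range of bump centres (e/A^2), within the grid.
#' @param width_range Range of bump widths (e/A^2).
#' @param area_range Range of total profile areas (A^2).
#' @param latent `"moments"` (properties as smooth functions of descriptor
#'   moments) or `"rbf"` (smooth RBF mixture in descriptor space).
#' @param noise_sd Label noise. Units: g/mL (density), log10 cP (viscosity),
#'   K (melting temperature).
#' @param temperature_range Sampling range for temperatures (K).
#' @param seed Integer seed; fixes every downstream draw.
#' @return A `des_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 30, n_bumps = c(1, 3),
                           center_range = c(-0.018, 0.018),
                           width_range = c(0.0012, 0.004),
                           area_range = c(40, 250),
                           latent = c("moments", "rbf"),
                           noise_sd = NULL,
                           temperature_range = c(278, 372), seed = 1L) {
  latent <- match.arg(latent)
  grid <- sigma_grid()
  if (center_range[1] < grid$centers[1] ||
      center_range[2] > grid$centers[grid$n_bins] ||
      width_range[1] <= 0 || area_range[1] <= 0 ||
      diff(center_range) < 0 || diff(width_range) < 0 ||
      diff(area_range) < 0 || diff(temperature_range) < 0) {
    abort("infeasible synthetic-spec ranges.", class = "desgp_spec_error")
  }
  structure(
    list(n_compounds = as.integer(n_compounds), n_bumps = n_bumps,
         center_range = center_range, width_range = width_range,
         area_range = area_range, latent = latent, noise_sd = noise_sd,
         temperature_range = temperature_range, seed = as.integer(seed)),
    class = "des_synthetic_spec"
  )
}

default_noise_sd <- function(property) {
  switch(property, density = 0.005, viscosity = 0.05,
         melting_temperature = 3)
}

#' Generate a synthetic profile library
#'
#' Each profile is a dominant Gaussian bump near \eqn{\sigma = 0} plus a few
#' smaller wing bumps at random centres, scaled to a random total area.
#' Compound ids are `syn001`, `syn002`, ... Deterministic given the spec's
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of `des_sigma_profile` (a profile library).
#' @export
gen_profiles <- function(spec) {
  stopifnot(inherits(spec, "des_synthetic_spec"))
  grid <- sigma_grid()
  sg <- grid$centers
  withr::with_seed(spec$seed, {
    profs <- lapply(seq_len(spec$n_compounds), function(i) {
      # dominant nonpolar peak
      centers <- runif(1, -0.004, 0.004)
      widths <- runif(1, 0.002, 0.005)
      weights <- 1
      k <- sample(seq(spec$n_bumps[1], spec$n_bumps[2]), 1)
      if (k > 0) {
        centers <- c(centers, runif(k, spec$center_range[1], spec$center_range[2]))
        widths <- c(widths, runif(k, spec$width_range[1], spec$width_range[2]))
        weights <- c(weights, runif(k, 0.05, 0.45))
      }
      v <- rowSums(vapply(seq_along(centers), function(j) {
        weights[j] * exp(-(sg - centers[j])^2 / (2 * widths[j]^2))
      }, numeric(length(sg))))
      area <- runif(1, spec$area_range[1], spec$area_range[2])
      v <- v * area / sum(v)
      sigma_profile(sprintf("syn%03d", i), v, grid)
    })
  })
  names(profs) <- vapply(profs, `[[`, character(1), "compound_id")
  profs
}

# descriptor moments used by the "moments" latent family: aggregate the three
# 61-bin blocks and summarize total area, polarity spread, and wing fraction
feature_moments <- function(x183) {
  g <- x183[1:61] + x183[62:122] + x183[123:183]
  sg <- sigma_grid()$centers
  m0 <- sum(g)
  if (m0 <= 0) return(c(m0 = 0, spread = 0, wing = 0))
  spread <- sqrt(sum(sg^2 * g) / m0)
  wing <- sum(g[abs(sg) > 0.01]) / m0
  c(m0 = m0, spread = spread, wing = wing)
}

# latent property functions; x183 is the composition descriptor, temp in K.
# Coefficients are fixed once to give realistic ranges: density ~0.8-1.8
# g/mL with ~ -7e-4 K^-1 thermal expansion; log10 viscosity spanning roughly
# -2..6; melting temperatures ~100-570 K.
latent_moments <- function(x183, property, temp = NULL) {
  m <- feature_moments(x183)
  switch(property,
    density = 1.05 + 0.2 * tanh((m["m0"] - 140) / 60) + 0.8 * m["wing"] -
      7e-4 * (if (is.null(temp)) 0 else temp - 298),
    viscosity = -0.8 + 12 * m["wing"] + 1.5 * tanh((m["m0"] - 140) / 60) -
      0.022 * (if (is.null(temp)) 0 else temp - 298),  # log10 cP
    melting_temperature = 180 + 600 * m["wing"] + 0.6 * m["m0"]
  )
}

make_latent_rbf <- function(profiles, property, seed) {
  ids <- names(profiles)
  withr::with_seed(seed + 7L, {
    anchors <- t(vapply(seq_len(5), function(i) {
      pick <- sample(ids, 2)
      featurize_mixture(profiles, mixture_spec(pick, c(0.5, 0.5)))
    }, numeric(183)))
    w <- rnorm(5)
  })
  h <- stats::median(euclid_dist(anchors, anchors)[upper.tri(diag(5))])
  rng <- switch(property, density = c(0.85, 1.7), viscosity = c(-1.5, 5.5),
                melting_temperature = c(120, 560))
  function(x183, temp = NULL) {
    k <- exp(-euclid_dist(matrix(x183, 1), anchors)^2 / (2 * h^2))
    u <- drop(k %*% w) / (sum(abs(w)))   # in (-1, 1)
    val <- mean(rng) + diff(rng) / 2 * u
    if (!is.null(temp)) {
      val <- val - switch(property, density = 7e-4, viscosity = 0.022,
                          melting_temperature = 0) * (temp - 298)
    }
    val
  }
}

#' Generate a synthetic property dataset
#'
#' Samples mixtures of 1-3 synthetic compounds (binary-dominated, like real
#' DES databases) with Dirichlet mole fractions and, for density/viscosity,
#' uniform temperatures; labels are the latent function of the mixture
#' descriptor plus Gaussian noise. Viscosity is generated in log10 space and
#' exponentiated, so labels are positive and span several decades.
#'
#' @param spec A [synthetic_spec()].
#' @param property Property name.
#' @param n_rows Number of rows (>= 10).
#' @param profiles Optional pre-generated profile library (defaults to
#'   `gen_profiles(spec)`).
#' @return A `des_dataset` with the true noiseless labels attached as
#'   `attr(ds, "latent")`.
#' @export
gen_dataset <- function(spec, property = des_properties, n_rows = 200,
                        profiles = NULL) {
  stopifnot(inherits(spec, "des_synthetic_spec"))
  property <- match.arg(property)
  if (n_rows < 10) abort("n_rows must be >= 10.", class = "desgp_spec_error")
  if (is.null(profiles)) profiles <- gen_profiles(spec)
  ids <- names(profiles)
  uses_T <- property_uses_temperature(property)
  noise <- spec$noise_sd %||% default_noise_sd(property)
  latent_fn <- if (spec$latent == "moments") {
    function(x, temp) latent_moments(x, property, temp)
  } else {
    make_latent_rbf(profiles, property, spec$seed)
  }

  withr::with_seed(spec$seed + 1L, {
    rows <- lapply(seq_len(n_rows), function(i) {
      k <- sample(1:3, 1, prob = c(0.1, 0.65, 0.25))
      comps <- sample(ids, k)
      g <- rgamma(k, shape = 2)
      xs <- g / sum(g)
      temp <- if (uses_T) runif(1, spec$temperature_range[1],
                                spec$temperature_range[2]) else NULL
      ms <- mixture_spec(comps, xs, temperature = temp)
      x183 <- featurize_mixture(profiles, ms)[1:183]
      lat <- unname(latent_fn(x183, temp))
      list(comps = comps, xs = xs, temp = temp, latent = lat)
    })
    eps <- rnorm(n_rows, sd = noise)
  })

  lat <- vapply(rows, `[[`, numeric(1), "latent")
  label <- lat + eps
  if (property == "viscosity") {
    label <- 10^label          # latent is log10 cP
    lat <- 10^lat
  }
  if (property == "density") label <- pmax(label, 0.05)
  pad <- function(v, n = 3, fill = NA) c(v, rep(fill, n - length(v)))
  df <- tibble::tibble(
    comp1 = vapply(rows, function(r) r$comps[1], character(1)),
    comp2 = vapply(rows, function(r) pad(r$comps)[2], character(1)),
    comp3 = vapply(rows, function(r) pad(r$comps)[3], character(1)),
    x1 = vapply(rows, function(r) r$xs[1], numeric(1)),
    x2 = vapply(rows, function(r) pad(r$xs)[2], numeric(1)),
    x3 = vapply(rows, function(r) pad(r$xs)[3], numeric(1)),
    temperature_K = if (uses_T) vapply(rows, `[[`, numeric(1), "temp")
                    else NA_real_,
    label = label
  )
  ds <- des_dataset(df, property)
  attr(ds, "latent") <- lat
  ds
}
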