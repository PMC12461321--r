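# small trained model set shared across screening tests
screening_fixture <- function(n_compounds = 12, n_rows = 70, seed = 51) {
  spec <- synthetic_spec(n_compounds = n_compounds, seed = seed)
  profiles <- gen_profiles(spec)
  models <- lapply(stats::setNames(nm = c("density", "viscosity",
                                          "melting_temperature")),
                   function(p) {
    ds <- gen_dataset(spec, p, n_rows, profiles)
    X <- featurize_dataset(ds, profiles)
    train_gp(X, ds$label, "M32", seed = 1, n_restarts = 1, property = p)
  })
  list(spec = spec, profiles = profiles, models = models)
}

test_that("binary 1:1 enumeration matches the closed form and brute force", {
  expect_equal(nrow(enumerate_binary(c("a", "b"))), 1)

  ids <- sprintf("c%02d", 1:10)
  pairs <- enumerate_binary(ids)
  # brute-force double loop oracle
  brute <- 0L
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) brute <- brute + 1L
  expect_equal(nrow(pairs), brute)
  expect_true(all(pairs$comp_a < pairs$comp_b))   # canonical order, no self-pairs
  expect_equal(anyDuplicated(paste(pairs$comp_a, pairs$comp_b)), 0L)

  for (n in c(2, 17, 101, 400)) {
    expect_equal(nrow(enumerate_binary(sprintf("x%03d", 1:n))), n * (n - 1) / 2)
  }
  expect_error(enumerate_binary(c("a", "a")), class = "desgp_validation_error")
})

test_that("screening predicts all properties at 298 K with hard gates", {
  fx <- screening_fixture()
  cand <- enumerate_binary(names(fx$profiles))
  res <- screen_candidates(fx$models, fx$profiles, cand)
  expect_equal(nrow(res), choose(12, 2))
  expect_true(all(res$density > 0))
  expect_true(all(res$viscosity > 0))
  expect_identical(res$liquid_275, res$melting_temperature < 275)
  expect_identical(res$liquid_300, res$melting_temperature < 300)

  # batched evaluation equals one-at-a-time prediction
  one <- purrr::map_dfr(seq_len(5), function(i) {
    sub <- screen_candidates(fx$models, fx$profiles, cand[i, ])
    tibble::as_tibble(sub)[, c("density", "viscosity", "melting_temperature")]
  })
  expect_equal(one$density, res$density[1:5], tolerance = 1e-10)
  expect_equal(one$viscosity, res$viscosity[1:5], tolerance = 1e-10)
  expect_equal(one$melting_temperature, res$melting_temperature[1:5],
               tolerance = 1e-10)

  # candidates with missing profiles are skipped with a warning, not fatal
  cand_bad <- dplyr::bind_rows(cand[1:3, ],
                               tibble::tibble(comp_a = "ghost", comp_b = "syn001"))
  expect_warning(res_bad <- screen_candidates(fx$models, fx$profiles, cand_bad),
                 "skipped")
  expect_equal(nrow(res_bad), 3)
  expect_equal(nrow(attr(res_bad, "skipped")), 1)
})

test_that("candidates with identical profile content predict identically", {
  # two partners with bit-identical profiles occupy the same point in
  # descriptor space, so pairing either with the same compound is equivalent
  fx <- screening_fixture(n_compounds = 6)
  profiles <- fx$profiles
  twinned <- sigma_profile("twin1", profiles[[2]]$values)
  profiles[["twin1"]] <- twinned
  other <- profiles[[1]]$compound_id
  cand <- tibble::tibble(comp_a = c(other, other),
                         comp_b = c(profiles[[2]]$compound_id, "twin1"))
  res <- screen_candidates(fx$models, profiles, cand)
  expect_equal(res$melting_temperature[1], res$melting_temperature[2],
               tolerance = 1e-10)
  expect_equal(res$density[1], res$density[2], tolerance = 1e-10)
  expect_equal(res$viscosity[1], res$viscosity[2], tolerance = 1e-10)
})

test_that("selection respects gates, availability and dominance", {
  fx <- screening_fixture()
  cand <- enumerate_binary(names(fx$profiles))
  res <- screen_candidates(fx$models, fx$profiles, cand)

  for (mode in c("low", "high")) {
    gate <- c(low = 275, high = 300)[[mode]]
    sel <- select_candidates(res, mode, top_k = 1e6)
    expect_true(all(sel$melting_temperature < gate))
  }

  # availability restriction
  avail <- names(fx$profiles)[1:4]
  sel_a <- select_candidates(res, "high", availability = avail, top_k = 1e6)
  expect_true(all(sel_a$comp_a %in% avail & sel_a$comp_b %in% avail))
  expect_warning(sel_none <- select_candidates(res, "low",
                                               availability = "nothing"),
                 "no candidates")
  expect_equal(nrow(sel_none), 0)

  # ranking invariant to input order
  perm <- withr::with_seed(1, sample(nrow(res)))
  res_perm <- structure(res[perm, ], class = class(res),
                        gates = attr(res, "gates"), temperature = 298)
  s1 <- select_candidates(res, "low", top_k = 5)
  s2 <- select_candidates(res_perm, "low", top_k = 5)
  expect_equal(s1$comp_a, s2$comp_a)
  expect_equal(s1$comp_b, s2$comp_b)
})

test_that("a strictly dominating candidate ranks first under any scalarization", {
  # synthetic screen where candidate d1 dominates in both objectives
  df <- tibble::tibble(
    comp_a = c("d1", "d2", "d3", "d4"), comp_b = c("z1", "z2", "z3", "z4"),
    density = c(0.8, 0.9, 1.0, 1.1),
    density_sd = 0.01, viscosity = c(1, 5, 3, 10), viscosity_sd = 0.1,
    melting_temperature = c(250, 250, 250, 250), melting_temperature_sd = 1,
    liquid_275 = TRUE, liquid_300 = TRUE
  )
  res <- structure(df, class = c("des_screen", class(df)),
                   gates = c(low = 275, high = 300), temperature = 298)
  for (method in c("rank_sum", "pareto")) {
    sel <- select_candidates(res, "low", method = method)
    expect_equal(sel$comp_a[1], "d1")
  }
  # conservative gating uses mean + 1.96 sd
  df2 <- df
  df2$melting_temperature <- c(274, 250, 250, 250)
  df2$melting_temperature_sd <- c(10, 0.1, 0.1, 0.1)
  res2 <- structure(df2, class = class(res), gates = attr(res, "gates"),
                    temperature = 298)
  sel2 <- select_candidates(res2, "low", conservative = TRUE, top_k = 10)
  expect_false("d1" %in% sel2$comp_a)
})

test_that("screening output writes a CSV with a JSON mirror", {
  fx <- screening_fixture(n_compounds = 6)
  res <- screen_candidates(fx$models, fx$profiles,
                           enumerate_binary(names(fx$profiles)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_screen(res, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(res))
  js <- jsonlite::read_json(sub("csv$", "json", f), simplifyVector = TRUE)
  expect_equal(js$density, res$density, tolerance = 1e-12)
})
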