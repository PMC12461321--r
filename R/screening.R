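#' Enumerate the binary 1:1 design space
#'
#' All unordered pairs of distinct precursors, in canonical (lexicographic)
#' order within each pair and sorted deterministically overall. With the 342
#' precursors of the reference compound library this is
#' \eqn{\binom{342}{2} = 58{,}311} candidate DESs.
#'
#' @param precursor_ids Character vector of unique compound ids.
#' @return Tibble with columns `comp_a`, `comp_b` (`comp_a < comp_b`).
#' @export
#' @examples
#' nrow(enumerate_binary(letters[1:10]))  # choose(10, 2) = 45
enumerate_binary <- function(precursor_ids) {
  ids <- as.character(precursor_ids)
  if (anyDuplicated(ids)) {
    abort("precursor ids must be unique.", class = "desgp_validation_error")
  }
  if (length(ids) < 2) {
    abort("need at least two precursors to enumerate pairs.",
          class = "desgp_validation_error")
  }
  ids <- sort(ids, method = "radix")
  pairs <- utils::combn(ids, 2)
  tibble::tibble(comp_a = pairs[1, ], comp_b = pairs[2, ])
}

#' Screen candidate DESs with trained property models
#'
#' Featurises every candidate pair at equimolar composition
#' (\eqn{x = 0.5, 0.5}) and predicts all three properties: density and
#' viscosity at the screening temperature (298 K by default, appended as the
#' 184th feature) and melting temperature from the 183-entry composition
#' descriptor alone. Evaluation is batched; batching is a pure
#' implementation detail and agrees with one-at-a-time prediction to
#' 1e-10. Candidates with a missing profile are skipped and reported, not
#' fatal.
#'
#' @param models Named list of `des_gp` models: `density`, `viscosity`,
#'   `melting_temperature`.
#' @param profiles Profile library.
#' @param candidates Tibble from [enumerate_binary()] (columns `comp_a`,
#'   `comp_b`).
#' @param temperature Screening temperature (K).
#' @return A `des_screen` tibble: pair ids, predicted `density`,
#'   `viscosity`, `melting_temperature`, their standard uncertainties
#'   (`*_sd`), and the liquidity gate flags `liquid_275` / `liquid_300`.
#'   Skipped candidates are in `attr(, "skipped")`.
#' @export
screen_candidates <- function(models, profiles, candidates,
                              temperature = 298) {
  need <- c("density", "viscosity", "melting_temperature")
  if (!all(need %in% names(models))) {
    abort("screening needs density, viscosity and melting_temperature models.",
          class = "desgp_config_error")
  }
  known <- names(profiles)
  ok <- candidates$comp_a %in% known & candidates$comp_b %in% known
  skipped <- candidates[!ok, , drop = FALSE]
  if (nrow(skipped)) {
    warn(sprintf("%d candidate(s) skipped: missing sigma profiles.",
                 nrow(skipped)))
  }
  cand <- candidates[ok, , drop = FALSE]
  if (!nrow(cand)) {
    abort("no screenable candidates (all profiles missing).",
          class = "desgp_data_error")
  }
  specs <- purrr::map2(cand$comp_a, cand$comp_b,
                       ~ mixture_spec(c(.x, .y), c(0.5, 0.5)))
  X183 <- t(vapply(specs, function(s) featurize_mixture(profiles, s),
                   numeric(183)))
  X184 <- cbind(X183, temperature)

  pr_d <- predict(models$density, X184)
  pr_v <- predict(models$viscosity, X184)
  pr_m <- predict(models$melting_temperature, X183)

  out <- dplyr::mutate(cand,
    density = pr_d$.pred, density_sd = sqrt(pr_d$.pred_var),
    viscosity = pr_v$.pred, viscosity_sd = sqrt(pr_v$.pred_var),
    melting_temperature = pr_m$.pred,
    melting_temperature_sd = sqrt(pr_m$.pred_var),
    liquid_275 = .data$melting_temperature < 275,
    liquid_300 = .data$melting_temperature < 300
  )
  structure(out, class = c("des_screen", class(out)),
            temperature = temperature,
            gates = c(low = 275, high = 300),
            skipped = skipped)
}

#' Select and rank screened candidates
#'
#' Applies the liquidity gate, then ranks by a bi-objective rule over
#' predicted density and viscosity. `"low"` mode keeps candidates predicted
#' liquid below 275 K and seeks minimal density and viscosity (energy-saving
#' lubricants); `"high"` mode keeps those liquid below 300 K and seeks
#' maximal density and viscosity (heavy-load film strength). The default
#' scalarisation is the rank sum of the two objectives, with viscosity
#' ranked on the log scale given its multi-decade range; `method = "pareto"`
#' instead returns the non-dominated front (rank 1), then successive fronts.
#' Ties are broken by pair ids, so ranking is deterministic and independent
#' of input order.
#'
#' @param result A `des_screen`.
#' @param mode `"low"` or `"high"`.
#' @param availability Optional vector of available compound ids; candidates
#'   are kept only when both components are available.
#' @param top_k Number of candidates to return.
#' @param method `"rank_sum"` or `"pareto"`.
#' @param conservative Gate on mean + 1.96 sd of melting temperature instead
#'   of the mean alone.
#' @return Tibble of the top candidates with a `rank` column.
#' @export
select_candidates <- function(result, mode = c("low", "high"),
                              availability = NULL, top_k = 10,
                              method = c("rank_sum", "pareto"),
                              conservative = FALSE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(result, "des_screen"))
  gate <- attr(result, "gates")[[mode]]
  tm <- result$melting_temperature +
    if (conservative) 1.96 * result$melting_temperature_sd else 0
  keep <- tm < gate
  if (!is.null(availability)) {
    keep <- keep & result$comp_a %in% availability &
      result$comp_b %in% availability
  }
  cand <- tibble::as_tibble(result[keep, , drop = FALSE])
  if (!nrow(cand)) {
    warn("no candidates pass the gate/availability filter.")
    return(dplyr::mutate(cand, rank = integer()))
  }
  sgn <- if (mode == "low") 1 else -1
  obj1 <- sgn * cand$density
  obj2 <- sgn * log(cand$viscosity)
  score <- if (method == "rank_sum") {
    rank(obj1, ties.method = "min") + rank(obj2, ties.method = "min")
  } else {
    pareto_fronts(cbind(obj1, obj2))
  }
  ord <- order(score, cand$comp_a, cand$comp_b, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  head(cand, top_k)
}

# front index per point (1 = non-dominated), minimization in all columns
pareto_fronts <- function(M) {
  n <- nrow(M)
  front <- integer(n)
  remaining <- seq_len(n)
  f <- 0L
  while (length(remaining)) {
    f <- f + 1L
    dom <- vapply(remaining, function(i) {
      any(vapply(remaining, function(j) {
        j != i && all(M[j, ] <= M[i, ]) && any(M[j, ] < M[i, ])
      }, logical(1)))
    }, logical(1))
    front[remaining[!dom]] <- f
    remaining <- remaining[dom]
  }
  front
}

#' Write screening output as CSV + JSON mirror
#' @param result A `des_screen` (or selection thereof).
#' @param path CSV path; a `.json` sibling is written alongside.
#' @export
write_screen <- function(result, path) {
  df <- as.data.frame(result)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(df, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}
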