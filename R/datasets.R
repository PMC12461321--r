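des_properties <- c("density", "viscosity", "melting_temperature")

property_uses_temperature <- function(property) {
  property %in% c("density", "viscosity")
}

#' Property dataset container
#'
#' A `des_dataset` is a tibble of mixtures and labels with a fixed column
#' layout: `comp1, comp2, comp3` (component ids, `NA` when unused),
#' `x1, x2, x3` (mole fractions, `NA` when unused), `temperature_K`
#' (`NA` for melting-temperature data) and `label`. Units are g/mL for
#' density, cP for viscosity and K for melting temperature. Density and
#' viscosity datasets carry a temperature on every row; melting-temperature
#' datasets carry none.
#'
#' @param df Data frame with the columns above (missing ones are added).
#' @param property One of `"density"`, `"viscosity"`,
#'   `"melting_temperature"`.
#' @return A validated `des_dataset` tibble.
#' @export
des_dataset <- function(df, property = des_properties) {
  property <- match.arg(property)
  df <- tibble::as_tibble(df)
  for (col in c("comp2", "comp3")) if (!col %in% names(df)) df[[col]] <- NA_character_
  for (col in c("x2", "x3")) if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"temperature_K" %in% names(df)) df$temperature_K <- NA_real_
  req <- c("comp1", "x1", "label")
  if (!all(req %in% names(df))) {
    abort("dataset needs at least comp1, x1 and label columns.",
          class = "desgp_format_error")
  }
  df <- df[, c("comp1", "comp2", "comp3", "x1", "x2", "x3",
               "temperature_K", "label")]
  uses_T <- property_uses_temperature(property)
  bad <- validate_dataset_rows(df, property)
  if (any(nzchar(bad))) {
    abort(paste0("invalid dataset rows: ",
                 paste(which(nzchar(bad)), collapse = ", ")),
          class = "desgp_validation_error")
  }
  structure(df, class = c("des_dataset", class(df)),
            property = property, uses_temperature = uses_T)
}

# per-row reason string; "" = valid
validate_dataset_rows <- function(df, property) {
  uses_T <- property_uses_temperature(property)
  vapply(seq_len(nrow(df)), function(i) {
    comps <- c(df$comp1[i], df$comp2[i], df$comp3[i])
    xs <- c(df$x1[i], df$x2[i], df$x3[i])
    keep <- !is.na(comps) & comps != ""
    if (!any(keep)) return("no components")
    if (any(is.na(xs[keep]))) return("missing fraction")
    if (any(xs[keep] <= 0)) return("nonpositive fraction")
    if (abs(sum(xs[keep]) - 1) > 1e-9) return("fractions do not sum to 1")
    if (anyDuplicated(comps[keep])) return("duplicate component")
    if (uses_T && (is.na(df$temperature_K[i]) || df$temperature_K[i] <= 0)) {
      return("missing temperature")
    }
    if (!is.finite(df$label[i])) return("non-finite label")
    if (property %in% c("density", "viscosity") && df$label[i] <= 0) {
      return("nonpositive label")
    }
    ""
  }, character(1))
}

# des_dataset rows as a list of mixture_spec
dataset_mixtures <- function(ds) {
  uses_T <- attr(ds, "uses_temperature")
  lapply(seq_len(nrow(ds)), function(i) {
    comps <- c(ds$comp1[i], ds$comp2[i], ds$comp3[i])
    xs <- c(ds$x1[i], ds$x2[i], ds$x3[i])
    keep <- !is.na(comps) & comps != ""
    mixture_spec(comps[keep], xs[keep],
                 temperature = if (uses_T) ds$temperature_K[i] else NULL)
  })
}

#' Load a property dataset from a delimited file
#'
#' Reads the CSV layout of [des_dataset()], validates each row (fractions sum
#' to one, component ids resolvable in the profile library, temperature
#' present iff the property needs it) and returns the accepted rows.
#' Rejected rows are not silently dropped: they are attached as a rejection
#' report (`attr(ds, "rejections")`, a tibble of row numbers and reasons).
#'
#' @param source CSV path (or data frame already in the layout).
#' @param property Property name.
#' @param profiles Optional profile library; when given, rows whose ids have
#'   no profile are rejected with reason `"unknown compound"`.
#' @return A `des_dataset` with a `rejections` attribute.
#' @export
load_dataset <- function(source, property = des_properties, profiles = NULL) {
  property <- match.arg(property)
  df <- if (is.data.frame(source)) {
    tibble::as_tibble(source)
  } else {
    tibble::as_tibble(utils::read.csv(source, stringsAsFactors = FALSE))
  }
  for (col in c("comp2", "comp3")) if (!col %in% names(df)) df[[col]] <- NA_character_
  for (col in c("x2", "x3")) if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"temperature_K" %in% names(df)) df$temperature_K <- NA_real_
  df$comp1 <- as.character(df$comp1)
  df$comp2 <- as.character(df$comp2)
  df$comp3 <- as.character(df$comp3)
  df <- df[, c("comp1", "comp2", "comp3", "x1", "x2", "x3",
               "temperature_K", "label")]
  for (col in c("comp1", "comp2", "comp3")) {
    blank <- !is.na(df[[col]]) & df[[col]] == ""
    df[[col]][blank] <- NA_character_
  }

  reason <- validate_dataset_rows(df, property)
  if (!is.null(profiles)) {
    known <- names(profiles)
    for (i in which(!nzchar(reason))) {
      comps <- c(df$comp1[i], df$comp2[i], df$comp3[i])
      comps <- comps[!is.na(comps)]
      if (!all(comps %in% known)) reason[i] <- "unknown compound"
    }
  }
  keep <- !nzchar(reason)
  if (!any(keep)) {
    abort("no valid rows in dataset.", class = "desgp_data_error")
  }
  rejections <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  ds <- des_dataset(df[keep, , drop = FALSE], property)
  attr(ds, "rejections") <- rejections
  ds
}

#' Write a property dataset as CSV
#' @param ds A `des_dataset`.
#' @param path Output path.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(ds)
}

#' Stratified three-way hold-out split
#'
#' Splits a dataset into training, validation and test sets (default
#' 70/20/10) so each set is representative of the full label distribution:
#' labels are binned into `n_strata` equal-frequency (quantile) bins and the
#' split fractions are applied within every bin, using largest-remainder
#' rounding so realized counts are exact to within one row per stratum.
#' Rows are shuffled within bins under `seed`, making the split deterministic
#' and reproducible.
#'
#' @param ds A `des_dataset` (or any data frame with a `label` column).
#' @param fractions Named or ordered train/validation/test fractions, sum 1.
#' @param n_strata Number of quantile bins of the label.
#' @param seed Integer seed.
#' @return A `des_split` with integer index vectors `$train`, `$validation`,
#'   `$test`.
#' @export
stratified_split <- function(ds, fractions = c(train = 0.7, validation = 0.2,
                                               test = 0.1),
                             n_strata = 10, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3) {
    abort("split fractions must be three values summing to 1.",
          class = "desgp_config_error")
  }
  labels <- ds$label
  n <- length(labels)
  n_strata <- max(1L, min(as.integer(n_strata), n))
  qs <- quantile(labels, probs = seq(0, 1, length.out = n_strata + 1),
                 type = 7, names = FALSE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs)
  stratum <- cut(labels, breaks = qs, labels = FALSE, include.lowest = TRUE)

  idx <- list(train = integer(), validation = integer(), test = integer())
  withr::with_seed(as.integer(seed), {
    for (s in sort(unique(stratum))) {
      rows <- which(stratum == s)
      rows <- rows[sample.int(length(rows))]
      counts <- largest_remainder(length(rows), fractions)
      splits <- rep(1:3, times = counts)
      idx$train <- c(idx$train, rows[splits == 1])
      idx$validation <- c(idx$validation, rows[splits == 2])
      idx$test <- c(idx$test, rows[splits == 3])
    }
  })
  structure(
    list(train = sort(idx$train), validation = sort(idx$validation),
         test = sort(idx$test),
         fractions = fractions, n_strata = n_strata, seed = as.integer(seed)),
    class = "des_split"
  )
}

# integer allocation of n across fractions, largest remainder method
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' @export
print.des_split <- function(x, ...) {
  cat(sprintf("<des_split: %d train / %d validation / %d test, %d strata, seed %d>\n",
              length(x$train), length(x$validation), length(x$test),
              x$n_strata, x$seed))
  invisible(x)
}

#' Regression metrics for property predictions
#'
#' Computes the coefficient of determination
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}, the mean absolute
#' error in label units and, for viscosity, the mean absolute logarithmic
#' error \eqn{MALE = mean\,\lvert\log_{10} y - \log_{10}\hat y\rvert}.
#' Because viscosity spans many orders of magnitude, it is analysed on the
#' logarithmic scale: its \eqn{R^2} is computed on \eqn{\log_{10}} values
#' (raw-scale \eqn{R^2} would reflect only the few largest labels), while
#' MAE remains in raw label units.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @param property Property name; MALE is reported only for viscosity.
#' @return One-row tibble with `r2`, `mae` and (viscosity) `male`.
#' @export
evaluate_predictions <- function(predicted, observed,
                                 property = des_properties) {
  property <- match.arg(property)
  if (length(predicted) != length(observed) || length(observed) < 2) {
    abort("evaluate needs equal-length vectors of length >= 2.",
          class = "desgp_validation_error")
  }
  if (property == "viscosity") {
    obs_s <- log10(observed)
    pred_s <- log10(pmax(predicted, 1e-12))
  } else {
    obs_s <- observed
    pred_s <- predicted
  }
  ss_res <- sum((obs_s - pred_s)^2)
  ss_tot <- sum((obs_s - mean(obs_s))^2)
  r2 <- if (ss_tot == 0) {
    warn("zero label variance: R^2 is undefined.")
    NaN
  } else 1 - ss_res / ss_tot
  # residuals in raw label units regardless of the R^2 scale
  out <- tibble::tibble(
    property = property,
    r2 = r2,
    mae = mean(abs(observed - predicted))
  )
  if (property == "viscosity") {
    out$male <- mean(abs(log10(observed) - log10(pmax(predicted, 1e-12))))
  }
  out
}

#' Kernel x normalisation benchmark grid
#'
#' Fits one GP per combination of kernel family (RBF, RQ, M32) and label
#' normalisation (none, standardise, log-standardise) — nine fits per
#' property — on the training split only, and scores each on the validation
#' split. Feature normalisation is held at log-standardisation, the setting
#' retained for final models; `extended = TRUE` crosses feature normalisation
#' too (27 cells). A fit that errors is recorded as a failed cell rather
#' than aborting the grid.
#'
#' @param ds A `des_dataset`.
#' @param split A [stratified_split()] of `ds`.
#' @param profiles Profile library for featurisation.
#' @param seed Seed forwarded to every fit.
#' @param extended Cross feature normalisation as well?
#' @param n_restarts Optimiser restarts per fit.
#' @return Tibble with one row per cell, sorted by validation `r2`
#'   (descending; ties by kernel name), columns `kernel`, `label_norm`,
#'   `feature_norm`, `r2`, `mae`, `male` (viscosity), `status`.
#' @export
benchmark_grid <- function(ds, split, profiles, seed = 1L, extended = FALSE,
                           n_restarts = 2) {
  property <- attr(ds, "property")
  X <- featurize_dataset(ds, profiles)
  y <- ds$label
  label_ok_log <- all(y >= 0)
  feature_modes <- if (extended) c("none", "standardize", "log_standardize")
                   else "log_standardize"
  cells <- tidyr::expand_grid(
    kernel = c("M32", "RBF", "RQ"),
    label_norm = c("none", "standardize", "log_standardize"),
    feature_norm = feature_modes
  )
  res <- purrr::pmap(cells, function(kernel, label_norm, feature_norm) {
    if (label_norm == "log_standardize" && !label_ok_log) {
      return(list(r2 = NA_real_, mae = NA_real_, male = NA_real_,
                  status = "failed: negative labels"))
    }
    fit <- tryCatch(
      train_gp(X[split$train, , drop = FALSE], y[split$train],
               family = kernel, feature_mode = feature_norm,
               label_mode = label_norm, seed = seed,
               n_restarts = n_restarts, property = property),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(list(r2 = NA_real_, mae = NA_real_, male = NA_real_,
                  status = paste0("failed: ", conditionMessage(fit))))
    }
    pr <- predict(fit, X[split$validation, , drop = FALSE])
    m <- evaluate_predictions(pr$.pred, y[split$validation], property)
    list(r2 = m$r2, mae = m$mae,
         male = if ("male" %in% names(m)) m$male else NA_real_,
         status = "ok")
  })
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  out$property <- property
  dplyr::arrange(out, dplyr::desc(.data$r2), .data$kernel)
}
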