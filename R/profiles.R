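#' Construct a sigma profile
#'
#' A sigma profile is a compound's unnormalised polarity histogram: for each
#' of the 61 screened-charge-density bins it stores \eqn{P(\sigma) \cdot A},
#' the surface area (in \ifelse{html}{\out{&Aring;}}{A}\eqn{^2}) carrying
#' charge density \eqn{\sigma}. The sum over bins is the compound's total
#' COSMO cavity surface area.
#'
#' @param compound_id Character identifier (used to resolve dataset rows).
#' @param values Numeric vector of 61 nonnegative bin areas (A^2).
#' @param grid A [sigma_grid()]; only the canonical grid is accepted.
#'
#' @return A `des_sigma_profile` object with fields `compound_id`, `grid`,
#'   `values` and `total_area`.
#' @export
#' @examples
#' p <- sigma_profile("water-ish", dnorm(sigma_grid()$centers, 0, 0.005))
#' p$total_area
sigma_profile <- function(compound_id, values, grid = sigma_grid()) {
  values <- as.numeric(values)
  if (length(values) != grid$n_bins) {
    abort(
      sprintf("sigma profile '%s' has %d values; the grid has %d bins.",
              compound_id, length(values), grid$n_bins),
      class = "desgp_format_error"
    )
  }
  if (anyNA(values) || any(values < 0)) {
    abort(
      sprintf("sigma profile '%s' contains negative or missing bin areas.", compound_id),
      class = "desgp_validation_error"
    )
  }
  structure(
    list(
      compound_id = as.character(compound_id),
      grid = grid,
      values = values,
      total_area = sum(values)
    ),
    class = "des_sigma_profile"
  )
}

#' @export
print.des_sigma_profile <- function(x, ...) {
  cat(sprintf("<sigma profile '%s': total area %.3f A^2 over %d bins>\n",
              x$compound_id, x$total_area, x$grid$n_bins))
  invisible(x)
}

#' Read a sigma profile from two-column text
#'
#' Parses the plain-text interchange format used by most sigma-profile
#' distributions: an optional `#`-prefixed header, then exactly 61 rows of
#' `sigma  P(sigma)*A`, whitespace- or comma-delimited. The sigma column must
#' match the canonical grid of [sigma_grid()] to within `1e-9`.
#'
#' @param source Path to a file, or a connection.
#' @param compound_id Identifier for the profile; defaults to the file stem.
#' @param grid Expected [sigma_grid()].
#'
#' @return A `des_sigma_profile`.
#' @export
read_sigma_profile <- function(source, compound_id = NULL, grid = sigma_grid()) {
  if (is.character(source) && is.null(compound_id)) {
    compound_id <- sub("\\.[^.]*$", "", basename(source))
  }
  if (is.null(compound_id)) compound_id <- "profile"
  lines <- readLines(source, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) != grid$n_bins) {
    abort(
      sprintf("'%s': expected %d data rows, found %d.",
              compound_id, grid$n_bins, length(lines)),
      class = "desgp_format_error"
    )
  }
  fields <- strsplit(lines, "[,[:space:]]+")
  mat <- vapply(fields, function(f) {
    f <- f[nzchar(f)]
    if (length(f) < 2) c(NA_real_, NA_real_) else as.numeric(f[1:2])
  }, numeric(2))
  sigma <- mat[1, ]
  areas <- mat[2, ]
  if (anyNA(sigma) || anyNA(areas)) {
    abort(sprintf("'%s': non-numeric rows in sigma-profile file.", compound_id),
          class = "desgp_format_error")
  }
  bad <- grid_mismatch_index(sigma, grid)
  if (bad != 0L) {
    abort(
      sprintf("'%s': sigma value %.6g at row %d is off the canonical grid (expected %.6g).",
              compound_id, sigma[bad], bad, grid$centers[bad]),
      class = "desgp_grid_error"
    )
  }
  sigma_profile(compound_id, areas, grid)
}

#' Write a sigma profile as two-column text
#'
#' Emits the format accepted by [read_sigma_profile()] (one `#` header line,
#' 61 data rows) at full double precision, so a write/read round trip
#' reproduces the profile bit-for-bit.
#'
#' @param profile A `des_sigma_profile`.
#' @param sink File path or connection.
#' @export
write_sigma_profile <- function(profile, sink) {
  stopifnot(inherits(profile, "des_sigma_profile"))
  header <- sprintf("# sigma profile: %s (sigma e/A^2, P(sigma)*A A^2)",
                    profile$compound_id)
  rows <- sprintf("%.17g %.17g", profile$grid$centers, profile$values)
  writeLines(c(header, rows), sink)
  invisible(profile)
}

#' Read a directory of sigma profiles
#'
#' Every regular file in `dir` (optionally filtered by `pattern`) is parsed
#' with [read_sigma_profile()]; the filename stem becomes the compound id.
#'
#' @param dir Directory path.
#' @param pattern Optional filename regexp (default: `*.sigma` and `*.txt`).
#' @return A named list of `des_sigma_profile` objects (a "profile library").
#' @export
read_profile_library <- function(dir, pattern = "\\.(sigma|txt)$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) {
    abort(sprintf("no sigma-profile files found in '%s'.", dir),
          class = "desgp_format_error")
  }
  profs <- lapply(files, read_sigma_profile)
  names(profs) <- vapply(profs, `[[`, character(1), "compound_id")
  profs
}

#' Write a profile library to a directory
#' @param profiles Named list of `des_sigma_profile`.
#' @param dir Output directory (created if missing).
#' @export
write_profile_library <- function(profiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in profiles) {
    write_sigma_profile(p, file.path(dir, paste0(p$compound_id, ".sigma")))
  }
  invisible(profiles)
}

#' Specify a mixture
#'
#' A mixture is 1 to 3 components with strictly positive mole fractions
#' summing to one, and (for temperature-dependent properties) a temperature
#' in Kelvin.
#'
#' @param components Character vector of 1-3 compound ids.
#' @param fractions Numeric mole fractions, same length, summing to 1.
#' @param temperature Optional temperature in K.
#' @return A `des_mixture` list.
#' @export
#' @examples
#' mixture_spec(c("ChCl", "urea"), c(1, 2) / 3, temperature = 298)
mixture_spec <- function(components, fractions, temperature = NULL) {
  components <- as.character(components)
  fractions <- as.numeric(fractions)
  n <- length(components)
  if (n < 1 || n > 3 || length(fractions) != n) {
    abort("a mixture has 1-3 components with one mole fraction each.",
          class = "desgp_validation_error")
  }
  if (anyNA(fractions) || any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    abort("mole fractions must be positive and sum to 1 (tol 1e-9).",
          class = "desgp_validation_error")
  }
  if (anyDuplicated(components)) {
    abort("duplicate component ids in mixture.", class = "desgp_validation_error")
  }
  if (!is.null(temperature)) {
    temperature <- as.numeric(temperature)
    if (!is.finite(temperature) || temperature <= 0) {
      abort("temperature must be a positive Kelvin value.",
            class = "desgp_validation_error")
    }
  }
  structure(
    list(components = components, fractions = fractions, temperature = temperature),
    class = "des_mixture"
  )
}

# canonical slot order: descending mole fraction, ties by compound id.
# Deterministic and permutation-invariant.
canonical_order <- function(components, fractions) {
  order(-fractions, components, method = "radix")
}

#' Build the concatenated mixture descriptor
#'
#' The feature vector of a DES is the concatenation of the sigma profiles of
#' its components, each weighted by its mole fraction:
#' \deqn{SP = [SP_1 x_1, SP_2 x_2, SP_3 x_3]}
#' giving 183 entries (3 blocks of 61). Mixtures with fewer than three
#' components leave the trailing blocks at zero (an implied \eqn{x = 0}
#' component), so unary, binary and ternary systems share one feature space.
#' If the mixture carries a temperature, it is appended raw (Kelvin) as a
#' 184th entry; scaling is the model's concern, not the descriptor's.
#'
#' Components are placed into slots in canonical order (descending mole
#' fraction, ties broken by compound id) so the descriptor is invariant to
#' the order components are listed in.
#'
#' @param profiles Named list of `des_sigma_profile` (a profile library).
#' @param spec A [mixture_spec()].
#' @return Numeric vector of length 183 (no temperature) or 184.
#' @export
featurize_mixture <- function(profiles, spec) {
  stopifnot(inherits(spec, "des_mixture"))
  missing <- setdiff(spec$components, names(profiles))
  if (length(missing)) {
    abort(sprintf("no sigma profile for: %s", paste(missing, collapse = ", ")),
          class = "desgp_lookup_error")
  }
  grid <- sigma_grid()
  ord <- canonical_order(spec$components, spec$fractions)
  out <- numeric(3 * grid$n_bins)
  for (slot in seq_along(ord)) {
    i <- ord[slot]
    p <- profiles[[spec$components[i]]]
    if (!inherits(p, "des_sigma_profile") || p$grid$n_bins != grid$n_bins ||
        grid_mismatch_index(p$grid$centers, grid) != 0L) {
      abort(sprintf("profile '%s' is not on the canonical grid.", spec$components[i]),
            class = "desgp_grid_error")
    }
    idx <- (slot - 1L) * grid$n_bins + seq_len(grid$n_bins)
    out[idx] <- spec$fractions[i] * p$values
  }
  if (!is.null(spec$temperature)) out <- c(out, spec$temperature)
  out
}

#' Featurize a property dataset into a design matrix
#'
#' Applies [featurize_mixture()] to every row of a `des_dataset`, returning
#' the n x 183 (melting temperature) or n x 184 (density, viscosity) design
#' matrix the GP consumes.
#'
#' @param ds A `des_dataset` (see [des_dataset()]).
#' @param profiles Profile library.
#' @return Numeric matrix.
#' @export
featurize_dataset <- function(ds, profiles) {
  stopifnot(inherits(ds, "des_dataset"))
  specs <- dataset_mixtures(ds)
  X <- t(vapply(specs, function(s) featurize_mixture(profiles, s),
                numeric(if (attr(ds, "uses_temperature")) 184L else 183L)))
  X
}
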