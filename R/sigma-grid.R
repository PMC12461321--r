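#' The canonical sigma-profile discretisation
#'
#' COSMO-RS sigma profiles in this package live on the standard COSMOtherm
#' grid: 61 bins whose centres run from \eqn{-0.030} to \eqn{+0.030}
#' e\eqn{\cdot}{.}\ifelse{html}{\out{&Aring;}}{A}\eqn{^{-2}} in steps of
#' 0.001. This is the only common convention that yields a 61-entry
#' per-compound descriptor, and it is fixed package-wide: every profile read,
#' written or generated is validated against it.
#'
#' @param start First bin centre, screened charge density (e/A^2).
#' @param step Bin width (e/A^2).
#' @param n_bins Number of bins.
#'
#' @return A `des_sigma_grid` list with fields `start`, `step`, `n_bins` and
#'   the precomputed `centers`.
#' @export
#' @examples
#' g <- sigma_grid()
#' range(g$centers)
sigma_grid <- function(start = -0.030, step = 0.001, n_bins = 61L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L || step <= 0) {
    abort("sigma_grid needs n_bins >= 2 and a positive step.", class = "desgp_grid_error")
  }
  centers <- start + step * (seq_len(n_bins) - 1)
  structure(
    list(start = start, step = step, n_bins = n_bins, centers = centers),
    class = "des_sigma_grid"
  )
}

#' @export
print.des_sigma_grid <- function(x, ...) {
  cat(sprintf(
    "<sigma grid: %d bins, %g to %g e/A^2, step %g>\n",
    x$n_bins, x$centers[1], x$centers[x$n_bins], x$step
  ))
  invisible(x)
}

# check a sigma column against the canonical centres; returns index of first
# offender or 0L
grid_mismatch_index <- function(sigma, grid = sigma_grid(), tol = 1e-9) {
  if (length(sigma) != grid$n_bins) return(-1L)
  bad <- which(abs(sigma - grid$centers) > tol)
  if (length(bad)) bad[1] else 0L
}
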