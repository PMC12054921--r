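#' Complex permittivity spectrum
#'
#' Real and imaginary parts of the relative permittivity sampled on a
#' wavenumber grid.  For a passive medium `eps_imag >= 0` everywhere.
#'
#' @param grid a [spectral_grid()] or numeric wavenumber vector (cm^-1).
#' @param eps_real,eps_imag numeric vectors matching the grid length.
#' @return an object of class `"dielectric_spectrum"`.
#' @export
dielectric_spectrum <- function(grid, eps_real, eps_imag) {
  grid <- as_grid(grid)
  eps_real <- as.numeric(eps_real); eps_imag <- as.numeric(eps_imag)
  if (length(eps_real) != length(grid) || length(eps_imag) != length(grid))
    stop("eps_real and eps_imag must match the grid length")
  if (anyNA(eps_real) || anyNA(eps_imag) ||
      any(!is.finite(eps_real)) || any(!is.finite(eps_imag)))
    stop("permittivity contains non-finite values")
  if (any(eps_imag < -1e-12))
    stop("eps_imag must be non-negative (passive medium)")
  structure(list(grid = grid, eps_real = eps_real,
                 eps_imag = pmax(eps_imag, 0)),
            class = "dielectric_spectrum")
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf("<dielectric_spectrum> %d points, %.6g .. %.6g cm^-1\n",
              length(x$grid), x$grid[1L], x$grid[length(x$grid)]))
  cat(sprintf("  eps' in [%.4g, %.4g], eps'' in [%.4g, %.4g]\n",
              min(x$eps_real), max(x$eps_real),
              min(x$eps_imag), max(x$eps_imag)))
  invisible(x)
}

#' Complex refractive index spectrum
#'
#' @param grid a [spectral_grid()] or numeric wavenumber vector (cm^-1).
#' @param n_real,n_imag numeric vectors matching the grid length;
#'   `n_real > 0`, `n_imag >= 0`.
#' @return an object of class `"refractive_index_spectrum"`.
#' @export
refractive_index_spectrum <- function(grid, n_real, n_imag) {
  grid <- as_grid(grid)
  n_real <- as.numeric(n_real); n_imag <- as.numeric(n_imag)
  if (length(n_real) != length(grid) || length(n_imag) != length(grid))
    stop("n_real and n_imag must match the grid length")
  if (anyNA(n_real) || anyNA(n_imag) ||
      any(!is.finite(n_real)) || any(!is.finite(n_imag)))
    stop("refractive index contains non-finite values")
  if (any(n_real <= 0)) stop("n_real must be positive")
  if (any(n_imag < -1e-12)) stop("n_imag must be non-negative (passive medium)")
  structure(list(grid = grid, n_real = n_real, n_imag = pmax(n_imag, 0)),
            class = "refractive_index_spectrum")
}

#' @export
print.refractive_index_spectrum <- function(x, ...) {
  cat(sprintf("<refractive_index_spectrum> %d points, %.6g .. %.6g cm^-1\n",
              length(x$grid), x$grid[1L], x$grid[length(x$grid)]))
  cat(sprintf("  n' in [%.4g, %.4g], n'' in [%.4g, %.4g]\n",
              min(x$n_real), max(x$n_real), min(x$n_imag), max(x$n_imag)))
  invisible(x)
}

#' Convert permittivity to complex refractive index
#'
#' Uses the principal square root of the complex permittivity:
#' `n' = sqrt((|eps| + eps')/2)`, `n'' = sqrt((|eps| - eps')/2)` with
#' `|eps| = sqrt(eps'^2 + eps''^2)`.  [n_to_eps()] is the exact algebraic
#' inverse (`eps' = n'^2 - n''^2`, `eps'' = 2 n' n''`).
#'
#' @param eps a [dielectric_spectrum()].
#' @return a [refractive_index_spectrum()] on the same grid.
#' @examples
#' g <- spectral_grid(c(1000, 2000))
#' eps_to_n(dielectric_spectrum(g, c(2.25, 3), c(0, 4)))
#' @export
eps_to_n <- function(eps) {
  stopifnot(inherits(eps, "dielectric_spectrum"))
  nn <- eps_to_n_num(eps$eps_real, eps$eps_imag)
  refractive_index_spectrum(eps$grid, nn$n_real, nn$n_imag)
}

eps_to_n_num <- function(eps_real, eps_imag) {
  mod <- sqrt(eps_real^2 + eps_imag^2)
  list(n_real = sqrt(pmax(mod + eps_real, 0) / 2),
       n_imag = sqrt(pmax(mod - eps_real, 0) / 2))
}

#' Convert complex refractive index to permittivity
#'
#' @param n a [refractive_index_spectrum()].
#' @return a [dielectric_spectrum()] on the same grid.
#' @export
n_to_eps <- function(n) {
  stopifnot(inherits(n, "refractive_index_spectrum"))
  dielectric_spectrum(n$grid, n$n_real^2 - n$n_imag^2, 2 * n$n_real * n$n_imag)
}
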