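#' Spectral grid of wavenumbers
#'
#' A spectral grid is a strictly increasing vector of positive wavenumbers in
#' reciprocal centimetres (cm^-1).  All spectra in the package (permittivity,
#' refractive index, extinction, absorbance) are sampled on such a grid.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1; strictly
#'   increasing, all positive, length at least 2.
#' @return a numeric vector of class `"spectral_grid"`.
#' @examples
#' g <- spectral_grid(seq(500, 4000, length.out = 600))
#' range(g)
#' @export
spectral_grid <- function(wavenumbers) {
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 2L)
    stop("a spectral grid needs at least 2 points")
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop("spectral grid contains non-finite values")
  if (any(wavenumbers <= 0))
    stop("wavenumbers must be positive")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  structure(wavenumbers, class = "spectral_grid")
}

#' Default mid-infrared grid
#'
#' Uniform grid over the mid-IR window used throughout: `n` points from `lo`
#' to `hi` cm^-1.  The default (600 points over 500--4000 cm^-1) matches the
#' mesh density of typical literature dispersion tables.
#'
#' @param lo,hi window limits in cm^-1.
#' @param n number of points.
#' @return a [spectral_grid()].
#' @export
default_grid <- function(lo = 500, hi = 4000, n = 600L) {
  spectral_grid(seq(lo, hi, length.out = n))
}

## accept either a spectral_grid or a raw numeric vector at API boundaries
as_grid <- function(x) {
  if (inherits(x, "spectral_grid")) return(x)
  spectral_grid(x)
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %d points, %.6g .. %.6g cm^-1\n",
              length(x), x[1L], x[length(x)]))
  invisible(x)
}

#' Convert wavenumber to vacuum wavelength (and back)
#'
#' `wavenumber_to_wavelength()` maps a wavenumber in cm^-1 to the vacuum
#' wavelength in micrometres, `lambda = 10^4 / nu`; the two functions are
#' mutual inverses.
#'
#' @param nu wavenumber(s) in cm^-1, positive.
#' @param lambda_um vacuum wavelength(s) in micrometres, positive.
#' @return numeric vector of wavelengths in um (or wavenumbers in cm^-1).
#' @examples
#' wavenumber_to_wavelength(1730)  # 5.780 um, the C=O carbonyl band of PMMA
#' wavelength_to_wavenumber(2.5)   # 4000 cm^-1
#' @export
wavenumber_to_wavelength <- function(nu) {
  nu <- as.numeric(nu)
  if (anyNA(nu) || any(nu <= 0)) stop("wavenumber must be positive")
  1e4 / nu
}

#' @rdname wavenumber_to_wavelength
#' @export
wavelength_to_wavenumber <- function(lambda_um) {
  lambda_um <- as.numeric(lambda_um)
  if (anyNA(lambda_um) || any(lambda_um <= 0)) stop("wavelength must be positive")
  1e4 / lambda_um
}
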