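#' Detector geometry for absorbance conversion
#'
#' Apparent absorbance relates to extinction efficiency through the ratio of
#' the detector reception area `G` to the geometric cross-section `g` of the
#' sample, `Qext = (G/g) (1 - 10^-A)`; single-detector instruments have
#' `G >> g`.
#'
#' @param reception_area_G detector reception area (any area unit).
#' @param sample_cross_section_g sample geometric cross-section, same unit;
#'   `G > g > 0`.
#' @return an object of class `"detector_geometry"`.
#' @export
detector_geometry <- function(reception_area_G, sample_cross_section_g) {
  G <- reception_area_G; g <- sample_cross_section_g
  if (!is.finite(G) || !is.finite(g) || g <= 0 || G <= g)
    stop("detector geometry requires G > g > 0")
  structure(list(G = G, g = g), class = "detector_geometry")
}

#' Apparent absorbance spectrum
#'
#' Decadic apparent absorbance `A = -log10(I/I0)`; for wavelength-scale
#' samples it mixes true absorption with scattering losses.
#'
#' @param grid a [spectral_grid()] or numeric wavenumber vector (cm^-1).
#' @param absorbance finite numeric values matching the grid length.
#' @return an object of class `"absorbance_spectrum"`.
#' @export
absorbance_spectrum <- function(grid, absorbance) {
  grid <- as_grid(grid)
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(grid))
    stop("absorbance must match the grid length")
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance contains non-finite values")
  structure(list(grid = grid, absorbance = absorbance),
            class = "absorbance_spectrum")
}

#' Convert apparent absorbance to extinction efficiency (and back)
#'
#' `absorbance_to_qext()` applies `Qext = (G/g) (1 - 10^-A)`;
#' `qext_to_absorbance()` inverts it, `A = -log10(1 - Qext g/G)`, which
#' requires `Qext < G/g` pointwise (otherwise the stated geometry cannot
#' have produced the spectrum).
#'
#' @param A an [absorbance_spectrum()].
#' @param qext an [extinction_spectrum()].
#' @param geom a [detector_geometry()].
#' @return an [extinction_spectrum()] resp. an [absorbance_spectrum()].
#' @export
absorbance_to_qext <- function(A, geom) {
  stopifnot(inherits(A, "absorbance_spectrum"),
            inherits(geom, "detector_geometry"))
  extinction_spectrum(A$grid, (geom$G / geom$g) * (1 - 10^(-A$absorbance)))
}

#' @rdname absorbance_to_qext
#' @export
qext_to_absorbance <- function(qext, geom) {
  stopifnot(inherits(qext, "extinction_spectrum"),
            inherits(geom, "detector_geometry"))
  ratio <- qext$qext * geom$g / geom$G
  if (any(ratio >= 1))
    stop("qext >= G/g: inconsistent detector geometry for this spectrum")
  absorbance_spectrum(qext$grid, -log10(1 - ratio))
}
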