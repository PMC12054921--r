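#' Lorentz oscillator set
#'
#' A Kramers-Kronig-consistent dielectric model: a superposition of `M`
#' Lorentz oscillator bands plus a constant offset `eps_inf`.  Band `m` is
#' parameterised by its resonance wavenumber `nu0` (cm^-1), strength `nup`
#' (cm^-1, enters squared) and damping `gamma` (cm^-1, the full width at half
#' maximum of the absorption band).  With non-negative strengths and positive
#' damping the imaginary part of the permittivity is non-negative everywhere,
#' as required for a passive medium.
#'
#' Bands are stored in canonical order: ascending `nu0`, ties broken by
#' descending `nup`.  This makes serialization deterministic and band
#' matching well-defined.
#'
#' @param nu0 numeric vector of resonance wavenumbers, cm^-1, positive.
#' @param nup numeric vector of strength parameters, cm^-1, non-negative.
#' @param gamma numeric vector of damping constants (FWHM), cm^-1, positive.
#' @param eps_inf constant permittivity offset, dimensionless, `>= 1`;
#'   absorbs the contribution of resonances far above the modelled window.
#' @return an object of class `"oscillator_set"`: a list with elements
#'   `bands` (data.frame with columns `nu0`, `nup`, `gamma`) and `eps_inf`.
#' @examples
#' os <- oscillator_set(nu0 = c(1730, 1000), nup = c(200, 100),
#'                      gamma = c(20, 15), eps_inf = 2.25)
#' os
#' @seealso [eval_permittivity()], [generate_material()], [polymer_fixture()]
#' @export
oscillator_set <- function(nu0, nup, gamma, eps_inf = 2.25) {
  nu0 <- as.numeric(nu0); nup <- as.numeric(nup); gamma <- as.numeric(gamma)
  m <- length(nu0)
  if (m < 1L) stop("an oscillator set needs at least one band")
  if (length(nup) != m || length(gamma) != m)
    stop("nu0, nup and gamma must have equal length")
  if (anyNA(c(nu0, nup, gamma, eps_inf)) || any(!is.finite(c(nu0, nup, gamma, eps_inf))))
    stop("oscillator parameters must be finite")
  if (any(nu0 <= 0)) stop("nu0 must be positive")
  if (any(nup < 0)) stop("nup must be non-negative")
  if (any(gamma <= 0)) stop("gamma must be positive")
  if (length(eps_inf) != 1L || eps_inf < 1) stop("eps_inf must be a scalar >= 1")
  ord <- order(nu0, -nup)
  structure(
    list(bands = data.frame(nu0 = nu0[ord], nup = nup[ord], gamma = gamma[ord]),
         eps_inf = as.numeric(eps_inf)),
    class = "oscillator_set")
}

#' @export
print.oscillator_set <- function(x, ...) {
  cat(sprintf("<oscillator_set> %d band(s), eps_inf = %.4g\n",
              nrow(x$bands), x$eps_inf))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Number of bands of an oscillator set
#' @param set an [oscillator_set()].
#' @return integer band count `M`.
#' @export
n_bands <- function(set) {
  stopifnot(inherits(set, "oscillator_set"))
  nrow(set$bands)
}

#' Evaluate the Lorentz permittivity on a grid
#'
#' Sums the `M` oscillator bands of `set` on the grid:
#' \deqn{\epsilon'(\nu) = \epsilon_\infty + \sum_m
#'   \frac{\nu_p^{(m)2}(\nu_0^{(m)2}-\nu^2)}
#'        {(\nu_0^{(m)2}-\nu^2)^2+(\nu\gamma^{(m)})^2}, \quad
#'  \epsilon''(\nu) = \sum_m
#'   \frac{\nu\gamma^{(m)}\nu_p^{(m)2}}
#'        {(\nu_0^{(m)2}-\nu^2)^2+(\nu\gamma^{(m)})^2}.}
#' The pair satisfies the Kramers-Kronig relations analytically, so any
#' permittivity built this way is physically admissible by construction.
#'
#' @param set an [oscillator_set()].
#' @param grid a [spectral_grid()] or numeric wavenumber vector (cm^-1).
#' @return a [dielectric_spectrum()].
#' @examples
#' os <- oscillator_set(1730, 200, 20)
#' sp <- eval_permittivity(os, default_grid())
#' max(sp$eps_imag)            # ~ nup^2/(nu0*gamma) at resonance
#' @export
eval_permittivity <- function(set, grid) {
  stopifnot(inherits(set, "oscillator_set"))
  grid <- as_grid(grid)
  ep <- lorentz_eps_parts(set$bands$nu0, set$bands$nup, set$bands$gamma,
                          as.numeric(grid))
  dielectric_spectrum(grid, set$eps_inf + ep$re, ep$im)
}

## vectorised band summation; nu may be any numeric vector (also negative,
## used by the parity property tests).  Returns list(re, im) without eps_inf.
lorentz_eps_parts <- function(nu0, nup, gamma, nu) {
  re <- numeric(length(nu)); im <- numeric(length(nu))
  nu2 <- nu * nu
  for (m in seq_along(nu0)) {
    a <- nu0[m]^2 - nu2
    b <- nu * gamma[m]
    den <- a * a + b * b
    p2 <- nup[m]^2
    re <- re + p2 * a / den
    im <- im + p2 * b / den
  }
  list(re = re, im = im)
}

#' Lorentzian approximation of an absorption band
#'
#' Near a sharp resonance the exact imaginary part of a single Lorentz band
#' may be approximated by a Lorentzian of height `nup^2/(nu0*gamma)` and full
#' width at half maximum `gamma`:
#' \deqn{\epsilon''(\nu) \approx \frac{\gamma\nu_p^2/(4\nu_0)}
#'       {(\nu_0-\nu)^2 + (\gamma/2)^2}.}
#' The two expressions agree exactly at resonance; the approximation error
#' vanishes as `gamma/nu0 -> 0`.
#'
#' @param nu0,nup,gamma single-band parameters in cm^-1.
#' @param grid a [spectral_grid()] or numeric wavenumber vector.
#' @return numeric vector: the approximate imaginary permittivity.
#' @export
lorentzian_approximation <- function(nu0, nup, gamma, grid) {
  stopifnot(nu0 > 0, nup >= 0, gamma > 0)
  nu <- as.numeric(as_grid(grid))
  (gamma * nup^2 / (4 * nu0)) / ((nu0 - nu)^2 + (gamma / 2)^2)
}

#' Anti-symmetrized Lorentzian basis set
#'
#' The comparison basis: each band contributes an odd-extended Lorentzian
#' pair to the imaginary part and its analytic Hilbert-transform partner to
#' the real part, so the pair is Kramers-Kronig consistent by construction.
#' Unlike the Lorentz dielectric basis, amplitudes `h` are *unrestricted in
#' sign* -- the basis can (and in practice does) exploit negative
#' contributions, which is its main physical shortcoming.
#'
#' Band `m` contributes the complex term
#' \deqn{h_m \frac{\gamma_m}{2}\left[\frac{1}{(\nu_0^{(m)}-\nu) - i\gamma_m/2}
#'      + \frac{1}{(\nu_0^{(m)}+\nu) + i\gamma_m/2}\right],}
#' whose imaginary part is `h_m [L(nu - nu0) - L(nu + nu0)]` with `L` a
#' Lorentzian of FWHM `gamma` normalised to unit height, i.e. `h_m` is
#' (approximately) the peak height of band `m`.
#'
#' @param nu0 positions, cm^-1, positive.
#' @param h amplitudes, dimensionless, any sign.
#' @param gamma widths (FWHM), cm^-1, positive.
#' @param offset constant real offset (plays the role of `eps_inf`).
#' @return an object of class `"antisym_set"`.
#' @export
antisym_set <- function(nu0, h, gamma, offset = 2.25) {
  nu0 <- as.numeric(nu0); h <- as.numeric(h); gamma <- as.numeric(gamma)
  m <- length(nu0)
  if (m < 1L || length(h) != m || length(gamma) != m)
    stop("nu0, h and gamma must have equal positive length")
  if (anyNA(c(nu0, h, gamma, offset))) stop("parameters must be finite")
  if (any(nu0 <= 0)) stop("nu0 must be positive")
  if (any(gamma <= 0)) stop("gamma must be positive")
  ord <- order(nu0, -abs(h))
  structure(
    list(bands = data.frame(nu0 = nu0[ord], h = h[ord], gamma = gamma[ord]),
         offset = as.numeric(offset)),
    class = "antisym_set")
}

#' @export
print.antisym_set <- function(x, ...) {
  cat(sprintf("<antisym_set> %d band(s), offset = %.4g\n",
              nrow(x$bands), x$offset))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Evaluate the anti-symmetrized Lorentzian model on a grid
#'
#' @param set an [antisym_set()].
#' @param grid a [spectral_grid()] or numeric wavenumber vector; negative
#'   wavenumbers are allowed here (used to verify the odd symmetry of the
#'   imaginary part).
#' @return a list with components `eps_real` and `eps_imag` (the model is
#'   used for permittivities in this package); when `grid` is a valid
#'   spectral grid and the imaginary part is non-negative on it, the result
#'   can be wrapped in [dielectric_spectrum()].
#' @export
eval_antisym_lorentzian <- function(set, grid) {
  stopifnot(inherits(set, "antisym_set"))
  nu <- as.numeric(grid)
  parts <- antisym_parts(set$bands$nu0, set$bands$h, set$bands$gamma, nu)
  list(eps_real = set$offset + parts$re, eps_imag = parts$im)
}

antisym_parts <- function(nu0, h, gamma, nu) {
  re <- numeric(length(nu)); im <- numeric(length(nu))
  for (m in seq_along(nu0)) {
    g2 <- gamma[m] / 2
    term <- h[m] * g2 * (1 / complex(real = nu0[m] - nu, imaginary = -g2) +
                         1 / complex(real = nu0[m] + nu, imaginary =  g2))
    re <- re + Re(term)
    im <- im + Im(term)
  }
  list(re = re, im = im)
}
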