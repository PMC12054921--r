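#' Numerical Kramers-Kronig consistency check
#'
#' Validates that a sampled permittivity pair is causality-consistent by
#' reconstructing the real part from the imaginary part through the
#' Kramers-Kronig relation
#' \deqn{\epsilon'(\nu) = \epsilon_\infty + \frac{2}{\pi}\,P\!\!\int_0^\infty
#'   \frac{\Omega\,\epsilon''(\Omega)}{\Omega^2-\nu^2}\,d\Omega}
#' and reporting the worst relative disagreement.  The principal-value
#' integral is evaluated with Maclaurin's alternating-point rule on a uniform
#' grid: the integrand is summed only over sample points of opposite index
#' parity to the evaluation point, with effective spacing `2h`, which skips
#' the singular point exactly and needs no subtraction trick.
#'
#' The check only makes sense on a grid wide enough that `eps_imag` has
#' decayed at both ends; mid-IR-window data alone cannot be validated this
#' way.  If the edge values of `eps_imag` exceed `tail_threshold` times its
#' maximum the result carries `narrow_grid = TRUE`.
#'
#' @param eps a [dielectric_spectrum()] on a *uniform* grid, typically
#'   produced with [kk_validation_grid()].
#' @param eps_inf the constant offset to which `eps_real` tends far from all
#'   resonances.
#' @param n_eval number of interior evaluation points (evenly spread over the
#'   central 96 percent of the grid).
#' @param tail_threshold fraction of `max(eps_imag)` above which an edge
#'   value flags the grid as too narrow.
#' @return a list with `max_rel_discrepancy` (max over the evaluation points
#'   of `|eps'_KK - eps'| / max|eps' - eps_inf|`), `wavenumbers`,
#'   `eps_real_kk`, `eps_real`, and the logical `narrow_grid`.
#' @examples
#' g <- kk_validation_grid(hi = 20000, by = 2)
#' sp <- eval_permittivity(oscillator_set(1500, 200, 30), g)
#' kk_check(sp, eps_inf = 2.25)$max_rel_discrepancy
#' @export
kk_check <- function(eps, eps_inf, n_eval = 200L, tail_threshold = 1e-3) {
  stopifnot(inherits(eps, "dielectric_spectrum"))
  nu <- as.numeric(eps$grid)
  h <- diff(nu)
  if (diff(range(h)) > 1e-8 * mean(h))
    stop("kk_check requires a uniform grid")
  h <- mean(h)
  N <- length(nu)

  im_max <- max(eps$eps_imag)
  narrow <- im_max > 0 &&
    (eps$eps_imag[1L] > tail_threshold * im_max ||
     eps$eps_imag[N] > tail_threshold * im_max)
  if (narrow)
    warning("eps_imag has not decayed at the grid edges; KK check unreliable")

  lo <- max(2L, ceiling(0.02 * N))
  hi <- min(N - 1L, floor(0.98 * N))
  idx <- unique(round(seq(lo, hi, length.out = min(n_eval, hi - lo + 1L))))

  w_all <- nu * eps$eps_imag              # Omega * eps''(Omega)
  nu2 <- nu * nu
  eps_kk <- numeric(length(idx))
  for (parity in 0:1) {
    tgt <- idx[idx %% 2L == parity]
    if (!length(tgt)) next
    src <- which(seq_len(N) %% 2L != parity)   # opposite parity
    # matrix of 1/(Omega_j^2 - nu_i^2); targets never coincide with sources
    denom <- outer(-nu2[tgt], nu2[src], "+")
    eps_kk[match(tgt, idx)] <-
      eps_inf + (2 / pi) * (2 * h) * as.numeric((1 / denom) %*% w_all[src])
  }

  scale <- max(abs(eps$eps_real - eps_inf))
  if (scale == 0) scale <- 1
  disc <- abs(eps_kk - eps$eps_real[idx]) / scale
  list(max_rel_discrepancy = max(disc),
       wavenumbers = nu[idx],
       eps_real_kk = eps_kk,
       eps_real = eps$eps_real[idx],
       narrow_grid = narrow)
}

#' Wide uniform grid for Kramers-Kronig validation
#'
#' The transform needs `eps_imag` over (in principle) all wavenumbers; this
#' helper builds the default validation grid from `by` up to `hi` cm^-1 at
#' uniform spacing `by`, far beyond the mid-IR window so mid-IR bands have
#' fully decayed at both ends.
#'
#' @param hi upper limit, cm^-1.
#' @param by grid spacing, cm^-1.
#' @return a [spectral_grid()].
#' @export
kk_validation_grid <- function(hi = 50000, by = 1) {
  spectral_grid(seq(by, hi, by = by))
}
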