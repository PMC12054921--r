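#' Homogeneous sphere scattering geometry
#'
#' @param radius_um sphere radius in micrometres, positive.  The default of
#'   5 um is the model-cell radius used throughout the simulations.
#' @param medium_index real refractive index of the (non-absorbing)
#'   surrounding medium, `>= 1`; defaults to vacuum/air.
#' @return an object of class `"sphere_model"`.
#' @export
sphere_model <- function(radius_um = 5, medium_index = 1) {
  if (!is.finite(radius_um) || radius_um <= 0) stop("radius must be positive")
  if (!is.finite(medium_index) || medium_index < 1)
    stop("medium_index must be a real number >= 1")
  structure(list(radius_um = radius_um, medium_index = medium_index),
            class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("<sphere_model> radius %.4g um, medium index %.4g\n",
              x$radius_um, x$medium_index))
  invisible(x)
}

#' Mie size parameter
#'
#' `x = 2 pi r nu 1e-4 * medium_index` for radius `r` in um and wavenumber
#' `nu` in cm^-1 (i.e. `2 pi r / lambda_medium`).  Governs the scattering
#' regime: Rayleigh for `x << 1`, resonant Mie scattering for `x ~ 1-30`.
#'
#' @param sphere a [sphere_model()].
#' @param nu wavenumber(s) in cm^-1, positive.
#' @return dimensionless size parameter(s).
#' @examples
#' size_parameter(sphere_model(5), 1000)  # pi
#' @export
size_parameter <- function(sphere, nu) {
  stopifnot(inherits(sphere, "sphere_model"))
  nu <- as.numeric(nu)
  if (anyNA(nu) || any(nu <= 0)) stop("wavenumber must be positive")
  2 * pi * sphere$radius_um * nu * 1e-4 * sphere$medium_index
}

#' Extinction-efficiency spectrum
#'
#' @param grid a [spectral_grid()] or numeric wavenumber vector (cm^-1).
#' @param qext extinction efficiencies, dimensionless, non-negative.
#' @return an object of class `"extinction_spectrum"`.
#' @export
extinction_spectrum <- function(grid, qext) {
  grid <- as_grid(grid)
  qext <- as.numeric(qext)
  if (length(qext) != length(grid)) stop("qext must match the grid length")
  if (anyNA(qext) || any(!is.finite(qext)))
    stop("qext contains non-finite values")
  if (any(qext < -1e-12)) stop("qext must be non-negative")
  structure(list(grid = grid, qext = pmax(qext, 0)),
            class = "extinction_spectrum")
}

#' @export
print.extinction_spectrum <- function(x, ...) {
  cat(sprintf("<extinction_spectrum> %d points, %.6g .. %.6g cm^-1, Qext in [%.4g, %.4g]\n",
              length(x$grid), x$grid[1L], x$grid[length(x$grid)],
              min(x$qext), max(x$qext)))
  invisible(x)
}

#' Lorenz-Mie efficiencies of a homogeneous sphere
#'
#' Computes extinction, scattering and absorption efficiencies from the
#' Lorenz-Mie series.  The Mie coefficients `a_n`, `b_n` are obtained from
#' the logarithmic derivative `D_n(mx)` by downward recurrence (started 25
#' orders above both the truncation order and `|mx|`, which is numerically
#' safe for absorbing spheres); the real-argument Riccati-Bessel function
#' `psi_n(x)` also uses a normalised downward recurrence (upward recursion
#' loses digits for orders above `x`), while `chi_n(x)` grows with order and
#' recurses upward stably.  The series is truncated at
#' `n_max = round(x + 4 x^(1/3) + 2) + 2` (Wiscombe's criterion plus a
#' two-order margin so the truncation tail stays below 1e-10 relative).
#'
#' Vectorised over `(m, x)` pairs.  The convention is `m = m' + i m''` with
#' `m'' >= 0` for an absorbing sphere.
#'
#' @param m complex relative refractive index (sphere over medium);
#'   `Re(m) > 0`, `Im(m) >= 0`.
#' @param x size parameter(s), positive.
#' @param extra_orders additional series terms beyond the truncation
#'   criterion (for convergence self-checks; the default criterion is
#'   already converged to well below 1e-10 relative).
#' @return a data.frame with columns `qext`, `qsca`, `qabs`.
#' @examples
#' mie_efficiencies(1.5 + 0.01i, 5)
#' @export
mie_efficiencies <- function(m, x, extra_orders = 0L) {
  m <- as.complex(m); x <- as.numeric(x)
  if (length(m) == 1L) m <- rep(m, length(x))
  if (length(x) == 1L) x <- rep(x, length(m))
  if (length(m) != length(x)) stop("m and x must have matching lengths")
  if (anyNA(m) || anyNA(x) || any(!is.finite(x)) ||
      any(!is.finite(Re(m))) || any(!is.finite(Im(m))))
    stop("non-finite m or x")
  if (any(x <= 0)) stop("size parameter must be positive")
  if (any(Re(m) <= 0) || any(Im(m) < -1e-15))
    stop("relative index must have Re(m) > 0 and Im(m) >= 0")

  P <- length(x)
  nmax_i <- pmax(3L, as.integer(round(x + 4 * x^(1/3) + 2)) + 2L +
                       as.integer(extra_orders))
  N <- max(nmax_i)

  ## logarithmic derivative D_n(mx): downward recurrence started above both
  ## the truncation order and |mx| (needed for stability when |mx| > n_max)
  mx <- m * x
  D <- matrix(0i, nrow = N, ncol = P)
  Dn <- rep(0i, P)
  nstart <- max(N, ceiling(max(Mod(mx)))) + 25L
  for (n in seq(nstart, 2L, by = -1L)) {
    k <- n / mx
    Dn <- k - 1 / (Dn + k)
    if (n - 1L <= N) D[n - 1L, ] <- Dn
  }

  ## psi_n(x), n = 0..N: normalised downward (Miller) recurrence, stable for
  ## all orders; psi = x j_n(x) decays for n > x where upward recursion
  ## would lose digits
  PSI <- matrix(0, nrow = N + 1L, ncol = P)
  jp1 <- numeric(P)
  jn <- rep(1e-30, P)
  for (n in seq(max(N, ceiling(max(x))) + 15L, 0L, by = -1L)) {
    if (n <= N) PSI[n + 1L, ] <- jn
    jm1 <- (2 * n + 1) / x * jn - jp1
    jp1 <- jn
    jn <- jm1
    big <- abs(jn) > 1e250
    if (any(big)) {
      jn[big] <- jn[big] * 1e-250
      jp1[big] <- jp1[big] * 1e-250
      PSI[, big] <- PSI[, big] * 1e-250
    }
  }
  ## normalise against the closed forms psi_0 = sin x, psi_1 = sin x / x -
  ## cos x, whichever is better conditioned per point
  s0 <- sin(x); s1 <- sin(x) / x - cos(x)
  use0 <- abs(PSI[1L, ]) >= abs(PSI[2L, ])
  scale <- ifelse(use0, s0 / PSI[1L, ], s1 / PSI[2L, ])
  PSI <- PSI * rep(scale, each = N + 1L)

  ## chi_n(x) grows with n: upward recurrence is stable
  chi_nm1 <- cos(x); chi_nm2 <- -sin(x)   # chi_0, chi_{-1}
  qext <- numeric(P); qsca <- numeric(P)
  active <- rep(TRUE, P)
  for (n in seq_len(N)) {
    active <- active & (n <= nmax_i)
    if (!any(active)) break
    i <- which(active)
    cn <- (2 * n - 1) / x[i]
    psi    <- PSI[n + 1L, i]
    psi_m1 <- PSI[n, i]
    chi <- cn * chi_nm1[i] - chi_nm2[i]
    xi    <- complex(real = psi, imaginary = -chi)
    xi_m1 <- complex(real = psi_m1, imaginary = -chi_nm1[i])
    Dn <- D[n, i]
    nox <- n / x[i]
    fa <- Dn / m[i] + nox
    fb <- Dn * m[i] + nox
    an <- (fa * psi - psi_m1) / (fa * xi - xi_m1)
    bn <- (fb * psi - psi_m1) / (fb * xi - xi_m1)
    w <- 2 * n + 1
    qext[i] <- qext[i] + w * Re(an + bn)
    qsca[i] <- qsca[i] + w * (Mod(an)^2 + Mod(bn)^2)
    chi_nm2[i] <- chi_nm1[i]; chi_nm1[i] <- chi
  }
  qext <- qext * 2 / x^2
  qsca <- qsca * 2 / x^2
  data.frame(qext = qext, qsca = qsca, qabs = qext - qsca)
}

#' Forward model: extinction spectrum of a homogeneous sphere
#'
#' Maps a complex refractive index spectrum and a sphere geometry to the
#' extinction-efficiency spectrum by evaluating the Lorenz-Mie series at
#' every grid point, with relative index `m(nu) = n(nu) / medium_index` and
#' size parameter from [size_parameter()].  This is the forward model that
#' the inverse-scattering fit repeatedly evaluates.
#'
#' @param n a [refractive_index_spectrum()].
#' @param sphere a [sphere_model()].
#' @return an [extinction_spectrum()] on the same grid.
#' @examples
#' os <- oscillator_set(1730, 200, 20)
#' nn <- eps_to_n(eval_permittivity(os, default_grid(n = 50)))
#' forward_qext(nn, sphere_model(5))
#' @export
forward_qext <- function(n, sphere) {
  stopifnot(inherits(n, "refractive_index_spectrum"),
            inherits(sphere, "sphere_model"))
  q <- forward_qext_num(n$n_real, n$n_imag, as.numeric(n$grid), sphere)
  extinction_spectrum(n$grid, q)
}

## numeric core shared with the fit Jacobian (no container overhead)
forward_qext_num <- function(n_real, n_imag, nu, sphere) {
  m <- complex(real = n_real, imaginary = n_imag) / sphere$medium_index
  x <- 2 * pi * sphere$radius_um * nu * 1e-4 * sphere$medium_index
  mie_efficiencies(m, x)$qext
}
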