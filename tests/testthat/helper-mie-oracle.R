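# Independent Lorenz-Mie oracle used by the dual-route checks.
#
# Deliberately a different algorithm from the package implementation: the
# complex-argument Riccati-Bessel functions come from Miller's downward
# recurrence on the spherical Bessel function j_n itself (normalised against
# the closed forms j_0, j_1), the real-argument ones from base R's
# half-integer besselJ/besselY, and the Mie coefficients from the explicit
# a_n/b_n formulas -- no logarithmic derivative anywhere.

oracle_sph_j_complex <- function(nmax, z) {
  # j_0 .. j_nmax of complex z by downward recurrence
  nstart <- max(nmax, ceiling(Mod(z))) + 25L
  store <- rep(0i, nstart + 1L)
  jp1 <- 0i
  jn <- 1e-30 + 0i
  for (k in nstart:0) {
    if (k <= nmax) store[k + 1L] <- jn
    jm1 <- (2 * k + 1) / z * jn - jp1
    jp1 <- jn
    jn <- jm1
    # guard against overflow of the unnormalised recurrence
    if (Mod(jn) > 1e250) {
      jn <- jn * 1e-250; jp1 <- jp1 * 1e-250
      store <- store * 1e-250
    }
  }
  j0 <- sin(z) / z
  j1 <- sin(z) / z^2 - cos(z) / z
  # normalise against whichever closed form is better conditioned
  if (Mod(store[1L]) >= Mod(store[2L])) store * (j0 / store[1L])
  else store * (j1 / store[2L])
}

oracle_mie <- function(m, x, extra_orders = 0L) {
  nmax <- as.integer(round(x + 4 * x^(1/3) + 2)) + as.integer(extra_orders)
  nmax <- max(nmax, 3L)
  n <- seq_len(nmax)
  z <- m * x

  j_mx <- oracle_sph_j_complex(nmax, z)          # j_0 .. j_nmax at mx
  psi_mx <- z * j_mx[n + 1L]
  psi_mx_nm1 <- z * j_mx[n]
  dpsi_mx <- psi_mx_nm1 - n / z * psi_mx

  sq <- sqrt(pi * x / 2)
  psi <- sq * besselJ(x, n + 0.5)
  psi_nm1 <- sq * besselJ(x, n - 0.5)
  chi <- -sq * besselY(x, n + 0.5)
  chi_nm1 <- -sq * besselY(x, n - 0.5)
  dpsi <- psi_nm1 - n / x * psi
  dchi <- chi_nm1 - n / x * chi
  xi <- complex(real = psi, imaginary = -chi)
  dxi <- complex(real = dpsi, imaginary = -dchi)

  a <- (m * psi_mx * dpsi - psi * dpsi_mx) / (m * psi_mx * dxi - xi * dpsi_mx)
  b <- (psi_mx * dpsi - m * psi * dpsi_mx) / (psi_mx * dxi - m * xi * dpsi_mx)
  w <- 2 * n + 1
  qext <- 2 / x^2 * sum(w * Re(a + b))
  qsca <- 2 / x^2 * sum(w * (Mod(a)^2 + Mod(b)^2))
  list(qext = qext, qsca = qsca, qabs = qext - qsca)
}
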