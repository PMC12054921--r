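test_that("oscillator sets validate and canonicalise", {
  os <- oscillator_set(c(3000, 1000, 1000), c(50, 10, 80), c(20, 15, 25),
                       eps_inf = 2)
  # ascending nu0, equal centres ordered by descending nup
  expect_equal(os$bands$nu0, c(1000, 1000, 3000))
  expect_equal(os$bands$nup, c(80, 10, 50))
  expect_equal(n_bands(os), 3L)
  expect_error(oscillator_set(numeric(0), numeric(0), numeric(0)), "at least one")
  expect_error(oscillator_set(1000, -1, 20), "non-negative")
  expect_error(oscillator_set(1000, 10, 0), "positive")
  expect_error(oscillator_set(-10, 10, 20), "positive")
  expect_error(oscillator_set(1000, 10, 20, eps_inf = 0.5), "eps_inf")
})

test_that("single-band permittivity matches the closed forms", {
  # at resonance the imaginary part collapses to nup^2 / (nu0 * gamma)
  os <- oscillator_set(1730, 200, 20)
  sp <- eval_permittivity(os, spectral_grid(c(1000, 1730, 2500)))
  expect_equal(sp$eps_imag[2L], 200^2 / (1730 * 20), tolerance = 1e-12)
  # static limit: eps'' -> 0 and eps' -> eps_inf + sum nup^2/nu0^2
  os2 <- oscillator_set(1000, 100, 10, eps_inf = 2)
  sp2 <- eval_permittivity(os2, spectral_grid(c(1e-6, 500)))
  expect_equal(sp2$eps_real[1L], 2.01, tolerance = 1e-9)
  expect_lt(sp2$eps_imag[1L], 1e-10)
})

test_that("multi-band evaluation equals the term-by-term oracle", {
  os <- oscillator_set(c(900, 2800), c(150, 80), c(30, 18), eps_inf = 2.4)
  nu <- c(600, 890, 1500, 2805, 3900)
  sp <- eval_permittivity(os, spectral_grid(nu))
  # independent term-by-term summation straight from the band formulas
  re <- rep(2.4, length(nu)); im <- numeric(length(nu))
  for (m in 1:2) {
    b <- os$bands[m, ]
    for (l in seq_along(nu)) {
      A <- b$nu0^2 - nu[l]^2
      den <- A^2 + (nu[l] * b$gamma)^2
      re[l] <- re[l] + b$nup^2 * A / den
      im[l] <- im[l] + b$nup^2 * nu[l] * b$gamma / den
    }
  }
  expect_equal(sp$eps_real, re, tolerance = 1e-14)
  expect_equal(sp$eps_imag, im, tolerance = 1e-14)
})

test_that("permittivity parity: eps' even, eps'' odd in wavenumber", {
  parts <- mieinvert:::lorentz_eps_parts
  nu <- c(200, 850, 1730.5, 3999)
  p_pos <- parts(c(1000, 2600), c(120, 60), c(25, 40), nu)
  p_neg <- parts(c(1000, 2600), c(120, 60), c(25, 40), -nu)
  expect_equal(p_neg$re, p_pos$re)
  expect_equal(p_neg$im, -p_pos$im)
})

test_that("eps'' is non-negative and positive where strengths are positive", {
  for (seed in 1:5) {
    os <- generate_material(material_recipe(seed = seed))
    sp <- eval_permittivity(os, default_grid(n = 200))
    expect_true(all(sp$eps_imag >= 0))
    expect_true(all(sp$eps_imag > 0))   # every nup > 0 in generated sets
  }
})

test_that("permittivity <-> refractive index conversions are exact inverses", {
  g <- spectral_grid(c(1000, 2000, 3000))
  n <- eps_to_n(dielectric_spectrum(g, c(2.25, 0, 3), c(0, 2, 4)))
  expect_equal(n$n_real, c(1.5, 1, 2))
  expect_equal(n$n_imag, c(0, 1, 1))
  eps_back <- n_to_eps(n)
  expect_equal(eps_back$eps_real, c(2.25, 0, 3))
  expect_equal(eps_back$eps_imag, c(0, 2, 4))

  # identities 2 n' n'' = eps'' and n'^2 - n''^2 = eps' on random spectra
  set.seed(42)
  for (k in 1:20) {
    er <- runif(50, -2, 6); ei <- runif(50, 0, 5)
    gg <- spectral_grid(sort(runif(50, 100, 5000)))
    nn <- eps_to_n(dielectric_spectrum(gg, er, ei))
    expect_equal(nn$n_real^2 - nn$n_imag^2, er, tolerance = 1e-12)
    expect_equal(2 * nn$n_real * nn$n_imag, ei, tolerance = 1e-12)
  }
})

test_that("Lorentzian approximation matches the exact band near resonance", {
  nu0 <- 2000; nup <- 150; gamma <- 20
  # exact equality at resonance
  peak <- lorentzian_approximation(nu0, nup, gamma, spectral_grid(c(nu0, nu0 + 1)))
  expect_equal(peak[1L], nup^2 / (nu0 * gamma), tolerance = 1e-14)
  # half maximum at nu0 +/- gamma/2 (FWHM = gamma)
  half <- lorentzian_approximation(nu0, nup, gamma,
                                   spectral_grid(c(nu0 - gamma / 2, nu0 + gamma / 2)))
  expect_equal(half, rep(peak[1L] / 2, 2L), tolerance = 1e-12)
  # sup-norm error over [nu0 - 2 gamma, nu0 + 2 gamma] shrinks as gamma/nu0 -> 0
  sup_err <- vapply(c(0.05, 0.01, 0.002), function(ratio) {
    g <- ratio * nu0
    grid <- spectral_grid(seq(nu0 - 2 * g, nu0 + 2 * g, length.out = 400))
    exact <- eval_permittivity(oscillator_set(nu0, nup, g), grid)$eps_imag
    approx <- lorentzian_approximation(nu0, nup, g, grid)
    max(abs(approx - exact)) / max(exact)
  }, numeric(1))
  expect_true(all(diff(sup_err) < 0))
  expect_lt(sup_err[2L], 0.02)   # gamma/nu0 = 0.01 is already very accurate
})

test_that("anti-symmetrized Lorentzian basis behaves as an odd/analytic pair", {
  s <- antisym_set(c(1000, 2500), c(1.5, -0.7), c(30, 50), offset = 2.1)
  # zero amplitudes: imaginary part identically zero, real part the offset
  s0 <- antisym_set(c(1000, 2500), c(0, 0), c(30, 50), offset = 2.1)
  ev0 <- eval_antisym_lorentzian(s0, seq(500, 4000, length.out = 30))
  expect_equal(ev0$eps_imag, rep(0, 30))
  expect_equal(ev0$eps_real, rep(2.1, 30))
  # odd imaginary part: zero at nu = 0, antisymmetric overall
  ev <- eval_antisym_lorentzian(s, c(-1200, 0, 1200))
  expect_equal(ev$eps_imag[2L], 0)
  expect_equal(ev$eps_imag[1L], -ev$eps_imag[3L])
  expect_equal(ev$eps_real[1L], ev$eps_real[3L])
})

test_that("antisym real part is the Hilbert transform of its imaginary part", {
  # single band on a wide fine grid; PV quadrature oracle reproduces the
  # analytic real part away from the offset
  s <- antisym_set(1500, 2.0, 40, offset = 0)
  nu <- seq(1, 30000, by = 1)
  ev <- eval_antisym_lorentzian(s, nu)
  idx <- seq(1000, 2200, by = 40)
  kk <- pv_hilbert_real_from_imag(nu, ev$eps_imag, idx)
  expect_equal(kk, ev$eps_real[idx], tolerance = 1e-4)
})
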