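test_that("size parameter follows the geometry", {
  s5 <- sphere_model(5)
  expect_equal(size_parameter(s5, 1000), pi)
  expect_equal(size_parameter(s5, 4000), 4 * pi)
  expect_equal(size_parameter(sphere_model(5, medium_index = 1.3), 1000),
               1.3 * pi)
  expect_lt(size_parameter(s5, 1e-6), 1e-8)
  expect_error(size_parameter(s5, -100), "positive")
  expect_error(sphere_model(0), "positive")
  expect_error(sphere_model(5, 0.9), "medium_index")
})

test_that("lossless spheres scatter without absorbing", {
  q <- mie_efficiencies(1.5 + 0i, c(0.05, 0.7, 3.2, 11, 28))
  expect_true(all(abs(q$qabs) < 1e-12))
  expect_equal(q$qext, q$qsca, tolerance = 1e-12)
})

test_that("small-sphere limit agrees with the Rayleigh closed form", {
  m <- 1.5 + 0.1i
  x <- 0.01
  q <- mie_efficiencies(m, x)$qext
  rayleigh <- 4 * x * Im((m^2 - 1) / (m^2 + 2))
  expect_lt(abs(q - rayleigh) / rayleigh, 0.01)
})

test_that("Mie efficiencies agree with the independent oracle", {
  set.seed(7)
  for (k in 1:60) {
    m <- complex(real = runif(1, 1.1, 2.0), imaginary = runif(1, 0, 0.5))
    x <- exp(runif(1, log(0.01), log(30)))
    o <- oracle_mie(m, x, extra_orders = 2L)  # same truncation order
    q <- mie_efficiencies(m, x)
    expect_lt(abs(q$qext - o$qext) / o$qext, 1e-8)
    expect_lt(abs(q$qsca - o$qsca) / o$qsca, 1e-8)
  }
})

test_that("series truncation is self-consistent", {
  set.seed(8)
  for (k in 1:20) {
    m <- complex(real = runif(1, 1.1, 2.0), imaginary = runif(1, 0, 0.5))
    x <- exp(runif(1, log(0.05), log(30)))
    q1 <- mie_efficiencies(m, x)
    q2 <- mie_efficiencies(m, x, extra_orders = 15L)
    expect_lt(abs(q1$qext - q2$qext) / q1$qext, 1e-10)
  }
})

test_that("mie_efficiencies rejects invalid input", {
  expect_error(mie_efficiencies(1.5 + 0.1i, -1), "positive")
  expect_error(mie_efficiencies(NA_complex_, 1), "non-finite")
  expect_error(mie_efficiencies(1.5 - 0.2i, 1), "Im")
  expect_error(mie_efficiencies(c(1.5 + 0i, 1.6 + 0i), c(1, 2, 3)), "matching")
})

test_that("forward model is the pointwise Mie map", {
  g <- spectral_grid(seq(500, 4000, length.out = 25))
  s <- sphere_model(5)
  # no contrast: nothing scatters
  n0 <- refractive_index_spectrum(g, rep(1, length(g)), rep(0, length(g)))
  expect_true(all(forward_qext(n0, s)$qext < 1e-12))
  # constant index: every point equals the single-(m, x) computation
  n1 <- refractive_index_spectrum(g, rep(1.5, length(g)), rep(0, length(g)))
  q <- forward_qext(n1, s)
  for (l in c(1L, 9L, 25L)) {
    single <- mie_efficiencies(1.5 + 0i, size_parameter(s, g[l]))$qext
    expect_equal(q$qext[l], single, tolerance = 1e-14)
  }
  # medium index enters through the relative index and the size parameter
  s2 <- sphere_model(5, medium_index = 1.33)
  q2 <- forward_qext(n1, s2)
  expected <- mie_efficiencies(1.5 / 1.33 + 0i, size_parameter(s2, g[9L]))$qext
  expect_equal(q2$qext[9L], expected, tolerance = 1e-14)
})

test_that("extinction approaches the extinction paradox limit at large x", {
  # x ~ 100 with an absorbing index: Qext -> 2 within a loose band
  q <- mie_efficiencies(1.5 + 0.1i, 100)$qext
  expect_lt(abs(q - 2), 0.3)
})
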