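sph <- sphere_model(5)

test_that("residuals vanish for the generating parameters", {
  truth <- separated_truth(2, seed = 21)
  given <- simulate_given_qext(truth, sph, tiny_grid())$observed
  r <- residuals_qext(truth, given, sph)
  expect_lt(max(abs(r)), 1e-12)
  expect_equal(objective_S(truth, given, sph), sum(r^2))
})

test_that("an empty model leaves the negated given spectrum as residual", {
  truth <- separated_truth(2, seed = 22)
  given <- simulate_given_qext(truth, sph, tiny_grid())$observed
  empty <- oscillator_set(c(1000, 2000), c(0, 0), c(20, 20), eps_inf = 1)
  r <- residuals_qext(empty, given, sph)
  expect_equal(r, -given$qext, tolerance = 1e-12)
})

test_that("residuals against a perturbed model match explicit forward runs", {
  g <- tiny_grid()
  truth <- oscillator_set(1500, 150, 30, eps_inf = 2.25)
  trial <- oscillator_set(1500, 150, 40, eps_inf = 2.25)
  given <- simulate_given_qext(truth, sph, g)$observed
  # oracle: two explicit forward evaluations
  q_trial <- forward_qext(eps_to_n(eval_permittivity(trial, g)), sph)
  expect_equal(residuals_qext(trial, given, sph), q_trial$qext - given$qext,
               tolerance = 1e-14)
  expect_equal(objective_S(trial, given, sph),
               sum((q_trial$qext - given$qext)^2), tolerance = 1e-12)
})

test_that("Case I initialization is the unbiased equi-spaced grid", {
  cfg <- fit_config(n_bands = 25, init_scheme = "case1")
  init <- init_case1(cfg)
  expect_equal(nrow(init$bands), 25L)
  expect_equal(init$bands$nu0[1L], 500)
  expect_equal(init$bands$nu0[25L], 4000)
  expect_equal(unique(round(diff(init$bands$nu0), 6)), round(3500 / 24, 6))
  expect_true(all(init$bands$nup == 20))
  expect_true(all(init$bands$gamma == 20))
  init2 <- init_case1(fit_config(n_bands = 2))
  expect_equal(init2$bands$nu0, c(500, 4000))
  expect_error(init_case1(fit_config(n_bands = 1)), "at least 2")
})

test_that("Case II initialization respects the absorbing intervals", {
  cfg <- fit_config(n_bands = 25, init_scheme = "case2")
  init <- init_case2(cfg)
  lo_block <- init$bands$nu0[init$bands$nu0 <= 2200]
  hi_block <- init$bands$nu0[init$bands$nu0 >= 2800]
  expect_length(lo_block, 20L)
  expect_length(hi_block, 5L)
  expect_equal(unique(round(diff(lo_block), 6)), round(1700 / 19, 6))
  expect_equal(unique(round(diff(hi_block), 6)), 175)
  # silent windows hold no initial bands
  expect_false(any(init$bands$nu0 > 2200 & init$bands$nu0 < 2800))
  expect_false(any(init$bands$nu0 > 3500))
  expect_true(all(init$bands$nup == 20) && all(init$bands$gamma == 20))
  # degenerate single full-range interval reduces to Case I
  cfg1 <- fit_config(n_bands = 25,
                     intervals = data.frame(lo = 500, hi = 4000, count = 25L))
  expect_equal(init_case2(cfg1)$bands, init_case1(cfg)$bands)
  # counts must sum to the band count
  expect_error(init_case2(fit_config(n_bands = 10)), "sum")
})

test_that("noiseless reconstruction recovers a known truth (end to end)", {
  truth <- separated_truth(3, seed = 31)
  sim <- simulate_given_qext(truth, sph, tiny_grid(200))
  cfg <- fit_config(n_bands = 6, init_scheme = "case1", max_iter = 400)
  fit <- reconstruct_from_qext(sim$observed, sph, cfg)
  # monotone improvement and S == sum(R^2)
  expect_lte(fit$objective_S, fit$initial_S)
  expect_equal(fit$objective_S, sum(fit$residuals^2),
               tolerance = 1e-10)
  # feasibility: physical signs respected
  expect_true(all(fit$params$bands$nup >= 0))
  expect_true(all(fit$params$bands$gamma > 0))
  # parameter recovery after matching; surplus bands die
  mb <- match_bands(fit$params, truth)
  expect_equal(nrow(mb$pairs), 3L)
  expect_lt(max(abs(mb$pairs$d_nu0)), 1)
  em <- reconstruction_error_metrics(fit, sim$truth_eps)
  expect_lt(em$rel_l2_eps_imag, 0.05)
})

test_that("a zero spectrum drives the model to the empty medium", {
  g <- tiny_grid(60)
  given <- extinction_spectrum(g, rep(0, length(g)))
  cfg <- fit_config(n_bands = 2, init_scheme = "case1", max_iter = 200,
                    max_reseeds = 0L)
  fit <- reconstruct_from_qext(given, sph, cfg)
  expect_lt(fit$objective_S, 1e-8)
  expect_lt(max(fit$model_spectrum$qext), 1e-4)
  # remaining band strengths are spectroscopically negligible
  b <- fit$params$bands
  expect_lt(max(b$nup^2 / (b$nu0 * b$gamma)), 1e-3)
  expect_lt(abs(fit$params$eps_inf - 1), 0.05)
})

test_that("reconstruction is deterministic", {
  truth <- separated_truth(2, seed = 33)
  given <- simulate_given_qext(truth, sph, tiny_grid(80))$observed
  cfg <- fit_config(n_bands = 4, init_scheme = "case1", max_iter = 60)
  f1 <- reconstruct_from_qext(given, sph, cfg)
  f2 <- reconstruct_from_qext(given, sph, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$objective_S, f2$objective_S)
  expect_error(reconstruct_from_qext(given, sph,
                                     fit_config(basis = "antisym")),
               "dielectric")
})

test_that("reconstruction degrades gracefully under 1 percent noise", {
  medians <- vapply(1:10, function(seed) {
    truth <- separated_truth(3, seed = 40 + seed)
    sim <- simulate_given_qext(truth, sph, tiny_grid(200),
                               noise_model(0.01, seed = seed))
    cfg <- fit_config(n_bands = 6, init_scheme = "case1", max_iter = 200,
                      max_reseeds = 2L)
    fit <- reconstruct_from_qext(sim$observed, sph, cfg)
    stats::median(abs(match_bands(fit$params, truth)$pairs$d_nu0))
  }, numeric(1))
  expect_lt(stats::median(medians), 5)
})

test_that("direct permittivity fit recovers a representable target", {
  truth <- separated_truth(3, seed = 51)
  g <- tiny_grid(250)
  eps <- eval_permittivity(truth, g)
  cfg <- fit_config(n_bands = 3, init_scheme = "peaks", max_iter = 400)
  fit <- fit_permittivity_direct(eps, cfg)
  scale <- max(abs(eps$eps_real), eps$eps_imag)
  expect_lt(max(abs(fit$residual_errors$e_real)), 1e-6 * scale)
  expect_lt(max(abs(fit$residual_errors$e_imag)), 1e-6 * scale)
  mb <- match_bands(fit$params, truth)
  expect_lt(max(abs(mb$pairs$d_nu0)), 0.1)
})

test_that("a constant target collapses to the offset", {
  g <- tiny_grid(50)
  eps <- dielectric_spectrum(g, rep(2.6, length(g)), rep(0, length(g)))
  cfg <- fit_config(n_bands = 2, init_scheme = "case1", max_iter = 200,
                    max_reseeds = 0L)
  fit <- fit_permittivity_direct(eps, cfg)
  expect_equal(fit$params$eps_inf, 2.6, tolerance = 1e-3)
  expect_lt(max(fit$params$bands$nup^2 / (fit$params$bands$nu0 *
                                          fit$params$bands$gamma)), 1e-3)
})

test_that("direct and inverse fits agree on well-separated truths", {
  truth <- separated_truth(2, seed = 61)
  g <- tiny_grid(150)
  sim <- simulate_given_qext(truth, sph, g)
  cfg <- fit_config(n_bands = 4, init_scheme = "case1", max_iter = 300)
  fit_q <- reconstruct_from_qext(sim$observed, sph, cfg)
  fit_e <- fit_permittivity_direct(sim$truth_eps, cfg)
  c_q <- match_bands(fit_q$params, truth)$pairs$fitted_nu0
  c_e <- match_bands(fit_e$params, truth)$pairs$fitted_nu0
  expect_equal(c_q, c_e, tolerance = 1e-2)
})

test_that("band matching is exact, order-free and drops dead oscillators", {
  truth <- oscillator_set(c(800, 1600, 3000), c(100, 150, 90), c(20, 25, 30))
  # identical sets match with zero error
  mb <- match_bands(truth, truth)
  expect_equal(mb$pairs$d_nu0, rep(0, 3))
  expect_equal(mb$n_unmatched_truth, 0L)
  # an extra zero-strength band is discarded before matching
  padded <- oscillator_set(c(800, 1600, 2200, 3000), c(100, 150, 0, 90),
                           c(20, 25, 20, 30))
  mb2 <- match_bands(padded, truth)
  expect_equal(mb2$n_discarded, 1L)
  expect_equal(mb2$pairs$d_nu0, rep(0, 3))
  # input order is irrelevant (constructor canonicalises)
  permuted <- oscillator_set(c(3000, 800, 1600), c(90, 100, 150), c(30, 20, 25))
  expect_equal(match_bands(permuted, truth)$pairs$d_nu0, rep(0, 3))
})

test_that("reconstruction error metrics are the relative L2 norms", {
  truth <- separated_truth(2, seed = 71)
  eps <- eval_permittivity(truth, tiny_grid(60))
  expect_equal(reconstruction_error_metrics(eps, eps),
               list(rel_l2_eps_real = 0, rel_l2_eps_imag = 0))
  scaled <- dielectric_spectrum(eps$grid, eps$eps_real, 1.1 * eps$eps_imag)
  em <- reconstruction_error_metrics(scaled, eps)
  expect_equal(em$rel_l2_eps_imag, 0.1, tolerance = 1e-12)
  expect_equal(em$rel_l2_eps_real, 0)
  other <- eval_permittivity(truth, tiny_grid(61))
  expect_error(reconstruction_error_metrics(other, eps), "align")
})
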