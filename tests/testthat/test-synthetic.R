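test_that("material generation is deterministic and respects the recipe", {
  r <- material_recipe(seed = 11)
  m1 <- generate_material(r)
  m2 <- generate_material(r)
  expect_identical(m1, m2)
  m3 <- generate_material(material_recipe(seed = 12))
  expect_false(identical(m1$bands$nu0, m3$bands$nu0))
  # counts per interval and pairwise separation
  expect_equal(nrow(m1$bands), 18L)
  expect_equal(sum(m1$bands$nu0 <= 2200), 14L)
  expect_equal(sum(m1$bands$nu0 >= 2800), 4L)
  d <- diff(sort(m1$bands$nu0[m1$bands$nu0 <= 2200]))
  expect_true(all(d >= 50))
  # infeasible packing errors out
  expect_error(generate_material(
    material_recipe(n_bands = 10L, intervals = data.frame(lo = 1000, hi = 1400),
                    min_separation = 50)), "cannot hold")
  expect_error(material_recipe(n_bands = 2L,
                               intervals = data.frame(lo = 1000, hi = 1100)),
               "no room")
})

test_that("generated materials leave the silent windows silent", {
  # band centres never fall in the windows; what remains there is Lorentzian
  # tail, bounded by (gamma / 2 distance)^2 of the nearest band's peak --
  # about 1e-2 at the default edge margin (see the methods vignette)
  g <- default_grid(n = 400)
  nu <- as.numeric(g)
  silent <- (nu > 2200 & nu < 2800) | nu > 3500
  for (seed in c(2, 9, 23)) {
    m <- generate_material(material_recipe(seed = seed))
    expect_false(any((m$bands$nu0 > 2050 & m$bands$nu0 < 2950) |
                     m$bands$nu0 > 3350))
    im <- eval_permittivity(m, g)$eps_imag
    expect_lt(max(im[silent]), 1e-2 * max(im))
  }
})

test_that("polymer fixtures carry their published band positions", {
  expect_true(1730 %in% polymer_fixture("PMMA")$bands$nu0)
  pei <- polymer_fixture("PEI")$bands$nu0
  expect_true(all(c(1720, 1780, 1355, 743, 1234) %in% pei))
  expect_true(all(c(2970, 1772, 1500, 1080, 1015, 830) %in%
                  polymer_fixture("PC")$bands$nu0))
  for (nm in c("PMMA", "PC", "PDMS", "PEI", "PET", "PS")) {
    f <- polymer_fixture(nm)
    sp <- eval_permittivity(f, default_grid(n = 150))
    expect_true(all(sp$eps_imag >= 0))
  }
  expect_error(polymer_fixture("PTFE"), "unknown polymer")
})

test_that("simulation reproduces the noiseless protocol and seeds its noise", {
  m <- polymer_fixture("PS")
  g <- tiny_grid(80)
  s0 <- simulate_given_qext(m, sphere_model(5), g)
  expect_identical(s0$observed$qext, s0$truth$qext)
  # truth equals the explicit forward chain
  q <- forward_qext(eps_to_n(eval_permittivity(m, g)), sphere_model(5))
  expect_equal(s0$truth$qext, q$qext)
  # seeded noise: reproducible, and only the stochastic part changes
  sA <- simulate_given_qext(m, sphere_model(5), g, noise_model(0.02, seed = 5))
  sB <- simulate_given_qext(m, sphere_model(5), g, noise_model(0.02, seed = 5))
  sC <- simulate_given_qext(m, sphere_model(5), g, noise_model(0.02, seed = 6))
  expect_identical(sA$observed$qext, sB$observed$qext)
  expect_false(identical(sA$observed$qext, sC$observed$qext))
  expect_identical(sA$truth$qext, sC$truth$qext)
  # 2 percent relative noise stays near 2 percent
  rel <- abs(sA$observed$qext - sA$truth$qext) / sA$truth$qext
  expect_lt(max(rel), 0.1)
  expect_gt(stats::sd(rel), 0)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_material(material_recipe(seed = 3)))
  invisible(simulate_given_qext(polymer_fixture("PMMA"), sphere_model(5),
                                tiny_grid(40), noise_model(0.01, seed = 4)))
  expect_identical(.Random.seed, before)
})
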