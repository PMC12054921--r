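# Shared in-code fixtures for the test suite.

# Small uniform grid for cheap forward/inverse runs
tiny_grid <- function(n = 120L) spectral_grid(seq(500, 4000, length.out = n))

# A well-separated synthetic truth inside the mid-IR window: M bands drawn
# from the fingerprint/stretch intervals with a generous minimum separation.
separated_truth <- function(M, seed) {
  generate_material(material_recipe(
    n_bands = M,
    intervals = data.frame(lo = 700, hi = 3400),
    min_separation = 320,
    nup_range = c(100, 220), gamma_range = c(15, 35),
    eps_inf_range = c(2.1, 2.7),
    seed = seed))
}

# Maclaurin principal-value transform used as an independent oracle for the
# Hilbert-pair checks (straight-line implementation, no shortcuts)
pv_hilbert_real_from_imag <- function(nu, im, targets_idx) {
  h <- nu[2L] - nu[1L]
  vapply(targets_idx, function(i) {
    j <- seq_along(nu)[(seq_along(nu) - i) %% 2L == 1L]
    (2 / pi) * 2 * h * sum(nu[j] * im[j] / (nu[j]^2 - nu[i]^2))
  }, numeric(1))
}
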