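# mieinvert

Direct inverse-scattering reconstruction of mid-infrared optical constants
from extinction spectra of wavelength-scale spheres.

## The problem

Infrared microspectroscopy of single biological cells (and of polymer
microspheres used as model cells) measures an *apparent absorbance*: because
the sample is about as large as the IR wavelength, the light missing at the
detector has been both absorbed **and** scattered, so the recorded spectrum
mixes the chemical fingerprint with strong, shape-dependent Mie scattering
(baseline distortion, band shifts, derivative-like line shapes).  The
quantity that actually encodes the chemistry is the complex relative
permittivity ε̃(ν̃) = ε′(ν̃) + iε″(ν̃) — equivalently the complex refractive
index ñ = √ε̃ — and recovering it from the measured extinction efficiency
Q_ext(ν̃) is an inverse scattering problem.

`mieinvert` solves that problem directly, without a separate
scatter-correction step.  The permittivity is represented as a superposition
of M Lorentz oscillator bands,

    ε′(ν̃) = ε_∞ + Σ_m ν̃_p⁽ᵐ⁾² (ν̃₀⁽ᵐ⁾² − ν̃²) / [(ν̃₀⁽ᵐ⁾² − ν̃²)² + (ν̃ γ⁽ᵐ⁾)²]
    ε″(ν̃) =       Σ_m ν̃ γ⁽ᵐ⁾ ν̃_p⁽ᵐ⁾²      / [(ν̃₀⁽ᵐ⁾² − ν̃²)² + (ν̃ γ⁽ᵐ⁾)²]

with band centre ν̃₀, strength ν̃_p and width γ (all cm⁻¹).  Each band is
Kramers-Kronig consistent by construction, so every candidate spectrum is
causal and physically admissible.  A Lorenz-Mie forward model maps any
candidate ε̃(ν̃) plus a sphere radius to Q_ext(ν̃), and a bounded
Levenberg-Marquardt fit minimises the residual sum of squares

    S = Σ_l [Q_ext^model(ν̃_l) − Q_ext^given(ν̃_l)]²

over the 3M + 1 parameters {ν̃₀⁽ᵐ⁾, ν̃_p⁽ᵐ⁾, γ⁽ᵐ⁾, ε_∞}, with the physical
constraints ν̃_p ≥ 0, γ > 0 enforced as box bounds.  Two initializations are
built in: an unbiased equi-spaced band comb over the fitting window
("Case I") and an informed placement that skips the mid-IR silent windows
2200–2800 and 3500–4000 cm⁻¹ ("Case II").

The package also provides: a direct permittivity-fitting mode (no Mie model
in the loop) for validating the basis; an anti-symmetrized-Lorentzian
comparison basis with sign-free amplitudes; a numerical Kramers-Kronig
validator (Maclaurin principal-value rule); a seeded generator of
polymer-like synthetic materials and band-catalogue fixtures for six common
polymers (PMMA, PC, PDMS, PEI, PET, PS); delimited-text I/O for dispersion,
permittivity and extinction tables; and a command-line interface.

## Worked example

Simulate the extinction spectrum of a 5 µm PMMA-like sphere on the default
600-point grid (500–4000 cm⁻¹), then reconstruct its permittivity from the
spectrum alone:

```r
library(mieinvert)

material <- polymer_fixture("PMMA")     # 3 bands at published positions
sphere   <- sphere_model(radius_um = 5)
sim      <- simulate_given_qext(material, sphere, default_grid())

cfg <- fit_config(n_bands = 6, init_scheme = "case2",
                  intervals = data.frame(lo = c(500, 2800),
                                         hi = c(2200, 3500),
                                         count = c(4L, 2L)))
fit <- reconstruct_from_qext(sim$observed, sphere, cfg)
fit
#> <fit_result> dielectric basis, 6 band(s), S = 1.31895e-18 (from 67.9175),
#>   converged after 86 evals

match_bands(fit$params, material)$pairs
#>   truth_nu0 fitted_nu0 d_nu0 d_nup d_gamma
#> 1      1150       1150     0     0       0
#> 2      1730       1730     0     0       0
#> 3      2900       2900     0     0       0

reconstruction_error_metrics(fit, sim$truth_eps)
#> relative L2 error: eps_real 7.24e-12, eps_imag 1.64e-10
```

The objective drops from 67.9 (the unbiased start) to 1.3e-18: the three
true band centres (1150, 1730, 2900 cm⁻¹ — the C-O, C=O and C-H bands) are
recovered to machine precision and the three surplus basis functions die
away.  `fit$params$eps_inf` returns the recovered constant offset, and
`eval_permittivity(fit$params, grid)` evaluates the reconstructed ε̃ on any
grid.

## Command line

```sh
inst/cli/mieinvert simulate --output run --seed 7 --radius-um 5
inst/cli/mieinvert invert --input run_qext.csv --output run_fit \
    --n-bands 25 --init case2 --radius-um 5
inst/cli/mieinvert kk-check --input eps.csv --output kk.json --eps-inf 2.25
```

Every run writes a `*_manifest.json` with the effective configuration and
seeds, sufficient to reproduce its artifacts exactly.

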