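#' Recipe for a synthetic polymer-like material
#'
#' Describes the statistical structure of mid-IR organic-polymer dispersion:
#' absorption bands concentrated in the fingerprint interval (500--2200
#' cm^-1) and the C-H stretch interval (2800--3500 cm^-1), with the silent
#' windows 2200--2800 and 3500--4000 cm^-1 left empty.  Organic polymers
#' typically show 15--20 bands of substantial intensity, which the default
#' counts reflect.
#'
#' @param n_bands integer vector: bands per interval (same length as
#'   `intervals` rows).  Default `c(14, 4)`.
#' @param intervals data.frame with columns `lo`, `hi` in cm^-1; default the
#'   two absorbing intervals above.
#' @param nup_range,gamma_range uniform sampling ranges for strength and
#'   width, cm^-1.
#' @param eps_inf_range uniform sampling range for the constant offset.
#' @param min_separation minimum distance between band centres, cm^-1.
#' @param edge_margin clearance, cm^-1, between sampled band centres and the
#'   interval edges.  Real polymer bands do not sit at the silent-window
#'   boundaries, and without clearance the Lorentzian tails of edge bands
#'   would bleed into the windows; 150 cm^-1 keeps the windows
#'   spectroscopically quiet for the default width range.
#' @param seed integer seed; the recipe is deterministic given the seed.
#' @return an object of class `"material_recipe"`.
#' @export
material_recipe <- function(n_bands = c(14L, 4L),
                            intervals = data.frame(lo = c(500, 2800),
                                                   hi = c(2200, 3500)),
                            nup_range = c(50, 250),
                            gamma_range = c(10, 40),
                            eps_inf_range = c(2, 3),
                            min_separation = 50,
                            edge_margin = 150,
                            seed = 1L) {
  if (length(n_bands) != nrow(intervals))
    stop("n_bands must have one count per interval")
  if (any(intervals$lo >= intervals$hi)) stop("intervals must have lo < hi")
  ranges <- list(nup = nup_range, gamma = gamma_range, eps_inf = eps_inf_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 0)
      stop("invalid range for ", nm)
  }
  if (min_separation < 0) stop("min_separation must be non-negative")
  if (edge_margin < 0) stop("edge_margin must be non-negative")
  if (any(intervals$hi - intervals$lo <= 2 * edge_margin & n_bands > 0))
    stop("edge_margin leaves no room inside an interval")
  structure(list(n_bands = as.integer(n_bands), intervals = intervals,
                 nup_range = nup_range, gamma_range = gamma_range,
                 eps_inf_range = eps_inf_range,
                 min_separation = min_separation, edge_margin = edge_margin,
                 seed = as.integer(seed)),
            class = "material_recipe")
}

#' Multiplicative noise model for simulated extinction spectra
#'
#' i.i.d. Gaussian relative noise on Qext: `observed = truth * (1 + eta)`,
#' `eta ~ N(0, relative_sigma^2)`.  `relative_sigma = 0` (the default
#' protocol) reproduces noiseless forward simulations.
#'
#' @param relative_sigma relative standard deviation, `>= 0`.
#' @param seed integer seed for the noise draw.
#' @return an object of class `"noise_model"`.
#' @export
noise_model <- function(relative_sigma = 0, seed = 1L) {
  if (!is.finite(relative_sigma) || relative_sigma < 0)
    stop("relative_sigma must be non-negative")
  structure(list(relative_sigma = relative_sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Draw a synthetic polymer-like material
#'
#' Samples band centres uniformly within the recipe's absorbing intervals
#' (rejection-sampled until all pairwise distances respect
#' `min_separation`), strengths and widths uniformly within their ranges,
#' and `eps_inf` within its range.  Deterministic for a fixed seed; the
#' global RNG state is left untouched.
#'
#' @param recipe a [material_recipe()].
#' @param max_tries rejection-sampling budget per interval.
#' @return an [oscillator_set()] in canonical order.
#' @examples
#' generate_material(material_recipe(seed = 42))
#' @export
generate_material <- function(recipe, max_tries = 2000L) {
  stopifnot(inherits(recipe, "material_recipe"))
  rng <- local_rng(recipe$seed)
  centers <- numeric(0)
  for (i in seq_along(recipe$n_bands)) {
    k <- recipe$n_bands[i]
    if (k == 0L) next
    lo <- recipe$intervals$lo[i] + recipe$edge_margin
    hi <- recipe$intervals$hi[i] - recipe$edge_margin
    if ((hi - lo) < (k - 1L) * recipe$min_separation)
      stop("interval ", lo, "-", hi, " cannot hold ", k,
           " bands at separation ", recipe$min_separation)
    got <- numeric(0)
    tries <- 0L
    while (length(got) < k) {
      cand <- rng$runif(1L, lo, hi)
      if (!length(got) || min(abs(got - cand)) >= recipe$min_separation) {
        got <- c(got, cand)
      } else {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("could not place ", k, " bands at separation ",
               recipe$min_separation, " in ", lo, "-", hi)
      }
    }
    centers <- c(centers, got)
  }
  M <- length(centers)
  if (M < 1L) stop("recipe produces no bands")
  nup <- rng$runif(M, recipe$nup_range[1L], recipe$nup_range[2L])
  gam <- rng$runif(M, recipe$gamma_range[1L], recipe$gamma_range[2L])
  eps_inf <- rng$runif(1L, recipe$eps_inf_range[1L], recipe$eps_inf_range[2L])
  oscillator_set(centers, nup, gam, eps_inf = eps_inf)
}

## Band catalogues for the six test polymers.  Centres are the published
## mid-IR band positions (midpoints for published ranges); strengths and
## widths are plausible synthetic stand-ins, NOT measured values -- the
## fixtures emulate the character of each material, not its actual optical
## constants.
polymer_catalog <- list(
  PMMA = list(eps_inf = 2.20,
              nu0   = c(1150, 1730, 2900),
              nup   = c(180, 220, 120),
              gamma = c(35, 22, 40)),
  PC   = list(eps_inf = 2.50,
              nu0   = c(830, 1015, 1080, 1500, 1772, 2970),
              nup   = c(100, 150, 160, 130, 180, 90),
              gamma = c(20, 22, 24, 18, 20, 35)),
  PDMS = list(eps_inf = 2.00,
              nu0   = c(794.5, 1057, 1259.5, 2905),
              nup   = c(200, 230, 150, 100),
              gamma = c(25, 30, 14, 35)),
  PEI  = list(eps_inf = 2.60,
              nu0   = c(743, 1234, 1355, 1720, 1780),
              nup   = c(120, 160, 140, 190, 110),
              gamma = c(18, 22, 20, 18, 16)),
  PET  = list(eps_inf = 2.40,
              nu0   = c(1100, 1300, 1720, 2950),
              nup   = c(150, 170, 200, 100),
              gamma = c(28, 26, 20, 45)),
  PS   = list(eps_inf = 2.50,
              nu0   = c(727, 1526, 2886.5, 3053),
              nup   = c(190, 120, 110, 90),
              gamma = c(20, 25, 30, 22)))

#' Synthetic stand-in material for a named test polymer
#'
#' Builds an [oscillator_set()] whose band centres are the published mid-IR
#' band positions of the named polymer (midpoints for published ranges).
#' Strengths and widths are plausible synthetic defaults, fixed per package
#' version and documented in the band catalogue -- they are stand-ins for
#' measured optical constants, not reproductions of them.
#'
#' @param name one of `"PMMA"`, `"PC"`, `"PDMS"`, `"PEI"`, `"PET"`, `"PS"`.
#' @return an [oscillator_set()].
#' @examples
#' polymer_fixture("PMMA")   # carbonyl band at 1730 cm^-1
#' @export
polymer_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% names(polymer_catalog)))
    stop("unknown polymer; use one of ",
         paste(names(polymer_catalog), collapse = ", "))
  p <- polymer_catalog[[name]]
  oscillator_set(p$nu0, p$nup, p$gamma, eps_inf = p$eps_inf)
}

#' Simulate a given extinction spectrum from a known material
#'
#' The first step of the two-step validation protocol: assume full knowledge
#' of the material, compute its extinction efficiency exactly with the
#' forward model, and (optionally) corrupt it with seeded multiplicative
#' noise.  The noiseless truth is always returned alongside the observed
#' spectrum so recovery experiments can score themselves.
#'
#' @param material an [oscillator_set()].
#' @param sphere a [sphere_model()].
#' @param grid a [spectral_grid()]; defaults to 600 points over 500--4000
#'   cm^-1.
#' @param noise a [noise_model()]; default noiseless.
#' @return list with `observed` and `truth` (both [extinction_spectrum()])
#'   and `truth_eps` (the material's [dielectric_spectrum()] on the grid).
#' @export
simulate_given_qext <- function(material, sphere = sphere_model(5),
                                grid = default_grid(),
                                noise = noise_model(0)) {
  stopifnot(inherits(material, "oscillator_set"),
            inherits(sphere, "sphere_model"),
            inherits(noise, "noise_model"))
  grid <- as_grid(grid)
  eps <- eval_permittivity(material, grid)
  truth <- forward_qext(eps_to_n(eps), sphere)
  observed <- truth
  if (noise$relative_sigma > 0) {
    rng <- local_rng(noise$seed)
    eta <- rng$rnorm(length(truth$qext), 0, noise$relative_sigma)
    observed <- extinction_spectrum(grid, pmax(truth$qext * (1 + eta), 0))
  }
  list(observed = observed, truth = truth, truth_eps = eps)
}
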