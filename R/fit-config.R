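#' Configuration of a reconstruction fit
#'
#' Collects everything that defines a fit: model size, spectral window,
#' initialization scheme, parameter bounds, optimizer tolerances and budget,
#' and the seed of any stochastic element (jittered multi-start).  A config
#' plus the input spectrum determines a fit bit-for-bit.
#'
#' Initialization schemes:
#' \describe{
#'   \item{`case1`}{no prior knowledge: `n_bands` band centres equi-spaced
#'     (endpoints included) over `nu_range`, all strengths and widths at
#'     20 cm^-1.}
#'   \item{`case2`}{organic-polymer prior: bands allocated only to the
#'     absorbing intervals, by default 20 bands in 500--2200 cm^-1 and 5 in
#'     2800--3500 cm^-1, skipping the silent windows 2200--2800 and
#'     3500--4000 cm^-1; strengths and widths again 20 cm^-1.}
#'   \item{`peaks`}{data-driven: band centres at the `n_bands` highest local
#'     maxima of the target's imaginary part (direct permittivity fits
#'     only).}
#'   \item{`explicit`}{a user-supplied [oscillator_set()] in
#'     `explicit_init`.}
#' }
#'
#' @param n_bands number of basis functions `M` (25 by default; each band
#'   carries 3 parameters, so the default search space has 75 band
#'   parameters plus `eps_inf`).
#' @param nu_range fitting window `c(low, high)` in cm^-1.
#' @param init_scheme one of `"case1"`, `"case2"`, `"peaks"`, `"explicit"`.
#' @param intervals for `case2`: data.frame with columns `lo`, `hi`, `count`;
#'   default is the polymer allocation described above.  [init_case2()]
#'   errors if the counts do not sum to `n_bands`.
#' @param explicit_init an [oscillator_set()] for `init_scheme = "explicit"`.
#' @param eps_inf_init initial constant offset (2.25, i.e. n of about 1.5).
#' @param bounds named list with elements `nu0`, `nup`, `gamma`, `eps_inf`,
#'   each `c(lower, upper)`.  Defaults: `nu0` within `nu_range` widened by
#'   100 cm^-1, `nup` in \[0, 2000\], `gamma` in \[1, 400\], `eps_inf` in
#'   \[1, 6\].  The lower bounds on `nup` enforce the physical
#'   non-negativity of the dielectric basis.
#' @param basis `"dielectric"` (bounded Lorentz bands) or `"antisym"`
#'   (anti-symmetrized Lorentzians with sign-free amplitudes; direct
#'   permittivity fits only).
#' @param rel_tol,step_tol,max_iter,max_evals optimizer stopping rules:
#'   relative objective change, relative parameter step, iteration cap,
#'   residual-evaluation cap.
#' @param max_reseeds after the first optimization pass, up to this many
#'   deterministic refinement passes: the k weakest bands are re-seeded at
#'   the k largest residual peaks (k starts at 1 and escalates by one after
#'   every pass that fails to improve, resetting on improvement) and the fit
#'   is re-run, keeping the result only if the objective improves.  This
#'   recovers bands that an earlier pass parked at zero strength (where
#'   their gradient vanishes exactly) and escapes entangled local minima
#'   that single-band moves re-enter.  Set to 0 for a single plain pass.
#' @param reseed_rel_S stop re-seeding once `S` falls below this fraction of
#'   the squared norm of the target.
#' @param n_starts number of jittered restarts (1 = single start, the
#'   default); requires `seed` when larger than 1.
#' @param jitter_sd standard deviation of the multiplicative jitter applied
#'   to band centres on restarts, as a fraction of the window width.
#' @param seed integer seed for the jitter; ignored for single starts.
#' @return an object of class `"fit_config"`.
#' @export
fit_config <- function(n_bands = 25L,
                       nu_range = c(500, 4000),
                       init_scheme = c("case1", "case2", "peaks", "explicit"),
                       intervals = NULL,
                       explicit_init = NULL,
                       eps_inf_init = 2.25,
                       bounds = NULL,
                       basis = c("dielectric", "antisym"),
                       rel_tol = 1e-10, step_tol = 1e-8,
                       max_iter = 400L, max_evals = 40000L,
                       max_reseeds = 6L, reseed_rel_S = 1e-9,
                       n_starts = 1L, jitter_sd = 0.02, seed = NULL) {
  init_scheme <- match.arg(init_scheme)
  basis <- match.arg(basis)
  n_bands <- as.integer(n_bands)
  if (n_bands < 1L) stop("n_bands must be at least 1")
  if (length(nu_range) != 2L || nu_range[1L] >= nu_range[2L])
    stop("nu_range must be c(low, high) with low < high")
  if (is.null(intervals))
    intervals <- data.frame(lo = c(500, 2800), hi = c(2200, 3500),
                            count = c(20L, 5L))
  if (!all(c("lo", "hi", "count") %in% names(intervals)))
    stop("intervals needs columns lo, hi, count")
  if (any(intervals$lo >= intervals$hi)) stop("intervals must have lo < hi")
  default_bounds <- list(nu0 = c(nu_range[1L] - 100, nu_range[2L] + 100),
                         nup = c(0, 2000), gamma = c(1, 400),
                         eps_inf = c(1, 6))
  if (is.null(bounds)) bounds <- list()
  bounds <- utils::modifyList(default_bounds, bounds)
  for (nm in names(default_bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1L] > b[2L]) stop("invalid bounds for ", nm)
  }
  if (bounds$nup[1L] < 0 || bounds$gamma[1L] < 0)
    stop("lower bounds for nup and gamma must be non-negative")
  if (init_scheme == "explicit" && !inherits(explicit_init, "oscillator_set"))
    stop("explicit init_scheme requires explicit_init")
  if (n_starts > 1L && is.null(seed))
    stop("multi-start fits require a seed")
  structure(list(n_bands = n_bands, nu_range = as.numeric(nu_range),
                 init_scheme = init_scheme, intervals = intervals,
                 explicit_init = explicit_init,
                 eps_inf_init = eps_inf_init, bounds = bounds, basis = basis,
                 rel_tol = rel_tol, step_tol = step_tol,
                 max_iter = as.integer(max_iter),
                 max_evals = as.integer(max_evals),
                 max_reseeds = as.integer(max_reseeds),
                 reseed_rel_S = reseed_rel_S,
                 n_starts = as.integer(n_starts), jitter_sd = jitter_sd,
                 seed = seed),
            class = "fit_config")
}

#' @export
print.fit_config <- function(x, ...) {
  cat(sprintf("<fit_config> %d bands, %s basis, init %s, window %g-%g cm^-1\n",
              x$n_bands, x$basis, x$init_scheme,
              x$nu_range[1L], x$nu_range[2L]))
  invisible(x)
}

#' Unbiased equi-spaced initialization (Case I)
#'
#' Places the `n_bands` band centres uniformly over the fitting window,
#' endpoints included, with every strength and width at 20 cm^-1.  Using the
#' same unbiased start for every material guarantees that a basis function is
#' always near an actual absorption band, which is what keeps the
#' high-dimensional fit out of distant local minima.
#'
#' @param config a [fit_config()] with `n_bands >= 2`.
#' @return an [oscillator_set()].
#' @examples
#' init_case1(fit_config(n_bands = 25))
#' @export
init_case1 <- function(config) {
  stopifnot(inherits(config, "fit_config"))
  if (config$n_bands < 2L) stop("case1 initialization needs at least 2 bands")
  centers <- seq(config$nu_range[1L], config$nu_range[2L],
                 length.out = config$n_bands)
  oscillator_set(centers, rep(20, config$n_bands), rep(20, config$n_bands),
                 eps_inf = config$eps_inf_init)
}

#' Prior-informed interval initialization (Case II)
#'
#' Allocates band centres only to the spectral intervals where organic
#' materials actually absorb, skipping the silent windows.  The default
#' allocation is 20 bands evenly over 500--2200 cm^-1 and 5 evenly over
#' 2800--3500 cm^-1, endpoints included (a single band in an interval sits at
#' its midpoint); strengths and widths start at 20 cm^-1.
#'
#' @param config a [fit_config()]; `sum(intervals$count)` must equal
#'   `n_bands`.
#' @return an [oscillator_set()].
#' @examples
#' init_case2(fit_config(n_bands = 25))
#' @export
init_case2 <- function(config) {
  stopifnot(inherits(config, "fit_config"))
  iv <- config$intervals
  if (sum(iv$count) != config$n_bands)
    stop("interval counts must sum to n_bands")
  centers <- unlist(lapply(seq_len(nrow(iv)), function(i) {
    k <- iv$count[i]
    if (k == 0L) return(numeric(0))
    if (k == 1L) return((iv$lo[i] + iv$hi[i]) / 2)
    seq(iv$lo[i], iv$hi[i], length.out = k)
  }))
  oscillator_set(centers, rep(20, length(centers)), rep(20, length(centers)),
                 eps_inf = config$eps_inf_init)
}

#' Peak-picking initialization for direct permittivity fits
#'
#' Seeds band centres at the `n_bands` most prominent local maxima of the
#' target's imaginary permittivity; the width starts at the estimated FWHM
#' of each peak and the strength at `sqrt(peak * nu0 * gamma)` (the exact
#' single-band peak relation inverted).  Falls back to equi-spaced filling
#' when the target has fewer resolved maxima than `n_bands`.
#'
#' @param eps a [dielectric_spectrum()] (the fit target).
#' @param config a [fit_config()].
#' @return an [oscillator_set()].
#' @export
init_peaks <- function(eps, config) {
  stopifnot(inherits(eps, "dielectric_spectrum"),
            inherits(config, "fit_config"))
  nu <- as.numeric(eps$grid); y <- eps$eps_imag
  L <- length(nu)
  is_max <- which(y[2:(L - 1L)] > y[1:(L - 2L)] &
                  y[2:(L - 1L)] >= y[3:L]) + 1L
  is_max <- is_max[order(y[is_max], decreasing = TRUE)]
  M <- config$n_bands
  centers <- nu[utils::head(is_max, M)]
  heights <- y[utils::head(is_max, M)]
  gammas <- vapply(seq_along(centers), function(k) {
    i <- is_max[k]; half <- y[i] / 2
    r <- i; while (r < L && y[r] > half) r <- r + 1L
    l <- i; while (l > 1L && y[l] > half) l <- l - 1L
    max(nu[r] - nu[l], 2 * mean(diff(nu)))
  }, numeric(1))
  if (length(centers) < M) {
    extra <- M - length(centers)
    fill <- seq(config$nu_range[1L], config$nu_range[2L],
                length.out = extra + 2L)[2:(extra + 1L)]
    centers <- c(centers, fill)
    heights <- c(heights, rep(max(y) * 1e-3 + 1e-12, extra))
    gammas <- c(gammas, rep(20, extra))
  }
  nup <- sqrt(pmax(heights, 1e-12) * centers * gammas)
  oscillator_set(centers, nup, pmax(gammas, config$bounds$gamma[1L]),
                 eps_inf = config$eps_inf_init)
}
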