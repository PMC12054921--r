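## Parameter packing -------------------------------------------------------

pack_params <- function(set) {
  if (inherits(set, "oscillator_set"))
    c(set$bands$nu0, set$bands$nup, set$bands$gamma, set$eps_inf)
  else if (inherits(set, "antisym_set"))
    c(set$bands$nu0, set$bands$h, set$bands$gamma, set$offset)
  else stop("unknown parameter set")
}

unpack_params <- function(theta, M, basis = "dielectric") {
  nu0 <- theta[seq_len(M)]
  amp <- theta[M + seq_len(M)]
  gam <- theta[2L * M + seq_len(M)]
  off <- theta[3L * M + 1L]
  if (basis == "dielectric") oscillator_set(nu0, amp, gam, eps_inf = off)
  else antisym_set(nu0, amp, gam, offset = off)
}

pack_bounds <- function(config, M) {
  b <- config$bounds
  if (config$basis == "dielectric") {
    amp <- b$nup
    off <- b$eps_inf
  } else {
    amp <- c(-b$nup[2L], b$nup[2L])       # sign-free amplitudes
    off <- sqrt(b$eps_inf)                # offset lives on the n scale
  }
  list(lower = c(rep(b$nu0[1L], M), rep(amp[1L], M), rep(b$gamma[1L], M),
                 off[1L]),
       upper = c(rep(b$nu0[2L], M), rep(amp[2L], M), rep(b$gamma[2L], M),
                 off[2L]))
}

## Analytic derivatives of the dielectric basis ----------------------------
## Returns eps parts and the L x (3M+1) Jacobians of eps' and eps''.

lorentz_eps_jac <- function(theta, nu) {
  M <- (length(theta) - 1L) %/% 3L
  L <- length(nu)
  nu0 <- theta[seq_len(M)]; nup <- theta[M + seq_len(M)]
  gam <- theta[2L * M + seq_len(M)]
  re <- numeric(L); im <- numeric(L)
  d_re <- matrix(0, L, 3L * M + 1L); d_im <- matrix(0, L, 3L * M + 1L)
  nu2 <- nu * nu
  for (m in seq_len(M)) {
    A <- nu0[m]^2 - nu2
    B <- nu * gam[m]
    den <- A * A + B * B
    P <- nup[m]^2
    re <- re + P * A / den
    im <- im + P * B / den
    den2 <- den * den
    d_re[, m]          <- 2 * nu0[m] * P * (B * B - A * A) / den2
    d_im[, m]          <- -4 * nu0[m] * P * A * B / den2
    d_re[, M + m]      <- 2 * nup[m] * A / den
    d_im[, M + m]      <- 2 * nup[m] * B / den
    d_re[, 2L * M + m] <- -2 * nu * P * A * B / den2
    d_im[, 2L * M + m] <- nu * P * (A * A - B * B) / den2
  }
  d_re[, 3L * M + 1L] <- 1
  list(re = re, im = im, d_re = d_re, d_im = d_im)
}

## Same for the anti-symmetrized Lorentzian basis.

antisym_eps_jac <- function(theta, nu) {
  M <- (length(theta) - 1L) %/% 3L
  L <- length(nu)
  nu0 <- theta[seq_len(M)]; h <- theta[M + seq_len(M)]
  gam <- theta[2L * M + seq_len(M)]
  re <- numeric(L); im <- numeric(L)
  d_re <- matrix(0, L, 3L * M + 1L); d_im <- matrix(0, L, 3L * M + 1L)
  for (m in seq_len(M)) {
    g2 <- gam[m] / 2
    z1 <- complex(real = nu0[m] - nu, imaginary = -g2)
    z2 <- complex(real = nu0[m] + nu, imaginary =  g2)
    f <- 1 / z1 + 1 / z2
    term <- h[m] * g2 * f
    re <- re + Re(term); im <- im + Im(term)
    d_h   <- g2 * f
    d_nu0 <- -h[m] * g2 * (1 / z1^2 + 1 / z2^2)
    d_gam <- 0.5 * h[m] * (f + g2 * (1i / z1^2 - 1i / z2^2))
    d_re[, m]          <- Re(d_nu0); d_im[, m]          <- Im(d_nu0)
    d_re[, M + m]      <- Re(d_h);   d_im[, M + m]      <- Im(d_h)
    d_re[, 2L * M + m] <- Re(d_gam); d_im[, 2L * M + m] <- Im(d_gam)
  }
  d_re[, 3L * M + 1L] <- 1
  list(re = re, im = im, d_re = d_re, d_im = d_im)
}

eps_jac <- function(theta, nu, basis) {
  if (basis == "dielectric") {
    out <- lorentz_eps_jac(theta, nu)
    out$re <- out$re + theta[length(theta)]
    return(out)
  }
  ## anti-symmetrized Lorentzian comparison basis: the *refractive index* is
  ## the basis superposition (offset + sum of anti-symmetrized Lorentzians),
  ## and the permittivity follows as eps = n^2.  This mirrors the historical
  ## refractive-index fitting approach the dielectric basis is compared
  ## against; because sqrt of a Lorentz sum is not itself a Lorentzian sum,
  ## surplus basis functions act as signed correction terms.
  nj <- antisym_eps_jac(theta, nu)
  nr <- nj$re + theta[length(theta)]
  ni <- nj$im
  list(re = nr^2 - ni^2,
       im = 2 * nr * ni,
       d_re = 2 * (nr * nj$d_re - ni * nj$d_im),
       d_im = 2 * (ni * nj$d_re + nr * nj$d_im))
}

## Residuals and objective --------------------------------------------------

#' Residuals of a candidate model against a given extinction spectrum
#'
#' `R(nu_l) = Qext_model(params; nu_l) - Qext_given(nu_l)`, where the model
#' spectrum is the forward Mie computation of the candidate permittivity.
#'
#' @param params an [oscillator_set()].
#' @param given an [extinction_spectrum()] on the fitting mesh.
#' @param sphere a [sphere_model()].
#' @return numeric residual vector, one entry per mesh point.
#' @export
residuals_qext <- function(params, given, sphere) {
  stopifnot(inherits(params, "oscillator_set"),
            inherits(given, "extinction_spectrum"),
            inherits(sphere, "sphere_model"))
  eps <- eval_permittivity(params, given$grid)
  nn <- eps_to_n_num(eps$eps_real, eps$eps_imag)
  forward_qext_num(nn$n_real, nn$n_imag, as.numeric(given$grid), sphere) -
    given$qext
}

#' Residual sum of squares of a candidate model
#'
#' The objective minimised by [reconstruct_from_qext()]:
#' `S = sum_l R(nu_l)^2`.
#'
#' @inheritParams residuals_qext
#' @return scalar `S >= 0`.
#' @export
objective_S <- function(params, given, sphere) {
  r <- residuals_qext(params, given, sphere)
  sum(r * r)
}

## Semi-analytic Jacobian of the Qext residuals: analytic d(eps)/d(theta),
## closed-form dn/d(eps) = 1/(2n), finite differences only for the scalar
## map Qext(n', n'') at each mesh point (4 extra forward passes, independent
## of the number of parameters).
qext_jacobian <- function(theta, nu, sphere, basis, h = 1e-6) {
  ej <- eps_jac(theta, nu, basis)
  nn <- eps_to_n_num(ej$re, pmax(ej$im, 0))
  nr <- nn$n_real; ni <- nn$n_imag

  qr_p <- forward_qext_num(nr + h, ni, nu, sphere)
  qr_m <- forward_qext_num(nr - h, ni, nu, sphere)
  dQdnr <- (qr_p - qr_m) / (2 * h)
  hm <- pmin(h, ni)                      # keep n'' non-negative
  qi_p <- forward_qext_num(nr, ni + h, nu, sphere)
  qi_m <- forward_qext_num(nr, ni - hm, nu, sphere)
  dQdni <- (qi_p - qi_m) / (h + hm)

  ## dn/deps from 1/(2n): u + iv
  mod2 <- 2 * (nr^2 + ni^2)
  u <- nr / mod2; v <- -ni / mod2
  ## dQ/deps' and dQ/deps'' per mesh point
  dQdepsr <- dQdnr * u + dQdni * v
  dQdepsi <- -dQdnr * v + dQdni * u
  ej$d_re * dQdepsr + ej$d_im * dQdepsi
}

## Fit front ends -----------------------------------------------------------

make_fit_result <- function(opt, M, basis, model_spectrum, initial_S, config,
                            extra = list()) {
  res <- c(list(params = unpack_params(opt$par, M, basis),
                objective_S = opt$objective,
                residuals = opt$residuals,
                model_spectrum = model_spectrum,
                converged = opt$converged,
                n_evals = opt$n_evals, n_iter = opt$n_iter,
                initial_S = initial_S,
                basis = basis, config = config),
           extra)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s basis, %d band(s), S = %.6g (from %.6g), %s after %d evals\n",
              x$basis, nrow(x$params$bands), x$objective_S, x$initial_S,
              if (x$converged) "converged" else "NOT converged", x$n_evals))
  invisible(x)
}

initial_set <- function(config, target_eps = NULL) {
  set <- switch(config$init_scheme,
    case1 = init_case1(config),
    case2 = init_case2(config),
    peaks = {
      if (is.null(target_eps))
        stop("peaks initialization needs a permittivity target")
      init_peaks(target_eps, config)
    },
    explicit = config$explicit_init)
  if (config$basis == "antisym" && inherits(set, "oscillator_set")) {
    ## convert to the refractive-index scale: n'' peak of a weak band is
    ## roughly eps'' peak / (2 n_background)
    b <- set$bands
    n_off <- sqrt(set$eps_inf)
    set <- antisym_set(b$nu0, b$nup^2 / (b$nu0 * b$gamma) / (2 * n_off),
                       b$gamma, offset = n_off)
  }
  set
}

jitter_starts <- function(set, config) {
  ## first start is the unjittered initializer; later ones perturb centres
  starts <- list(pack_params(set))
  if (config$n_starts > 1L) {
    width <- diff(config$nu_range)
    M <- nrow(set$bands)
    rng <- local_rng(config$seed)
    for (k in seq_len(config$n_starts - 1L)) {
      th <- starts[[1L]]
      th[seq_len(M)] <- pmin(pmax(
        th[seq_len(M)] + rng$rnorm(M, 0, config$jitter_sd * width),
        config$nu_range[1L]), config$nu_range[2L])
      starts[[k + 1L]] <- th
    }
  }
  starts
}

## Shared optimization driver: jittered multi-start LM followed by
## deterministic residual-guided re-seeding.  `grid_nu` maps residual
## indices back to wavenumbers (residual vectors may stack several
## components per grid point); `target_norm2` scales the early-exit rule.
##
## Re-seeding escalates: the first pass moves the weakest band to the
## largest residual peak; each pass that fails to improve moves one more
## band (the k weakest to the k largest |R| local maxima), a progressively
## stronger perturbation that escapes entangled local minima where
## single-band moves immediately re-converge to the same point.  An
## improvement resets the escalation.
optimize_with_reseeds <- function(set0, fn_res, fn_jac, bnd, config,
                                  grid_nu, target_norm2) {
  run <- function(th0) {
    lm_bounded(th0, fn_res, fn_jac, bnd$lower, bnd$upper,
               rel_tol = config$rel_tol, step_tol = config$step_tol,
               max_iter = config$max_iter, max_evals = config$max_evals)
  }
  best <- NULL
  total_evals <- 0L
  for (th0 in jitter_starts(set0, config)) {
    opt <- run(th0)
    total_evals <- total_evals + opt$n_evals
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  M <- nrow(set0$bands)
  L <- length(grid_nu)
  amp0 <- if (config$basis == "dielectric") 20 else 0
  level <- 1L
  for (k in seq_len(config$max_reseeds)) {
    if (best$objective <= config$reseed_rel_S * target_norm2) break
    th <- best$par
    ## fold (possibly stacked) residuals into one magnitude per grid point
    r <- best$residuals
    rg <- sqrt(rowSums(matrix(r * r, nrow = L)))
    peaks <- which(rg[c(-1L, -L)] > rg[seq_len(L - 2L)] &
                   rg[c(-1L, -L)] >= rg[-seq_len(2L)]) + 1L
    peaks <- peaks[order(rg[peaks], decreasing = TRUE)]
    n_move <- min(level, M - 1L, length(peaks))
    if (n_move < 1L) break
    strength <- if (config$basis == "dielectric")
      th[M + seq_len(M)]^2 * th[2L * M + seq_len(M)]
    else abs(th[M + seq_len(M)]) * th[2L * M + seq_len(M)]
    weak <- order(strength)[seq_len(n_move)]
    tgt <- grid_nu[peaks[seq_len(n_move)]]
    th[weak] <- pmin(pmax(tgt, bnd$lower[weak]), bnd$upper[weak])
    th[M + weak] <- amp0
    th[2L * M + weak] <- pmax(20, bnd$lower[2L * M + weak])
    opt <- run(th)
    total_evals <- total_evals + opt$n_evals
    if (opt$objective < best$objective) {
      best <- opt
      level <- 1L
    } else {
      level <- level + 1L
    }
  }
  best$n_evals <- total_evals
  best
}

## Seeded RNG that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  use <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(rnorm = function(...) use(stats::rnorm(...)),
       runif = function(...) use(stats::runif(...)))
}

#' Reconstruct a permittivity from a given extinction spectrum
#'
#' The inverse-scattering engine: bounded nonlinear least squares over the
#' oscillator parameters (3M band parameters plus `eps_inf`), minimising the
#' residual sum of squares between the forward-model extinction spectrum and
#' the given one.  The bounds implement the physical non-negativity of the
#' dielectric basis (`nup >= 0`, `gamma > 0`), which is what keeps the
#' optimization numerically stable.  The run is deterministic for a fixed
#' config (multi-start jitter, if enabled, is seeded).
#'
#' @param given an [extinction_spectrum()] (the observable being inverted).
#' @param sphere a [sphere_model()]; the radius is treated as known.
#' @param config a [fit_config()] with `basis = "dielectric"`.
#' @return a `fit_result`: optimized [oscillator_set()] in `$params`,
#'   objective `$objective_S`, `$residuals`, the fitted `$model_spectrum`,
#'   convergence status and evaluation counts.
#' @examples
#' truth <- oscillator_set(1500, 150, 30)
#' g <- default_grid(n = 120)
#' given <- forward_qext(eps_to_n(eval_permittivity(truth, g)), sphere_model(5))
#' cfg <- fit_config(n_bands = 2, init_scheme = "case1", max_iter = 60)
#' fit <- reconstruct_from_qext(given, sphere_model(5), cfg)
#' @export
reconstruct_from_qext <- function(given, sphere, config = fit_config()) {
  stopifnot(inherits(given, "extinction_spectrum"),
            inherits(sphere, "sphere_model"),
            inherits(config, "fit_config"))
  if (config$basis != "dielectric")
    stop("Qext inversion requires the dielectric basis (a passive sphere)")
  if (anyNA(given$qext) || any(!is.finite(given$qext)))
    stop("given spectrum contains non-finite values")
  nu <- as.numeric(given$grid)
  set0 <- initial_set(config)
  M <- nrow(set0$bands)
  bnd <- pack_bounds(config, M)

  fn_res <- function(theta) {
    ej <- eps_jac(theta, nu, "dielectric")
    nn <- eps_to_n_num(ej$re, pmax(ej$im, 0))
    forward_qext_num(nn$n_real, nn$n_imag, nu, sphere) - given$qext
  }
  fn_jac <- function(theta) qext_jacobian(theta, nu, sphere, "dielectric")

  best <- optimize_with_reseeds(set0, fn_res, fn_jac, bnd, config,
                                grid_nu = nu,
                                target_norm2 = sum(given$qext^2))
  r0 <- fn_res(pack_params(set0))
  model <- extinction_spectrum(given$grid, best$residuals + given$qext)
  make_fit_result(best, M, "dielectric", model, sum(r0 * r0), config)
}

#' Fit a permittivity directly with a basis of dispersion functions
#'
#' Basis-validation mode: fits a (typically experimental or synthetic)
#' complex permittivity directly, without the Mie model in the loop, by
#' minimising `sum_l [e'(nu_l)^2 + e''(nu_l)^2]` where `e' = eps'_exp -
#' eps'_fit` and `e'' = eps''_exp - eps''_fit`.  With
#' `config$basis = "antisym"` the fit uses the anti-symmetrized-Lorentzian
#' comparison basis with sign-free amplitudes: the *refractive index* is
#' modelled as the basis superposition (as in the historical
#' index-of-refraction fitting approach) and the permittivity residuals are
#' computed from its square, so both bases compete on the identical target.
#'
#' @param exp_eps a [dielectric_spectrum()] (the target).
#' @param config a [fit_config()].
#' @return a `fit_result` with an extra element `residual_errors`: a list
#'   with `grid`, `e_real`, `e_imag` (target minus fit).
#' @export
fit_permittivity_direct <- function(exp_eps, config = fit_config()) {
  stopifnot(inherits(exp_eps, "dielectric_spectrum"),
            inherits(config, "fit_config"))
  nu <- as.numeric(exp_eps$grid)
  set0 <- initial_set(config, target_eps = exp_eps)
  M <- nrow(set0$bands)
  bnd <- pack_bounds(config, M)
  basis <- config$basis

  fn_res <- function(theta) {
    ej <- eps_jac(theta, nu, basis)
    c(ej$re - exp_eps$eps_real, ej$im - exp_eps$eps_imag)
  }
  fn_jac <- function(theta) {
    ej <- eps_jac(theta, nu, basis)
    rbind(ej$d_re, ej$d_im)
  }

  best <- optimize_with_reseeds(set0, fn_res, fn_jac, bnd, config,
                                grid_nu = nu,
                                target_norm2 = sum(exp_eps$eps_real^2 +
                                                   exp_eps$eps_imag^2))
  r0 <- fn_res(pack_params(set0))
  ej <- eps_jac(best$par, nu, basis)
  model <- list(grid = exp_eps$grid, eps_real = ej$re, eps_imag = ej$im)
  errors <- list(grid = exp_eps$grid,
                 e_real = exp_eps$eps_real - ej$re,
                 e_imag = exp_eps$eps_imag - ej$im)
  class(errors) <- "residual_errors"
  make_fit_result(best, M, basis, model, sum(r0 * r0), config,
                  extra = list(residual_errors = errors))
}

## Scoring ------------------------------------------------------------------

#' Match fitted bands against known truth bands
#'
#' Discards fitted bands whose strength `nup^2 * gamma` falls below
#' `strength_floor` times the strongest fitted band ("dead" oscillators the
#' fit parked at negligible amplitude), then finds the one-to-one pairing
#' that minimises the total centre displacement.  Both sets are in canonical
#' ascending-`nu0` order, for which the optimal pairing never crosses, so a
#' dynamic-programming alignment finds it exactly.
#'
#' @param fitted,truth [oscillator_set()] objects.
#' @param strength_floor relative strength threshold for dead bands.
#' @return a list: `pairs` (data.frame `truth_nu0`, `fitted_nu0`, `d_nu0`,
#'   `d_nup`, `d_gamma`), `n_unmatched_truth`, `n_unmatched_fitted`,
#'   `n_discarded`.
#' @export
match_bands <- function(fitted, truth, strength_floor = 1e-6) {
  stopifnot(inherits(fitted, "oscillator_set"),
            inherits(truth, "oscillator_set"))
  fb <- fitted$bands
  s <- fb$nup^2 * fb$gamma
  keep <- s >= strength_floor * max(s)
  n_discarded <- sum(!keep)
  fb <- fb[keep, , drop = FALSE]
  tb <- truth$bands

  swap <- nrow(tb) > nrow(fb)
  a <- if (swap) fb else tb           # smaller set, all of it gets matched
  b <- if (swap) tb else fb
  na <- nrow(a); nb <- nrow(b)
  ## non-crossing alignment DP on ascending centres
  cost <- matrix(Inf, na + 1L, nb + 1L)
  cost[1L, ] <- 0
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (j < i) next
    m <- cost[i, j] + abs(a$nu0[i] - b$nu0[j])
    cost[i + 1L, j + 1L] <- min(m, cost[i + 1L, j])
  }
  ## backtrack
  pairs_i <- integer(na); j <- nb + 1L
  for (i in seq(na + 1L, 2L)) {
    while (j > 2L && cost[i, j] == cost[i, j - 1L]) j <- j - 1L
    pairs_i[i - 1L] <- j - 1L
    j <- j - 1L
  }
  ai <- seq_len(na); bi <- pairs_i
  ti <- if (swap) bi else ai
  fi <- if (swap) ai else bi
  pairs <- data.frame(truth_nu0 = tb$nu0[ti],
                      fitted_nu0 = fb$nu0[fi],
                      d_nu0 = fb$nu0[fi] - tb$nu0[ti],
                      d_nup = fb$nup[fi] - tb$nup[ti],
                      d_gamma = fb$gamma[fi] - tb$gamma[ti])
  list(pairs = pairs,
       n_unmatched_truth = nrow(tb) - na,
       n_unmatched_fitted = nrow(fb) - na,
       n_discarded = n_discarded)
}

#' Relative L2 reconstruction errors against a known truth
#'
#' `||fit - truth||_2 / ||truth||_2` separately for the real and imaginary
#' permittivity components, on the truth's grid.
#'
#' @param fit a `fit_result` (dielectric basis; its parameters are evaluated
#'   on the truth grid) or a [dielectric_spectrum()] on the same grid.
#' @param truth a [dielectric_spectrum()].
#' @return list with `rel_l2_eps_real` and `rel_l2_eps_imag`.
#' @export
reconstruction_error_metrics <- function(fit, truth) {
  stopifnot(inherits(truth, "dielectric_spectrum"))
  if (inherits(fit, "fit_result")) {
    if (fit$basis != "dielectric")
      stop("error metrics need a dielectric-basis fit")
    fit <- eval_permittivity(fit$params, truth$grid)
  }
  stopifnot(inherits(fit, "dielectric_spectrum"))
  if (length(fit$grid) != length(truth$grid) ||
      any(abs(as.numeric(fit$grid) - as.numeric(truth$grid)) >
          1e-9 * max(as.numeric(truth$grid))))
    stop("grids do not align")
  l2 <- function(x) sqrt(sum(x * x))
  list(rel_l2_eps_real = l2(fit$eps_real - truth$eps_real) / l2(truth$eps_real),
       rel_l2_eps_imag = l2(fit$eps_imag - truth$eps_imag) / l2(truth$eps_imag))
}
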