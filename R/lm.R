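## Bounded Levenberg-Marquardt for least-squares residual vectors.
##
## Minimises sum(r(theta)^2) subject to box constraints by Marquardt-scaled
## damping, (J'J + lambda diag(J'J)) delta = -J'r, solved on the free
## parameter set (parameters pinned at a bound with the gradient pushing
## outward are held), with trial points clipped to the box and a cap on the
## relative step length.  The Jacobian is supplied by the caller (analytic
## or semi-analytic), so one iteration costs one Jacobian plus one residual
## evaluation regardless of the parameter count.
##
## Not exported: the fitting front ends (reconstruct_from_qext,
## fit_permittivity_direct) wrap it.

lm_bounded <- function(par, fn_res, fn_jac, lower, upper,
                       rel_tol = 1e-10, step_tol = 1e-8,
                       max_iter = 400L, max_evals = 40000L,
                       lambda0 = 1e-2, max_rel_step = 0.5) {
  p <- length(par)
  stopifnot(length(lower) == p, length(upper) == p, all(lower <= upper))
  par <- pmin(pmax(par, lower), upper)

  r <- fn_res(par)
  if (any(!is.finite(r))) stop("non-finite residuals at the initial point")
  S <- sum(r * r)
  n_evals <- 1L
  lambda <- lambda0
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter && n_evals < max_evals) {
    iter <- iter + 1L
    J <- fn_jac(par)
    if (any(!is.finite(J))) J[!is.finite(J)] <- 0
    g <- drop(crossprod(J, r))          # gradient / 2
    JtJ <- crossprod(J)
    ## relative floor keeps the damped normal matrix well conditioned even
    ## when a parameter's column is (currently) dead
    dmax <- max(diag(JtJ), .Machine$double.xmin)
    dscale <- pmax(diag(JtJ), 1e-8 * dmax)
    ## active set: hold parameters pinned at a bound with the gradient
    ## pushing outward (descent direction -g would leave the box)
    at_lo <- par <= lower & g > 0
    at_hi <- par >= upper & g < 0
    free <- which(!(at_lo | at_hi))
    if (!length(free)) { converged <- TRUE; break }

    improved <- FALSE
    tiny_step <- FALSE
    for (trial in 1:20) {
      delta <- rep(0, p)
      H <- JtJ[free, free, drop = FALSE] +
        lambda * diag(dscale[free], length(free))
      df <- tryCatch(solve(H, -g[free]), error = function(e) NULL)
      if (is.null(df)) { lambda <- lambda * 10; next }
      delta[free] <- df
      ## cap the relative step so a single near-Gauss-Newton move cannot
      ## fling the parameters across the box
      rel <- max(abs(delta) / pmax(abs(par), 1))
      if (rel > max_rel_step) delta <- delta * (max_rel_step / rel)
      cand <- pmin(pmax(par + delta, lower), upper)
      step <- cand - par
      if (max(abs(step) / pmax(abs(par), 1)) < step_tol) {
        tiny_step <- TRUE
        lambda <- lambda * 10
        if (lambda > 1e12) break
        next
      }
      r_new <- fn_res(cand)
      n_evals <- n_evals + 1L
      S_new <- if (any(!is.finite(r_new))) Inf else sum(r_new * r_new)
      if (S_new < S) {
        par <- cand; r <- r_new
        improved <- TRUE
        rel_drop <- (S - S_new) / max(S, .Machine$double.xmin)
        S <- S_new
        lambda <- max(lambda / 5, 1e-12)
        if (rel_drop < rel_tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
      if (n_evals >= max_evals) break
    }
    if (!improved) {
      ## no descent even under heavy damping (or only sub-tolerance steps
      ## remain): local optimum within the box
      converged <- converged || tiny_step || lambda > 1e12
      break
    }
    if (converged) break
  }
  list(par = par, residuals = r, objective = S, converged = converged,
       n_iter = iter, n_evals = n_evals)
}
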