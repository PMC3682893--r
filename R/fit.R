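#' Configuration for kill-curve fitting
#'
#' @param n_starts Number of random starting values per curve (default 10;
#'   each start is polished by both a Nelder-Mead simplex pass and a BFGS
#'   quasi-Newton pass).
#' @param use_sann Also run a stochastic-annealing (SANN) pass from each start.
#'   Off by default: the two deterministic optimisers from multiple starts
#'   reach the same optimum on simulated data; SANN is retained as an optional
#'   cross-check.
#' @param maxit Iteration cap per optimiser call.
#' @param seed Integer seed controlling the random starts (and SANN).
#' @param detection_time_h Samples at or after this time are "late-phase" for
#'   the detection-limit rule: if every late-phase count is zero the persister
#'   fraction is only bounded above, and the fit is flagged.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 10, use_sann = FALSE, maxit = 500,
                       seed = 1, detection_time_h = 8) {
  stopifnot(n_starts >= 1, maxit >= 10)
  structure(list(n_starts = as.integer(n_starts), use_sann = isTRUE(use_sann),
                 maxit = as.integer(maxit), seed = as.integer(seed),
                 detection_time_h = detection_time_h),
            class = "fit_config")
}

# Heuristic two-phase split of a curve into starting values.
# Early slope -> l1, late slope -> l2, intercepts -> c1, c2.
.heuristic_theta <- function(t, x, delta) {
  y <- log(pmax(x, 0.5) / delta)
  n <- length(t)
  i_early <- seq_len(max(3L, min(5L, sum(t <= 4))))
  i_late <- seq.int(max(n - 2L, 1L), n)
  fe <- stats::lm.fit(cbind(1, t[i_early]), y[i_early])$coefficients
  fl <- stats::lm.fit(cbind(1, t[i_late]), y[i_late])$coefficients
  l2 <- min(fl[2L], -1e-4)
  l1 <- fe[2L]
  if (!is.finite(l1) || l1 >= l2) l1 <- l2 * 50 - 0.5
  c2 <- exp(min(fl[1L], 700))
  c1 <- max(exp(min(fe[1L], 700)) - c2, c2 * 1e-3, 1e-6)
  unname(c(log(c1), log(max(c2, 1e-6)), log(-l2), log(l2 - l1)))
}

#' Fit the two-state kill-curve model to one replicate
#'
#' Maximises the Poisson log-likelihood of [poisson_loglik()] over the
#' constrained biexponential space via the unconstrained transform
#' `c1 = e^t1`, `c2 = e^t2`, `l2 = -e^t3`, `l1 = l2 - e^t4` (positivity and
#' eigenvalue ordering hold by construction).  Starting values are drawn
#' (seeded) by log-scale perturbation around a heuristic two-phase split of
#' the data; each start is optimised by Nelder-Mead and refined by BFGS, and
#' the best converged optimum is kept.  The fit is deterministic given
#' `(curve, config)`.
#'
#' The returned fit carries the identifiability interval of the persister
#' fraction ([feasible_fp_interval()]); its midpoint `fp_mid` is the point
#' estimate, the mechanistic rates are evaluated there, and the model-free
#' slow-amplitude fraction `c2/(c1 + c2)` is reported alongside.  When all
#' late-phase counts are zero the fraction is below the assay's detection
#' limit; the fit is flagged and `fp_bound = 3 / (N0_hat * max(delta_late))`
#' (the ~95% Poisson upper bound implied by observing zero colonies) is
#' reported as the usable upper bound.
#'
#' @param curve A [kill_curve()] with at least 5 distinct timepoints.
#' @param config A [fit_config()].
#' @return An object of class `persister_fit`; see Details.  Fields include
#'   `obs_hat`, `loglik`, `fraction` (a `fraction_interval`), `fp_mid`,
#'   `mech_hat`, `slow_fraction`, `detection_limited`, `fp_bound`, `starts`
#'   (per-start convergence records), `converged`, and `ci` (filled by
#'   [confidence_intervals()]).
#' @export
fit_replicate <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "kill_curve"), inherits(config, "fit_config"))
  d <- curve$data
  if (length(unique(d$time_h)) < 5L)
    stop("under-determined: at least 5 distinct timepoints are needed to fit 4 parameters",
         call. = FALSE)
  if (all(d$cfu == 0))
    stop("no signal: every colony count in the curve is zero", call. = FALSE)
  t <- d$time_h; x <- d$cfu; delta <- d$volume_ml

  theta0 <- .heuristic_theta(t, x, delta)
  starts <- .with_seed(derive_seed(config$seed, curve$strain, curve$treatment,
                                   curve$replicate, "starts"), {
    lapply(seq_len(config$n_starts), function(k) {
      if (k == 1L) theta0
      else theta0 + c(stats::runif(2, -1, 1) * log(10),
                      stats::runif(2, -0.5, 0.5) * log(10))
    })
  })

  run_start <- function(theta_s) {
    best <- list(par = theta_s, value = .nll_biexp(theta_s, t, x, delta),
                 convergence = 1L)
    o1 <- tryCatch(
      stats::optim(theta_s, .nll_biexp, t = t, x = x, delta = delta,
                   method = "Nelder-Mead", control = list(maxit = config$maxit)),
      error = function(e) NULL)
    if (!is.null(o1) && is.finite(o1$value) && o1$value < best$value) best <- o1
    if (config$use_sann) {
      o3 <- tryCatch(
        stats::optim(best$par, .nll_biexp, t = t, x = x, delta = delta,
                     method = "SANN", control = list(maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(o3) && is.finite(o3$value) && o3$value < best$value)
        best <- c(o3, list(convergence = best$convergence))
    }
    o2 <- tryCatch(
      stats::optim(best$par, .nll_biexp, t = t, x = x, delta = delta,
                   method = "BFGS", control = list(maxit = config$maxit)),
      error = function(e) NULL)
    if (!is.null(o2) && is.finite(o2$value) && o2$value <= best$value) best <- o2
    best
  }

  fits <- lapply(starts, run_start)
  values <- vapply(fits, function(f) f$value, numeric(1))
  conv <- vapply(fits, function(f) identical(f$convergence, 0L) ||
                   identical(f$convergence, 0), logical(1))
  i_best <- which.min(values)
  best <- fits[[i_best]]
  # final polish so that refitting from the optimum cannot improve it
  polish <- tryCatch(
    stats::optim(best$par, .nll_biexp, t = t, x = x, delta = delta,
                 method = "Nelder-Mead",
                 control = list(maxit = config$maxit, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$value) && polish$value < best$value)
    best <- polish

  obs_hat <- .theta_to_obs(best$par)
  fraction <- feasible_fp_interval(obs_hat)
  mech_hat <- obs_to_mech(obs_hat, fraction$fp_mid)
  N0_hat <- obs_hat$c1 + obs_hat$c2

  late <- t >= config$detection_time_h
  detection_limited <- any(late) && all(x[late] == 0)
  fp_bound <- if (detection_limited) {
    3 / (N0_hat * max(delta[late]))
  } else NA_real_

  structure(list(
    strain = curve$strain, treatment = curve$treatment,
    replicate = curve$replicate,
    obs_hat = obs_hat, theta_hat = best$par, loglik = -best$value,
    fraction = fraction, fp_mid = fraction$fp_mid,
    mech_hat = mech_hat, slow_fraction = obs_hat$c2 / N0_hat,
    N0_hat = N0_hat,
    detection_limited = detection_limited, fp_bound = fp_bound,
    starts = data.frame(start = seq_along(values), nll = values,
                        converged = conv),
    converged = any(conv) && is.finite(best$value),
    n_obs = length(t), ci = NULL,
    config = config), class = "persister_fit")
}

#' @export
print.persister_fit <- function(x, ...) {
  cat(sprintf("Two-state kill-curve fit: %s / %s / rep %s\n",
              x$strain, x$treatment, x$replicate))
  print(x$obs_hat)
  cat(sprintf("  log-likelihood %.3f over %d samples (%s)\n", x$loglik, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(x$fraction)
  if (x$detection_limited)
    cat(sprintf("  all late-phase counts zero: persister fraction < %.3g (detection limit)\n",
                x$fp_bound))
  print(x$mech_hat)
  cat(sprintf("  slow-amplitude fraction c2/(c1+c2) = %.4g\n", x$slow_fraction))
  invisible(x)
}

#' Normal-approximation confidence intervals for a fitted curve
#'
#' 95% intervals from the observed information (numerically differentiated
#' Hessian of the negative log-likelihood) at the MLE in the unconstrained
#' transformed coordinates, where the normal approximation is symmetric, then
#' mapped back to the natural scales.  `c1`, `c2` and `l2` map through their
#' own log coordinates; `l1 = l2 - e^t4` involves two coordinates and gets a
#' delta-method interval.  Endpoints always bracket the MLE.
#'
#' These are per-replicate (within-curve) intervals; the spread across
#' biological replicates is summarised separately by [summarize_strain()].
#'
#' @param fit A converged [fit_replicate()] result.
#' @param curve The [kill_curve()] the fit came from.
#' @return The fit with `ci` set to a data.frame (parameter, lower, estimate,
#'   upper), or flagged unavailable if the information matrix is singular.
#' @export
confidence_intervals <- function(fit, curve) {
  stopifnot(inherits(fit, "persister_fit"), inherits(curve, "kill_curve"))
  if (!fit$converged)
    stop("confidence intervals require a converged fit", call. = FALSE)
  d <- curve$data
  H <- tryCatch(
    stats::optimHess(fit$theta_hat, .nll_biexp,
                     t = d$time_h, x = d$cfu, delta = d$volume_ml),
    error = function(e) NULL)
  V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)) {
    fit$ci <- NULL
    fit$ci_unavailable <- TRUE
    return(fit)
  }
  th <- fit$theta_hat
  se <- sqrt(diag(V))
  z <- stats::qnorm(0.975)
  # log-scale parameters: exponentiate symmetric theta intervals
  lo <- th - z * se; hi <- th + z * se
  ob <- fit$obs_hat
  # l1 = -exp(t3) - exp(t4): delta method with the 2x2 block
  g <- c(0, 0, -exp(th[3L]), -exp(th[4L]))
  sd_l1 <- sqrt(max(drop(t(g) %*% V %*% g), 0))
  fit$ci <- data.frame(
    parameter = c("c1", "c2", "l1", "l2"),
    lower = c(exp(lo[1L]), exp(lo[2L]), ob$l1 - z * sd_l1, -exp(hi[3L])),
    estimate = c(ob$c1, ob$c2, ob$l1, ob$l2),
    upper = c(exp(hi[1L]), exp(hi[2L]), ob$l1 + z * sd_l1, -exp(lo[3L])))
  fit$ci_unavailable <- FALSE
  fit
}

# Multi-start fit of the reduced single-exponential model N(t) = c e^(l t).
.fit_single <- function(curve, config = fit_config()) {
  d <- curve$data
  t <- d$time_h; x <- d$cfu; delta <- d$volume_ml
  if (all(x == 0))
    stop("no signal: every colony count in the curve is zero", call. = FALSE)
  y <- log(pmax(x, 0.5) / delta)
  f <- stats::lm.fit(cbind(1, t), y)$coefficients
  theta0 <- c(min(f[1L], 700), log(-min(f[2L], -1e-4)))
  starts <- .with_seed(derive_seed(config$seed, curve$strain, curve$treatment,
                                   curve$replicate, "single"), {
    lapply(seq_len(max(3L, config$n_starts %/% 2L)), function(k) {
      if (k == 1L) theta0
      else theta0 + stats::runif(2, -1, 1) * log(10)
    })
  })
  fits <- lapply(starts, function(th) {
    o <- tryCatch(
      stats::optim(th, .nll_single, t = t, x = x, delta = delta,
                   method = "Nelder-Mead", control = list(maxit = config$maxit)),
      error = function(e) NULL)
    if (is.null(o)) return(list(par = th, value = Inf, convergence = 1L))
    o2 <- tryCatch(
      stats::optim(o$par, .nll_single, t = t, x = x, delta = delta,
                   method = "BFGS", control = list(maxit = config$maxit)),
      error = function(e) NULL)
    if (!is.null(o2) && o2$value <= o$value) o2 else o
  })
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  list(c_hat = exp(best$par[1L]), l_hat = -exp(best$par[2L]),
       loglik = -best$value)
}

#' Compare the biexponential to a single-exponential kill model
#'
#' Fits the reduced 2-parameter model `N(t) = c e^(lambda t)` by the same
#' Poisson likelihood and compares it to the full 4-parameter biexponential.
#' The reduced model is nested (a boundary case) in the full one, so the full
#' log-likelihood can never be lower.  A curve is called *biphasic* — evidence
#' of a persister subpopulation with a distinct death rate — when the
#' biexponential is favoured by more than 4 AIC units, the conventional cutoff
#' for "considerably less support" for the weaker model.
#'
#' @param curve A [kill_curve()].
#' @param config A [fit_config()].
#' @return A list with `loglik_biexp`, `loglik_single`, `lr_stat` (the
#'   likelihood-ratio statistic), `delta_aic` (`AIC_single - AIC_biexp`;
#'   positive favours the biexponential), `preferred`
#'   (`"biexponential"`/`"single"`), `biphasic` (logical), and both fits.
#' @export
compare_single_exponential <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "kill_curve"))
  full <- fit_replicate(curve, config)
  red <- .fit_single(curve, config)
  lr <- 2 * (full$loglik - red$loglik)
  delta_aic <- (2 * 2 - 2 * red$loglik) - (2 * 4 - 2 * full$loglik)
  list(loglik_biexp = full$loglik, loglik_single = red$loglik,
       lr_stat = lr, delta_aic = delta_aic,
       preferred = if (delta_aic > 4) "biexponential" else "single",
       biphasic = delta_aic > 4,
       fit_biexp = full, fit_single = red)
}
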