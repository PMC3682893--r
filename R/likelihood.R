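#' Poisson log-likelihood of a kill curve under a biexponential
#'
#' The error in colony counts is assumed to come from Poisson sampling of the
#' plated volume: `x_t ~ Poisson(N(t) * delta_t)`.  The log-likelihood is
#' `sum_t [ x_t log(N(t) delta_t) - N(t) delta_t - log(x_t!) ]`; a zero count
#' contributes `-N(t) delta_t`.
#'
#' If some predicted mean is exactly zero while the observed count is positive
#' the likelihood is `-Inf`; this is returned (with a warning), not raised as
#' an error, so optimisers can move away from such parameter values.
#'
#' @param obs An [obs_params()] object.
#' @param curve A [kill_curve()] object.
#' @return The log-likelihood (scalar).
#' @export
poisson_loglik <- function(obs, curve) {
  stopifnot(inherits(obs, "obs_params"), inherits(curve, "kill_curve"))
  mu <- total_cfu(obs, curve$data$time_h) * curve$data$volume_ml
  ll <- sum(stats::dpois(curve$data$cfu, mu, log = TRUE))
  if (!is.finite(ll) && any(mu == 0 & curve$data$cfu > 0))
    warning("zero predicted mean with positive count: log-likelihood is -Inf",
            call. = FALSE)
  ll
}

# Fast internal negative log-likelihood in unconstrained coordinates.
# theta = (log c1, log c2, log(-l2), log(l2 - l1)); enforces c1, c2 > 0 and
# l1 < l2 < 0 by construction.  Means are floored at a tiny positive value so
# the objective stays finite (equivalent to -Inf for any optimiser's purpose).
.nll_biexp <- function(theta, t, x, delta) {
  c1 <- exp(theta[1L]); c2 <- exp(theta[2L])
  l2 <- -exp(theta[3L]); l1 <- l2 - exp(theta[4L])
  if (!all(is.finite(c(c1, c2, l1, l2)))) return(1e300)
  mu <- (c1 * exp(l1 * t) + c2 * exp(l2 * t)) * delta
  mu <- pmax(mu, 1e-300)
  -sum(x * log(mu) - mu - lgamma(x + 1))
}

.theta_to_obs <- function(theta) {
  l2 <- -exp(theta[3L])
  obs_params(exp(theta[1L]), exp(theta[2L]), l2 - exp(theta[4L]), l2)
}

.obs_to_theta <- function(obs) {
  c(log(max(obs$c1, 1e-12)), log(max(obs$c2, 1e-12)),
    log(max(-obs$l2, 1e-12)), log(max(obs$l2 - obs$l1, 1e-12)))
}

# Single-exponential reduced model, theta = (log c, log(-lambda)).
.nll_single <- function(theta, t, x, delta) {
  cc <- exp(theta[1L]); l <- -exp(theta[2L])
  if (!all(is.finite(c(cc, l)))) return(1e300)
  mu <- cc * exp(l * t) * delta
  mu <- pmax(mu, 1e-300)
  -sum(x * log(mu) - mu - lgamma(x + 1))
}
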