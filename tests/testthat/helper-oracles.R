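# Independent oracles used across the suite.

# Adaptive numerical integration of the two-state ODE system (deSolve),
# independent of the package's closed-form solution.
ode_trajectory <- function(mech, init, times) {
  rhs <- function(t, y, parms) {
    list(c(-(parms$m + parms$a) * y[1] + parms$b * y[2],
           parms$a * y[1] - parms$b * y[2]))
  }
  # atol must sit far below the persister tail (can be ~10 CFU/ml) for the
  # comparison to be meaningful at 1e-8 relative error
  sol <- deSolve::ode(c(n = init$n0, p = init$p0), times, rhs,
                      list(m = mech$m, a = mech$a, b = mech$b),
                      rtol = 1e-11, atol = 1e-16)
  data.frame(time_h = sol[, "time"], n = sol[, "n"], p = sol[, "p"],
             total = sol[, "n"] + sol[, "p"])
}

# Brute-force Spearman rho: midranks by counting, Pearson by explicit sums.
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i) {
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    }, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sx <- rx - mean(rx); sy <- ry - mean(ry)
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den == 0) return(NA_real_)
  sum(sx * sy) / den
}

# Random mechanistic parameter draw (log-uniform over the documented ranges).
rand_mech_draw <- function() {
  m <- 10^runif(1, log10(0.1), log10(5))
  a <- 10^runif(1, -6, -1)
  b <- 10^runif(1, -6, log10(0.5))
  fp <- 10^runif(1, -6, log10(0.2))
  list(mech = mech_params(m, a, b),
       init = initial_state(10^runif(1, 7, 8), fp))
}

# Generating truth for recovery simulations: fp chosen, switching at its
# balanced-growth equilibrium (g = 1/h), typical kill and return rates.
recovery_truth <- function(fp, m = 2, b = 1e-3, g = 1, N0 = 5e7) {
  a <- fp / (1 - fp) * (g + b)
  list(mech = mech_params(m, a, b), init = initial_state(N0, fp))
}
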