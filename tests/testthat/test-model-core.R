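test_that("eigenvalues match the characteristic polynomial and its limits", {
  # decoupled limit: persisters inert, normals die at m
  expect_equal(unname(eigenvalues(mech_params(2, 0, 0))), c(-2, 0))
  # pure switching: total conserved, relaxation at a + b
  expect_equal(unname(eigenvalues(mech_params(0, 0.3, 0.7))), c(-1, 0))
  # generic case against a numerical root-finder
  m <- 2; a <- 0.01; b <- 0.05
  roots <- sort(Re(polyroot(c(m * b, m + a + b, 1))))
  ev <- eigenvalues(mech_params(m, a, b))
  expect_equal(unname(ev), roots, tolerance = 1e-12)
  expect_equal(unname(ev), c(-2.0103, -0.0497), tolerance = 1e-4)
  # ordering l1 <= l2 <= 0 over random draws
  set.seed(11)
  for (i in 1:50) {
    d <- rand_mech_draw()
    ev <- eigenvalues(d$mech)
    expect_true(ev[["l1"]] <= ev[["l2"]])
    expect_lte(ev[["l2"]], 0)
  }
  expect_error(mech_params(-1, 0, 0), "must be finite and >= 0")
})

test_that("mech_to_obs reproduces the numerically integrated ODE", {
  # decoupled limit: slow amplitude equals the persister count
  obs <- mech_to_obs(mech_params(2, 0, 0), initial_state(1e7, 0.01))
  expect_equal(obs$c1, 9.9e6)
  expect_equal(obs$c2, 1e5)
  expect_equal(obs$l1, -2)
  expect_equal(obs$l2, 0)
  # conservation without death
  obs0 <- mech_to_obs(mech_params(0, 0.2, 0.3), initial_state(1e7, 0.05))
  expect_equal(total_cfu(obs0, c(0, 1, 10, 48)), rep(1e7, 4), tolerance = 1e-12)
  # generic parameters against the Runge-Kutta oracle
  mech <- mech_params(2, 0.01, 0.05)
  init <- initial_state(1e7, 0.01)
  obs <- mech_to_obs(mech, init)
  times <- seq(0, 48, by = 0.5)
  ode <- ode_trajectory(mech, init, times)
  expect_lt(max(abs(total_cfu(obs, times) - ode$total) / ode$total), 1e-8)
  expect_equal(obs$c1 + obs$c2, init$N0)
})

test_that("total_cfu evaluates the biexponential and rejects negative times", {
  obs <- obs_params(1e7, 0, -1, -1e-9)
  expect_equal(total_cfu(obs, 2), 1e7 * exp(-2), tolerance = 1e-12)
  expect_equal(total_cfu(obs, 2), 1.3534e6, tolerance = 1e-4)
  obs2 <- obs_params(5e6, 5e3, -2, -0.01)
  expect_equal(total_cfu(obs2, 0), obs2$c1 + obs2$c2)
  # high-precision (30-digit) oracle value for 5e6 e^(-48) + 5e3 e^(-0.24)
  expect_equal(total_cfu(obs2, 24), 3933.13930533277, tolerance = 1e-12)
  expect_equal(total_cfu(obs2, c(0, 24)),
               c(5005000, total_cfu(obs2, 24)))
  expect_error(total_cfu(obs2, -1), ">= 0")
})

test_that("state trajectories are closed-form, non-negative, and sum to the total", {
  # persisters inert: n -> 0, p stays at p0
  tr <- state_trajectory(mech_params(2, 0, 0), initial_state(1e7, 0.01), c(0, 50))
  expect_equal(tr$p, c(1e5, 1e5))
  expect_equal(tr$n[2], 1e7 * 0.99 * exp(-100))
  # no persisters ever formed
  tr0 <- state_trajectory(mech_params(3, 0, 0), initial_state(1e7, 0), 0:48)
  expect_true(all(tr0$p == 0))
  # generic agreement with the ODE oracle, both compartments
  set.seed(21)
  for (i in 1:25) {
    d <- rand_mech_draw()
    times <- seq(0, 48, length.out = 25)
    tr <- state_trajectory(d$mech, d$init, times)
    ode <- ode_trajectory(d$mech, d$init, times)
    # compare where the density is physically meaningful (>= 1e-6 CFU/ml)
    keep <- ode$total >= 1e-6
    expect_lt(max(abs(tr$total - ode$total)[keep] / ode$total[keep]), 1e-8)
    expect_lt(max(abs(tr$n - ode$n)[keep] / pmax(ode$total[keep], 1)), 1e-8)
    expect_lt(max(abs(tr$p - ode$p)[keep] / pmax(ode$total[keep], 1)), 1e-8)
    expect_true(all(tr$n >= 0 & tr$p >= 0))
    # monotone nonincreasing total on a dense grid
    dense <- total_cfu(mech_to_obs(d$mech, d$init), seq(0, 48, length.out = 200))
    expect_true(all(diff(dense) <= 1e-9 * dense[-length(dense)]))
  }
})

test_that("feasible fraction interval matches a grid-search over fp", {
  # boundary case a = 0: true fp is the interval's upper endpoint
  obs <- mech_to_obs(mech_params(2, 1e-14, 0), initial_state(1e7, 0.01))
  iv <- feasible_fp_interval(obs)
  expect_equal(iv$fp_max, 0.01, tolerance = 1e-6)
  expect_equal(iv$D, 1.98, tolerance = 1e-6)
  # generic case: frozen from the derivation, checked here against a grid scan
  obs2 <- mech_to_obs(mech_params(2, 0.01, 0.05), initial_state(1e7, 0.01))
  iv2 <- feasible_fp_interval(obs2)
  expect_equal(iv2$fp_min, 0)
  expect_equal(iv2$fp_max, 0.015050, tolerance = 1e-4)
  expect_equal(iv2$fp_mid, (iv2$fp_min + iv2$fp_max) / 2)
  # grid-search oracle: rates from the inversion formulas, scanned over fp
  fp_grid <- seq(0, 0.999, by = 1e-4)
  D <- -(obs2$c1 * obs2$l1 + obs2$c2 * obs2$l2) / (obs2$c1 + obs2$c2)
  feas <- vapply(fp_grid, function(fp) {
    u <- 1 - fp
    m <- D / u
    b <- obs2$l1 * obs2$l2 / m
    a <- -(obs2$l1 + obs2$l2) - m - b
    m >= 0 && b >= 0 && a >= -1e-12
  }, logical(1))
  expect_lt(abs(min(fp_grid[feas]) - iv2$fp_min), 1.5e-4)  # grid resolution
  expect_lt(abs(max(fp_grid[feas]) - iv2$fp_max), 1.5e-4)
})

test_that("the interval always contains the generating fraction (identifiability)", {
  set.seed(31)
  for (i in 1:100) {
    d <- rand_mech_draw()
    obs <- mech_to_obs(d$mech, d$init)
    iv <- feasible_fp_interval(obs)
    expect_gte(d$init$fp, iv$fp_min - 1e-10)
    expect_lte(d$init$fp, iv$fp_max + 1e-10)
    expect_true(iv$fp_min <= iv$fp_mid && iv$fp_mid <= iv$fp_max)
    expect_lt(iv$fp_max, 1)
  }
})

test_that("obs_to_mech inverts mech_to_obs at the true fraction", {
  obs <- mech_to_obs(mech_params(2, 0.01, 0.05), initial_state(1e7, 0.01))
  mech_back <- obs_to_mech(obs, 0.01)
  expect_equal(mech_back$m, 2, tolerance = 1e-6)
  expect_equal(mech_back$a, 0.01, tolerance = 1e-6)
  expect_equal(mech_back$b, 0.05, tolerance = 1e-6)
  # round trip back to observational parameters
  obs2 <- mech_to_obs(mech_back, initial_state(obs$c1 + obs$c2, 0.01))
  for (f in c("c1", "c2", "l1", "l2"))
    expect_equal(obs2[[f]], obs[[f]], tolerance = 1e-9)
  # zero slow eigenvalue forces b = 0 at the upper endpoint
  obs0 <- mech_to_obs(mech_params(2, 0, 0), initial_state(1e7, 0.01))
  iv0 <- feasible_fp_interval(obs0)
  expect_equal(obs_to_mech(obs0, iv0$fp_max)$b, 0)
  # infeasible fraction errors, naming the interval
  expect_error(obs_to_mech(obs, 0.9), "outside the feasible interval")
})

test_that("degenerate repeated-eigenvalue inputs are rejected explicitly", {
  # (m + a + b)^2 == 4 m b at m == b, a == 0
  expect_error(mech_to_obs(mech_params(1, 0, 1), initial_state(1e7, 0.01)),
               "repeated eigenvalue")
})
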