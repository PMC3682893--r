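#' Decay eigenvalues of the two-state model
#'
#' The coupled system `n' = -(m + a) n + b p`, `p' = a n - b p` has
#' characteristic polynomial `lambda^2 + (m + a + b) lambda + m b = 0`.  Its
#' discriminant `(m + a + b)^2 - 4 m b` equals `(l1 - l2)^2` and is never
#' negative, so both eigenvalues are real and non-positive.
#'
#' @param mech A [mech_params()] object.
#' @return Named numeric vector `c(l1, l2)` with `l1 <= l2 <= 0` (1/h).
#' @export
#' @examples
#' eigenvalues(mech_params(2, 0.01, 0.05))
eigenvalues <- function(mech) {
  stopifnot(inherits(mech, "mech_params"))
  s <- mech$m + mech$a + mech$b
  # cancellation-free discriminant: (m+a+b)^2 - 4mb == (m-b)^2 + a(a+2m+2b)
  gap <- sqrt((mech$m - mech$b)^2 + mech$a * (mech$a + 2 * mech$m + 2 * mech$b))
  l1 <- -(s + gap) / 2
  # stable small root via the product l1*l2 = m*b (avoids s - gap cancellation)
  l2 <- if (mech$m * mech$b == 0) 0 else -2 * mech$m * mech$b / (s + gap)
  c(l1 = l1, l2 = l2)
}

# (x + gap)/2 evaluated without cancellation: when x < 0, uses the identity
# gap^2 - x^2 = prod4, so x + gap = prod4 / (gap - x).
.half_sum_gap <- function(x, gap, prod4) {
  if (x >= 0) (x + gap) / 2 else prod4 / (2 * (gap - x))
}

# Relative closeness of the two eigenvalues; repeated-eigenvalue boundary.
.is_degenerate <- function(l1, l2, tol = 1e-12) {
  abs(l1 - l2) < tol * max(abs(l1), abs(l2), .Machine$double.eps)
}

#' Map mechanistic parameters to the observable biexponential
#'
#' Solves the linear two-state system in closed form for the total count
#' `N(t) = n(t) + p(t)`.  With `N(0) = N0` and `N'(0) = -m (1 - fp) N0` (only
#' normal cells die), the amplitudes are
#' `c2 = (N'(0) - l1 N0) / (l2 - l1)` and `c1 = N0 - c2`.
#'
#' @param mech A [mech_params()] object.
#' @param init An [initial_state()] object.
#' @return An [obs_params()] object with `c1 + c2 == N0`.
#' @export
#' @examples
#' mech_to_obs(mech_params(2, 0.01, 0.05), initial_state(1e7, 0.01))
mech_to_obs <- function(mech, init) {
  stopifnot(inherits(mech, "mech_params"), inherits(init, "initial_state"))
  ev <- eigenvalues(mech)
  l1 <- ev[["l1"]]; l2 <- ev[["l2"]]
  if (.is_degenerate(l1, l2))
    stop("repeated eigenvalue (m + a + b)^2 == 4 m b: biexponential form degenerate",
         call. = FALSE)
  if (l1 >= 0)
    stop("fast eigenvalue is not negative; need m > 0 for a kill curve", call. = FALSE)
  N0 <- init$N0
  gap <- l2 - l1
  # c2 = N0 (|l1| - D)/gap with D = m(1-fp); the difference |l1| - D equals
  # ((a + b - m) + gap)/2 + m*fp, each piece evaluated cancellation-free
  # (gap^2 - (m-a-b)^2 = 4ma)
  m <- mech$m; a <- mech$a; b <- mech$b
  c2 <- N0 * (.half_sum_gap(a + b - m, gap, 4 * m * a) + m * init$fp) / gap
  c1 <- N0 - c2
  # c2 is provably >= 0 (clamp roundoff only); c1 may legitimately be
  # negative when b > m (see obs_params)
  obs_params(c1, max(c2, 0), l1, l2)
}

#' Total viable cell density predicted by the model
#'
#' @param obs An [obs_params()] object.
#' @param t Time(s) since drug addition (hours, `>= 0`); vectorised.
#' @return Numeric vector of `N(t)` (CFU/ml).
#' @export
#' @examples
#' total_cfu(obs_params(1e7, 0, -1, -1e-6), 2)
total_cfu <- function(obs, t) {
  stopifnot(inherits(obs, "obs_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  obs$c1 * exp(obs$l1 * t) + obs$c2 * exp(obs$l2 * t)
}

#' Closed-form normal and persister trajectories
#'
#' Returns the two compartments separately.  Each component is a combination
#' `A1 e^(l1 t) + A2 e^(l2 t)` of the two eigenmodes; the amplitudes follow
#' from the component's own initial value and derivative, e.g. for normals
#' `n(0) = n0 = (1 - fp) N0` and `n'(0) = -(m + a) n0 + b p0`, so both
#' compartments are exact closed forms (no subtraction of near-equal totals).
#'
#' @param mech A [mech_params()] object.
#' @param init An [initial_state()] object.
#' @param t Time(s) in hours, `>= 0`; vectorised.
#' @return A data.frame with columns `time_h`, `n`, `p`, `total`.
#' @export
state_trajectory <- function(mech, init, t) {
  stopifnot(inherits(mech, "mech_params"), inherits(init, "initial_state"),
            is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  ev <- eigenvalues(mech)
  l1 <- ev[["l1"]]; l2 <- ev[["l2"]]
  gap <- l2 - l1
  m <- mech$m; a <- mech$a; b <- mech$b
  n0 <- init$n0; p0 <- init$p0
  # each component as y(t) = e^(l1 t) (y0 + Q t phi(gap t)), phi(x)=expm1(x)/x:
  # uniformly stable, and exact in the repeated-eigenvalue limit gap -> 0,
  # where it reduces to the (y0 + Q t) e^(l1 t) form.
  # Q = dy(0) - l1 y0; the pieces |l1|-(m+a) = ((b-m-a)+gap)/2 and
  # |l1|-b = ((m+a-b)+gap)/2 are evaluated cancellation-free
  # (gap^2 - (m+a-b)^2 = 4ab).
  Qn <- n0 * .half_sum_gap(b - m - a, gap, 4 * a * b) + b * p0
  Qp <- a * n0 + p0 * .half_sum_gap(m + a - b, gap, 4 * a * b)
  phi <- function(x) ifelse(abs(x) < 1e-280, 1, expm1(x) / x)
  e1 <- exp(l1 * t)
  x <- gap * t
  comp <- function(y0, Q) {
    # amplitude form once the slow mode dominates (also avoids expm1 overflow)
    ifelse(x > 50,
           (y0 - Q / gap) * e1 + (Q / gap) * exp(l2 * t),
           e1 * (y0 + Q * t * phi(x)))
  }
  n <- pmax(comp(n0, Qn), 0)
  p <- pmax(comp(p0, Qp), 0)
  data.frame(time_h = t, n = n, p = p, total = n + p)
}

#' Feasible persister-fraction interval of a fitted biexponential
#'
#' A biexponential `(c1, c2, l1, l2)` determines only four observables while
#' the mechanistic model has five unknowns `(m, a, b, N0, fp)`; the persister
#' fraction is therefore identified only up to an interval.  Writing
#' `D = -(c1 l1 + c2 l2) / (c1 + c2)` (the initial per-capita death rate, so
#' `D = m (1 - fp)`) and `u = 1 - fp`, non-negativity of all three rates
#' reduces to `u` between `D / |l1|` and `D / |l2|`, intersected with
#' `u <= 1`: the interval is `[max(0, 1 - D/|l2|), 1 - D/|l1|]`.  For fitted
#' biphasic curves (`c1 > 0`), `D` is a `c`-weighted mean of `|l1|` and
#' `|l2|`, so `fp_min = 0`: the data never exclude `fp = 0` (a slow tail can
#' always be produced by switching into persistence during treatment), while
#' the largest admissible initial persister fraction corresponds to the
#' `a = 0` boundary (all slow-phase cells present from the start).
#'
#' The midpoint `fp_mid` is the package's point estimate of the persister
#' fraction; the model-free slow-amplitude fraction `c2 / (c1 + c2)` is
#' reported alongside by the fitting routines.
#'
#' @param obs An [obs_params()] object.
#' @return An object of class `fraction_interval`: list with `fp_min`,
#'   `fp_mid`, `fp_max`, plus the normal-fraction bounds `u_min`, `u_max`
#'   (the complementary convention, `u = 1 - fp`) and `D`.
#' @export
#' @examples
#' obs <- mech_to_obs(mech_params(2, 0.01, 0.05), initial_state(1e7, 0.01))
#' feasible_fp_interval(obs)
feasible_fp_interval <- function(obs) {
  stopifnot(inherits(obs, "obs_params"))
  N0 <- obs$c1 + obs$c2
  D <- -(obs$c1 * obs$l1 + obs$c2 * obs$l2) / N0
  if (D <= 0)
    stop("non-positive initial death rate D: observational parameters infeasible",
         call. = FALSE)
  u_lo <- D / abs(obs$l1)
  u_hi <- if (obs$l2 == 0) 1 else min(1, D / abs(obs$l2))
  if (u_lo > u_hi + 1e-12)
    stop("empty feasible set for the persister fraction", call. = FALSE)
  u_lo <- min(u_lo, u_hi)
  fp_min <- 1 - u_hi
  fp_max <- 1 - u_lo
  structure(list(fp_min = fp_min, fp_mid = (fp_min + fp_max) / 2,
                 fp_max = fp_max, u_min = u_lo, u_max = u_hi, D = D),
            class = "fraction_interval")
}

#' @export
print.fraction_interval <- function(x, ...) {
  cat(sprintf("Persister fraction feasible in [%.4g, %.4g], midpoint %.4g\n",
              x$fp_min, x$fp_max, x$fp_mid))
  cat(sprintf("  (normal-cell fraction u = 1 - fp in [%.4g, %.4g])\n",
              x$u_min, x$u_max))
  invisible(x)
}

#' Mechanistic rates implied by a biexponential at a given persister fraction
#'
#' Inverts [mech_to_obs()] at a chosen `fp` inside the feasible interval:
#' with `D = -(c1 l1 + c2 l2)/(c1 + c2)` and `u = 1 - fp`,
#' `m = D / u`, `b = l1 l2 / m`, `a = -(l1 + l2) - m - b`.
#'
#' @param obs An [obs_params()] object.
#' @param fp Persister fraction in the feasible interval of
#'   [feasible_fp_interval()].
#' @return A [mech_params()] object.
#' @export
#' @examples
#' obs <- mech_to_obs(mech_params(2, 0.01, 0.05), initial_state(1e7, 0.01))
#' obs_to_mech(obs, 0.01)
obs_to_mech <- function(obs, fp) {
  stopifnot(inherits(obs, "obs_params"), is.numeric(fp), length(fp) == 1L)
  iv <- feasible_fp_interval(obs)
  # small numerical slack: interval endpoints themselves must be admissible
  eps <- 1e-10
  if (!is.finite(fp) || fp < iv$fp_min - eps || fp > iv$fp_max + eps)
    stop(sprintf("fp = %.6g outside the feasible interval [%.6g, %.6g]",
                 fp, iv$fp_min, iv$fp_max), call. = FALSE)
  fp <- min(max(fp, iv$fp_min), iv$fp_max)
  u <- 1 - fp
  m <- iv$D / u
  b <- obs$l1 * obs$l2 / m
  a <- -(obs$l1 + obs$l2) - m - b
  mech_params(m, max(a, 0), max(b, 0))
}
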