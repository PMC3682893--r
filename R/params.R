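#' Mechanistic parameters of the two-state kill-curve model
#'
#' During antibiotic treatment cells are assumed to occupy one of two states:
#' *normal* cells, which die at rate `m` and switch into a *persister* state at
#' rate `a`; and persister cells, which neither die nor grow but switch back to
#' the normal state at rate `b`.  All rates are per hour.
#'
#' @param m Death rate of normal cells (1/h), `>= 0` (positive for any real
#'   antibiotic treatment).
#' @param a Switching rate normal -> persister (1/h), `>= 0`.
#' @param b Switching rate persister -> normal (1/h), `>= 0`.
#'
#' @return An object of class `mech_params`.
#' @seealso [eigenvalues()], [mech_to_obs()], [state_trajectory()]
#' @export
#' @examples
#' mech_params(m = 2, a = 0.01, b = 0.05)
mech_params <- function(m, a, b) {
  stopifnot(is.numeric(m), is.numeric(a), is.numeric(b),
            length(m) == 1L, length(a) == 1L, length(b) == 1L)
  if (!is.finite(m) || !is.finite(a) || !is.finite(b) || m < 0 || a < 0 || b < 0)
    stop("mechanistic rates m, a, b must be finite and >= 0", call. = FALSE)
  structure(list(m = m, a = a, b = b), class = "mech_params")
}

#' Initial state of a culture at drug addition
#'
#' @param N0 Total viable cell density at the moment of drug addition
#'   (CFU/ml, `> 0`).
#' @param fp Persister fraction at drug addition, i.e. `p0 / (n0 + p0)`,
#'   in `[0, 1]`.  Note this is the *persister* fraction; the complementary
#'   normal-cell fraction is `1 - fp`.
#'
#' @return An object of class `initial_state` with fields `N0`, `fp` and the
#'   reconstructed compartment counts `n0 = (1 - fp) * N0`, `p0 = fp * N0`.
#' @export
initial_state <- function(N0, fp) {
  stopifnot(is.numeric(N0), is.numeric(fp), length(N0) == 1L, length(fp) == 1L)
  if (!is.finite(N0) || N0 <= 0)
    stop("N0 must be finite and > 0", call. = FALSE)
  if (!is.finite(fp) || fp < 0 || fp > 1)
    stop("fp must lie in [0, 1]", call. = FALSE)
  structure(list(N0 = N0, fp = fp, n0 = (1 - fp) * N0, p0 = fp * N0),
            class = "initial_state")
}

#' Observational (biexponential) parameters
#'
#' The identifiable parameterisation of the total viable count,
#' `N(t) = c1 * exp(l1 * t) + c2 * exp(l2 * t)`, with a fast eigenvalue `l1`
#' and a slow eigenvalue `l2` (`l1 < l2 <= 0`).  This is the parameterisation
#' the Poisson likelihood is written in; four observables constrain five
#' mechanistic quantities, hence the identifiability interval of
#' [feasible_fp_interval()].
#'
#' @param c1 Fast-phase amplitude (CFU/ml).  Usually positive; it is negative
#'   for mechanistic regimes where persisters return to the normal state
#'   faster than normal cells die (`b > m`), in which case the total still
#'   decays monotonically.  Kill-curve *fitting* restricts itself to the
#'   biphasic `c1 > 0` region.
#' @param c2 Slow-phase amplitude (CFU/ml, `>= 0`).
#' @param l1 Fast decay eigenvalue (1/h, `< 0`).
#' @param l2 Slow decay eigenvalue (1/h, `<= 0`, with `l1 < l2`).
#'
#' @return An object of class `obs_params`.
#' @export
obs_params <- function(c1, c2, l1, l2) {
  stopifnot(is.numeric(c1), is.numeric(c2), is.numeric(l1), is.numeric(l2))
  if (!all(is.finite(c(c1, c2, l1, l2))))
    stop("observational parameters must be finite", call. = FALSE)
  if (c2 < 0)
    stop("slow amplitude c2 must be >= 0 (total would go negative)", call. = FALSE)
  if (c1 + c2 <= 0)
    stop("c1 + c2 must be > 0 (some cells at t = 0)", call. = FALSE)
  if (l1 >= 0)
    stop("fast eigenvalue l1 must be < 0", call. = FALSE)
  if (l2 > 0)
    stop("slow eigenvalue l2 must be <= 0", call. = FALSE)
  if (l1 >= l2)
    stop("eigenvalue ordering l1 < l2 violated", call. = FALSE)
  if (c1 * l1 + c2 * l2 > 0)
    stop("N'(0) > 0: total must be nonincreasing", call. = FALSE)
  structure(list(c1 = unname(c1), c2 = unname(c2),
                 l1 = unname(l1), l2 = unname(l2)), class = "obs_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat(sprintf("Two-state model rates (1/h): death m = %.4g, n->p a = %.4g, p->n b = %.4g\n",
              x$m, x$a, x$b))
  invisible(x)
}

#' @export
print.obs_params <- function(x, ...) {
  cat(sprintf("Biexponential: N(t) = %.4g e^(%.4g t) + %.4g e^(%.4g t)  [CFU/ml, t in h]\n",
              x$c1, x$l1, x$c2, x$l2))
  invisible(x)
}

#' @export
print.initial_state <- function(x, ...) {
  cat(sprintf("Initial state: N0 = %.4g CFU/ml, persister fraction fp = %.4g (normal fraction %.4g)\n",
              x$N0, x$fp, 1 - x$fp))
  invisible(x)
}
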