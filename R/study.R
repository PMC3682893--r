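#' Summarise replicate fits for one strain x treatment
#'
#' Aggregates per-replicate persister-fraction estimates on the log10 scale
#' (fractions span four orders of magnitude, so natural-scale means would be
#' dominated by single replicates): mean and standard error of
#' `log10(fp_mid)` across converged replicates.  Detection-limited replicates
#' contribute their upper bound `fp_bound` and raise a flag.
#'
#' @param fits List of [fit_replicate()] results for one strain x treatment.
#' @return A one-row data.frame (class includes `strain_summary`): `strain`,
#'   `treatment`, `n_replicates` (converged fits used), `mean_log10_fp`,
#'   `se_log10_fp` (`NA` when fewer than 2 replicates), `mean_slow_fraction`,
#'   `n_detection_limited`, `n_not_converged`.  If no fit converged, the
#'   summary fields are `NA` and `available` is `FALSE`.
#' @export
summarize_strain <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "persister_fit")))
  strain <- fits[[1]]$strain
  treatment <- fits[[1]]$treatment
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  det <- vapply(fits, function(f) isTRUE(f$detection_limited), logical(1))
  used <- conv
  out <- data.frame(strain = strain, treatment = treatment,
                    n_replicates = sum(used),
                    mean_log10_fp = NA_real_, se_log10_fp = NA_real_,
                    mean_slow_fraction = NA_real_,
                    n_detection_limited = sum(det & conv),
                    n_not_converged = sum(!conv),
                    available = any(used))
  if (!any(used)) return(out)
  lfp <- vapply(fits[used], function(f) {
    log10(if (isTRUE(f$detection_limited)) f$fp_bound else f$fp_mid)
  }, numeric(1))
  out$mean_log10_fp <- mean(lfp)
  out$se_log10_fp <- if (sum(used) >= 2) stats::sd(lfp) / sqrt(sum(used)) else NA_real_
  out$mean_slow_fraction <- mean(vapply(fits[used], `[[`, numeric(1),
                                        "slow_fraction"))
  out
}

# All permutations of 1..n (n! rows); used for exact permutation p-values.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

.spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Spearman rank correlation with a permutation p-value
#'
#' Spearman's rho (average ranks on ties) with a two-sided permutation test:
#' exact enumeration of all `n!` orderings when `n <= exact_max`, otherwise a
#' seeded Monte-Carlo permutation test (p computed with the add-one rule, so
#' `p` is always in (0, 1]).
#'
#' @param x,y Paired numeric vectors, `n >= 3`; incomplete pairs (any `NA`)
#'   are dropped.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param exact_max Enumerate exactly for `n` up to this (default 7).
#' @param seed Seed for the Monte-Carlo arm.
#' @return A one-row data.frame: `rho`, `p_value`, `n`, `method`
#'   (`"exact-permutation"` or `"monte-carlo"`), `seed`, `defined` (`FALSE`
#'   when a vector is constant and rho is undefined).
#' @export
spearman_perm <- function(x, y, n_perm = 10000, exact_max = 7, seed = 1) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rho <- .spearman_rho(x, y)
  if (is.na(rho)) {
    return(data.frame(rho = NA_real_, p_value = NA_real_, n = n,
                      method = "undefined", seed = seed, defined = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  if (n <= exact_max) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  } else {
    rhos <- .with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) stats::cor(rx, sample(ry)), numeric(1))
    })
    p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
    method <- "monte-carlo"
  }
  data.frame(rho = rho, p_value = p, n = n, method = method, seed = seed,
             defined = TRUE)
}

#' Pairwise cross-antibiotic correlations of persister fractions
#'
#' For every unordered pair of single-antibiotic treatments, rank-correlates
#' the per-strain `mean_log10_fp` values across strains measured in both
#' members.  This is the study's central test of the multidrug-tolerance
#' hypothesis: if one physiological change (e.g. dormancy) set each strain's
#' persister level, fractions would correlate positively across antibiotics.
#'
#' @param summaries data.frame of strain summaries (rows from
#'   [summarize_strain()]).
#' @param treatments Treatments to correlate (default: all in `summaries`
#'   without a `+`, i.e. single drugs).
#' @param min_n Minimum complete pairs per correlation (default 3); pairs
#'   with fewer are skipped with a reason.
#' @param n_perm,seed Passed to [spearman_perm()].
#' @return data.frame with one row per treatment pair: `treatment_a`,
#'   `treatment_b`, `rho`, `p_value`, `n`, `n_dropped`, `method`, `skipped`,
#'   `reason`.
#' @export
cross_antibiotic_correlations <- function(summaries, treatments = NULL,
                                          min_n = 3, n_perm = 10000,
                                          seed = 1) {
  stopifnot(is.data.frame(summaries),
            all(c("strain", "treatment", "mean_log10_fp") %in% names(summaries)))
  if (is.null(treatments))
    treatments <- sort(unique(summaries$treatment[!grepl("\\+", summaries$treatment)]))
  if (length(treatments) < 2)
    stop("need at least two treatments to correlate", call. = FALSE)
  pairs <- utils::combn(treatments, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- summaries[summaries$treatment == pr[1], c("strain", "mean_log10_fp")]
    b <- summaries[summaries$treatment == pr[2], c("strain", "mean_log10_fp")]
    merged <- merge(a, b, by = "strain", suffixes = c("_a", "_b"))
    merged <- merged[stats::complete.cases(merged), ]
    n_all <- length(unique(c(a$strain, b$strain)))
    base <- data.frame(treatment_a = pr[1], treatment_b = pr[2],
                       rho = NA_real_, p_value = NA_real_,
                       n = nrow(merged), n_dropped = n_all - nrow(merged),
                       method = NA_character_, skipped = TRUE,
                       reason = NA_character_)
    if (nrow(merged) < min_n) {
      base$reason <- sprintf("only %d complete strain pairs (< %d)",
                             nrow(merged), min_n)
      return(base)
    }
    sp <- spearman_perm(merged$mean_log10_fp_a, merged$mean_log10_fp_b,
                        n_perm = n_perm, seed = derive_seed(seed, pr[1], pr[2]))
    base$rho <- sp$rho; base$p_value <- sp$p_value; base$n <- sp$n
    base$method <- sp$method; base$skipped <- FALSE
    base
  })
  do.call(rbind, out)
}

#' Classify a combination-treatment persister fraction
#'
#' Given the persister fractions under two single antibiotics (`f_A`, `f_B`)
#' and under their combination (`f_AB`), decides which survival hypothesis the
#' triple supports: *exclusive* (no cell persists both drugs; `f_AB` below the
#' detection bound), *independent* (`f_AB ~ f_A * f_B`, persistence mechanisms
#' induced independently) or *coincident* (`f_AB ~ min(f_A, f_B)`, the
#' fraction surviving the more lethal drug is multidrug tolerant).  Distances
#' are measured in log10; the nearer hypothesis wins if its distance is within
#' `tau`, otherwise the call is *ambiguous*.
#'
#' @param f_A,f_B Single-drug persister fractions (> detection bound).
#' @param f_AB Combination persister fraction (`>= 0`).
#' @param tau Classification tolerance in log10 units (default 0.5: half an
#'   order of magnitude).
#' @param detection_bound Fractions below this are treated as "no detected
#'   persisters" (default `1e-9`; take it from the fits' `fp_bound` when
#'   available).
#' @return A one-row data.frame: `f_A`, `f_B`, `f_AB`, `label`, `d_coincident`,
#'   `d_independent` (log10 distances; reported for every call).
#' @export
classify_combination <- function(f_A, f_B, f_AB, tau = 0.5,
                                 detection_bound = 1e-9) {
  stopifnot(is.numeric(f_A), is.numeric(f_B), is.numeric(f_AB),
            is.finite(tau), tau > 0, detection_bound > 0)
  if (!is.finite(f_A) || !is.finite(f_B) || f_A <= detection_bound ||
      f_B <= detection_bound)
    stop("single-drug fractions must exceed the detection bound", call. = FALSE)
  if (!is.finite(f_AB) || f_AB < 0)
    stop("f_AB must be finite and >= 0", call. = FALSE)
  if (f_AB <= detection_bound) {
    d_coin <- d_ind <- Inf
    label <- "exclusive"
  } else {
    d_coin <- abs(log10(f_AB) - log10(min(f_A, f_B)))
    d_ind <- abs(log10(f_AB) - log10(f_A * f_B))
    d_best <- min(d_coin, d_ind)
    label <- if (d_best > tau) "ambiguous"
             else if (d_coin <= d_ind) "coincident" else "independent"
  }
  data.frame(f_A = f_A, f_B = f_B, f_AB = f_AB, label = label,
             d_coincident = d_coin, d_independent = d_ind)
}

#' Correlate the persister fraction with the mechanistic rates
#'
#' Pools strain x treatment fits and rank-correlates the persister fraction
#' (log10 `fp_mid`) with each mechanistic rate (log10 of `a`, `b`, `m`): which
#' parameter determines a strain's persister level?  In the two-state model
#' grown to switching equilibrium the fraction is set primarily by the
#' normal -> persister rate `a`.
#'
#' @param fits_table data.frame with columns `fp_mid`, `a`, `b`, `m` (one row
#'   per strain x treatment; e.g. built from [fit_replicate()] results).
#' @param n_perm,seed Passed to [spearman_perm()].
#' @return data.frame with exactly three rows (`fp` vs `a`, `b`, `m`):
#'   `variable`, `rho`, `p_value`, `n`, `method`, `defined`.
#' @export
parameter_determinants <- function(fits_table, n_perm = 10000, seed = 1) {
  stopifnot(is.data.frame(fits_table),
            all(c("fp_mid", "a", "b", "m") %in% names(fits_table)))
  ok <- stats::complete.cases(fits_table[, c("fp_mid", "a", "b", "m")])
  ft <- fits_table[ok, ]
  if (nrow(ft) < 3)
    stop("need at least 3 strain x treatment fits", call. = FALSE)
  out <- lapply(c("a", "b", "m"), function(v) {
    sp <- spearman_perm(log10(pmax(ft$fp_mid, .Machine$double.xmin)),
                        log10(pmax(ft[[v]], .Machine$double.xmin)),
                        n_perm = n_perm, seed = derive_seed(seed, "determinant", v))
    data.frame(variable = sprintf("fp_vs_%s", v), rho = sp$rho,
               p_value = sp$p_value, n = sp$n, method = sp$method,
               defined = sp$defined)
  })
  do.call(rbind, out)
}
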