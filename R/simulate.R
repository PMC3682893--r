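#' Simulate one Poisson-sampled kill curve
#'
#' Generates colony counts for a replicate: the deterministic two-state mean
#' `N(t)` is evaluated on the design's schedule, effective plated volumes are
#' chosen by [design_dilutions()], and counts are drawn
#' `x_t ~ Poisson(N(t) * delta_t)` — exactly the error model the fitting
#' likelihood assumes.  Deterministic given `seed`.
#'
#' @param mech A [mech_params()] object.
#' @param init An [initial_state()] object.
#' @param design A [plating_design()].
#' @param seed Integer seed.
#' @param strain,treatment,replicate Identifiers stored on the curve.
#' @return A [kill_curve()]; the generating truth is attached as
#'   `attr(, "truth")` (list with `mech`, `init`, `obs`).
#' @export
simulate_kill_curve <- function(mech, init, design = plating_design(),
                                seed = 1, strain = "sim", treatment = "drug",
                                replicate = "1") {
  stopifnot(inherits(mech, "mech_params"), inherits(init, "initial_state"),
            inherits(design, "plating_design"))
  obs <- mech_to_obs(mech, init)
  delta <- design_dilutions(obs, design)
  mu <- total_cfu(obs, design$schedule) * delta
  x <- .with_seed(seed, stats::rpois(length(mu), mu))
  curve <- kill_curve(design$schedule, x, delta,
                      strain = strain, treatment = treatment,
                      replicate = replicate)
  attr(curve, "truth") <- list(mech = mech, init = init, obs = obs)
  curve
}

#' Exact stochastic simulation of the two-state switching process
#'
#' Event-driven (Gillespie) simulation of the three elementary events —
#' death of a normal cell (propensity `m n`), switching normal -> persister
#' (`a n`) and persister -> normal (`b p`) — for integer cell counts.  Serves
#' as an independent oracle for the deterministic closed form: the ensemble
#' mean of `n(t) + p(t)` converges to [total_cfu()].
#'
#' @param mech A [mech_params()] object.
#' @param n0,p0 Integer initial counts of normal and persister cells.
#' @param t_grid Times (hours, non-decreasing, `>= 0`) at which to record the
#'   state.
#' @param seed Integer seed.
#' @return data.frame with columns `time_h`, `n`, `p`.
#' @export
simulate_stochastic <- function(mech, n0, p0, t_grid, seed = 1) {
  stopifnot(inherits(mech, "mech_params"),
            n0 >= 0, p0 >= 0, n0 == round(n0), p0 == round(p0),
            is.numeric(t_grid), all(t_grid >= 0), !is.unsorted(t_grid))
  states <- .with_seed(seed,
    cpp_gillespie_two_state(mech$m, mech$a, mech$b,
                            as.integer(n0), as.integer(p0),
                            as.numeric(t_grid)))
  data.frame(time_h = t_grid, n = states[, 1L], p = states[, 2L])
}

#' Study scenario: strains, treatments and parameter distributions
#'
#' Describes a synthetic study emulating a multi-strain, multi-antibiotic
#' persistence assay: 4 h of exponential growth, drug addition, sampling per
#' the plating design, 6 biological replicates.  Per strain x antibiotic, a
#' persister fraction `fp` (log-uniform over four orders of magnitude), kill
#' rate `m`, and return-switching rate `b` are drawn; the forward switching
#' rate is set to the balanced-growth equilibrium value
#' `a = fp/(1-fp) * (g + b)` (growth rate `g`), which makes the drawn `fp`
#' the persister fraction actually present after exponential growth.
#'
#' `fraction_model = "shared"` draws one `fp` per strain used for every
#' antibiotic (the multidrug-tolerance hypothesis: strains have characteristic
#' persister fractions); `"independent"` draws `fp` per strain x antibiotic
#' (no common mechanism).
#'
#' For combination treatments (pairs of antibiotics) the persister fraction
#' follows the pair's hypothesis: `exclusive` -> 0, `independent` ->
#' `fp_A * fp_B`, `coincident` -> `min(fp_A, fp_B)` (the fraction surviving
#' the more lethal drug); the kill rate is the max of the single-drug rates.
#'
#' @param n_strains Number of strains (default 12).
#' @param antibiotics Character vector of single-drug treatments.
#' @param pairs List of length-2 character vectors (combination treatments),
#'   or `NULL`.
#' @param n_replicates Biological replicates per strain x treatment
#'   (default 6).
#' @param fraction_model `"shared"` or `"independent"`.
#' @param combination_hypothesis Single label or one per pair:
#'   `"exclusive"`, `"independent"` or `"coincident"`.
#' @param fp_range,m_range,b_range,N0_range Log-uniform draw ranges for the
#'   persister fraction, kill rate (1/h), persister->normal switching rate
#'   (1/h) and initial density (CFU/ml).
#' @param growth_rate Pre-treatment exponential growth rate `g` (1/h) used to
#'   set `a` at its balanced-growth equilibrium.
#' @param seed Integer seed; all draws and counts derive from it.
#' @return A list of class `study_scenario`.
#' @export
study_scenario <- function(n_strains = 12,
                           antibiotics = c("ampicillin", "ciprofloxacin",
                                           "nalidixic_acid"),
                           pairs = NULL,
                           n_replicates = 6,
                           fraction_model = c("independent", "shared"),
                           combination_hypothesis = "coincident",
                           fp_range = c(1e-5, 0.1),
                           m_range = c(0.5, 5),
                           b_range = c(1e-4, 0.1),
                           N0_range = c(1e7, 1e8),
                           growth_rate = 1.0,
                           seed = 1) {
  fraction_model <- match.arg(fraction_model)
  hyp_vocab <- c("exclusive", "independent", "coincident")
  if (!is.null(pairs)) {
    stopifnot(all(vapply(pairs, length, integer(1)) == 2L))
    if (length(combination_hypothesis) == 1L)
      combination_hypothesis <- rep(combination_hypothesis, length(pairs))
    if (length(combination_hypothesis) != length(pairs))
      stop("one combination_hypothesis per pair (or a single label) required",
           call. = FALSE)
    if (!all(combination_hypothesis %in% hyp_vocab))
      stop("combination_hypothesis must be one of: ",
           paste(hyp_vocab, collapse = ", "), call. = FALSE)
    bad <- !unlist(pairs) %in% antibiotics
    if (any(bad))
      stop("pair members must be drawn from `antibiotics`", call. = FALSE)
  }
  stopifnot(n_strains >= 1, n_replicates >= 1,
            all(c(fp_range, m_range, b_range, N0_range) > 0),
            growth_rate >= 0)
  structure(list(n_strains = as.integer(n_strains), antibiotics = antibiotics,
                 pairs = pairs, n_replicates = as.integer(n_replicates),
                 fraction_model = fraction_model,
                 combination_hypothesis = if (is.null(pairs)) character(0)
                                          else combination_hypothesis,
                 fp_range = fp_range, m_range = m_range, b_range = b_range,
                 N0_range = N0_range, growth_rate = growth_rate,
                 seed = as.integer(seed)),
            class = "study_scenario")
}

.runif_log <- function(n, range) 10^stats::runif(n, log10(range[1]), log10(range[2]))

#' Generate a full synthetic study
#'
#' Draws generating parameters per the scenario, simulates every
#' strain x treatment x replicate kill curve by [simulate_kill_curve()], and
#' returns the long-format CFU table together with the truth table of
#' generating parameters.  All randomness derives from the scenario seed via
#' [derive_seed()]; identical seeds reproduce identical datasets.
#'
#' @param scenario A [study_scenario()].
#' @param design A [plating_design()].
#' @return A list with `cfu` (data.frame: `strain`, `treatment`, `replicate`,
#'   `time_h`, `plated_volume_ml`, `cfu`) and `truth` (data.frame: `strain`,
#'   `treatment`, `hypothesis`, `fp`, `m`, `a`, `b`, `N0`).
#' @export
generate_study <- function(scenario, design = plating_design()) {
  stopifnot(inherits(scenario, "study_scenario"),
            inherits(design, "plating_design"))
  strains <- sprintf("S%02d", seq_len(scenario$n_strains))
  ab <- scenario$antibiotics
  g <- scenario$growth_rate

  truth <- .with_seed(derive_seed(scenario$seed, "params"), {
    rows <- list()
    for (s in strains) {
      fp_shared <- .runif_log(1, scenario$fp_range)
      single <- list()
      for (drug in ab) {
        fp <- if (scenario$fraction_model == "shared") fp_shared
              else .runif_log(1, scenario$fp_range)
        m <- .runif_log(1, scenario$m_range)
        b <- .runif_log(1, scenario$b_range)
        a <- fp / (1 - fp) * (g + b)
        N0 <- .runif_log(1, scenario$N0_range)
        single[[drug]] <- list(fp = fp, m = m, a = a, b = b, N0 = N0)
        rows[[length(rows) + 1L]] <- data.frame(
          strain = s, treatment = drug, hypothesis = NA_character_,
          fp = fp, m = m, a = a, b = b, N0 = N0)
      }
      if (!is.null(scenario$pairs)) {
        for (i in seq_along(scenario$pairs)) {
          pr <- scenario$pairs[[i]]
          hyp <- scenario$combination_hypothesis[i]
          A <- single[[pr[1]]]; B <- single[[pr[2]]]
          fp_AB <- switch(hyp,
                          exclusive = 0,
                          independent = A$fp * B$fp,
                          coincident = min(A$fp, B$fp))
          lethal <- if (A$m >= B$m) A else B
          m_AB <- lethal$m; b_AB <- lethal$b
          a_AB <- fp_AB / (1 - fp_AB) * (g + b_AB)
          rows[[length(rows) + 1L]] <- data.frame(
            strain = s, treatment = paste(pr, collapse = "+"),
            hypothesis = hyp, fp = fp_AB, m = m_AB, a = a_AB, b = b_AB,
            N0 = lethal$N0)
        }
      }
    }
    do.call(rbind, rows)
  })

  cfu <- vector("list", nrow(truth) * scenario$n_replicates)
  idx <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    mech <- mech_params(tr$m, tr$a, tr$b)
    init <- initial_state(tr$N0, tr$fp)
    for (r in seq_len(scenario$n_replicates)) {
      curve <- simulate_kill_curve(
        mech, init, design,
        seed = derive_seed(scenario$seed, tr$strain, tr$treatment, r),
        strain = tr$strain, treatment = tr$treatment, replicate = r)
      idx <- idx + 1L
      cfu[[idx]] <- data.frame(strain = tr$strain, treatment = tr$treatment,
                               replicate = as.character(r),
                               time_h = curve$data$time_h,
                               plated_volume_ml = curve$data$volume_ml,
                               cfu = curve$data$cfu)
    }
  }
  list(cfu = do.call(rbind, cfu), truth = truth)
}
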