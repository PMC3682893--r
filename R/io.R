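#' Read a long-format CFU table into kill curves
#'
#' Expects a CSV with header
#' `strain,treatment,replicate,time_h,plated_volume_ml,cfu`
#' (one row per plated sample; `plated_volume_ml` is the *effective* plated
#' volume, i.e. plated volume times serial-dilution factor — exactly the
#' `delta_t` the Poisson likelihood needs).  Rows are grouped into one
#' [kill_curve()] per strain x treatment x replicate, sorted by time.
#'
#' @param path Path to the CSV file.
#' @return Named list of [kill_curve()] objects
#'   (names `strain/treatment/replicate`).
#' @export
read_cfu_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("strain", "treatment", "replicate", "time_h",
                "plated_volume_ml", "cfu")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  check_num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | !is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric %s at data row %d (value '%s')",
                   col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    v
  }
  df$time_h <- check_num("time_h")
  df$plated_volume_ml <- check_num("plated_volume_ml")
  df$cfu <- check_num("cfu")
  bad_cfu <- which(df$cfu < 0 | df$cfu != round(df$cfu))
  if (length(bad_cfu) > 0)
    stop(sprintf("cfu must be a non-negative integer: data row %d (value %g)",
                 bad_cfu[1], df$cfu[bad_cfu[1]]), call. = FALSE)
  bad_t <- which(df$time_h < 0)
  if (length(bad_t) > 0)
    stop(sprintf("negative time at data row %d", bad_t[1]), call. = FALSE)
  key <- paste(df$strain, df$treatment, df$replicate, sep = "/")
  dup <- duplicated(paste(key, df$time_h))
  if (any(dup))
    stop(sprintf("duplicated (strain, treatment, replicate, time) at data row %d",
                 which(dup)[1]), call. = FALSE)
  groups <- split(df, key)
  curves <- lapply(groups, function(gr) {
    gr <- gr[order(gr$time_h), ]
    kill_curve(gr$time_h, gr$cfu, gr$plated_volume_ml,
               strain = gr$strain[1], treatment = gr$treatment[1],
               replicate = gr$replicate[1])
  })
  curves
}

#' Write kill curves (or a long CFU data.frame) to CSV
#'
#' Inverse of [read_cfu_table()]: writes the canonical long format.
#'
#' @param curves A list of [kill_curve()] objects, or a data.frame already in
#'   the long format.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cfu_table <- function(curves, path) {
  df <- if (is.data.frame(curves)) curves else {
    do.call(rbind, lapply(curves, function(cv) {
      data.frame(strain = cv$strain, treatment = cv$treatment,
                 replicate = cv$replicate, time_h = cv$data$time_h,
                 plated_volume_ml = cv$data$volume_ml, cfu = cv$data$cfu)
    }))
  }
  required <- c("strain", "treatment", "replicate", "time_h",
                "plated_volume_ml", "cfu")
  stopifnot(all(required %in% names(df)))
  utils::write.csv(df[, required], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of a full run: either an input CFU table or a
#' simulation scenario, the per-curve fit settings, and the study-analysis
#' settings.  Round-trips through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param input Path to a long-format CFU CSV, or `NULL` to simulate.
#' @param scenario A [study_scenario()] (used when `input` is `NULL`).
#' @param design A [plating_design()].
#' @param fit A [fit_config()].
#' @param tau Combination-classification tolerance (log10 units).
#' @param detection_bound Fraction below which combination survival counts as
#'   "none detected".
#' @param n_perm Permutations for the correlation tests.
#' @param seed Analysis-stage seed.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param verbose Print stage progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, scenario = study_scenario(),
                            design = plating_design(), fit = fit_config(),
                            tau = 0.5, detection_bound = 1e-9,
                            n_perm = 10000, seed = 1,
                            out_dir = NULL, verbose = FALSE) {
  structure(list(input = input, scenario = scenario, design = design,
                 fit = fit, tau = tau, detection_bound = detection_bound,
                 n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sc <- raw$scenario
  scenario <- study_scenario(
    n_strains = sc$n_strains, antibiotics = unlist(sc$antibiotics),
    pairs = sc$pairs, n_replicates = sc$n_replicates,
    fraction_model = sc$fraction_model,
    combination_hypothesis = if (length(sc$combination_hypothesis)) unlist(sc$combination_hypothesis) else "coincident",
    fp_range = unlist(sc$fp_range), m_range = unlist(sc$m_range),
    b_range = unlist(sc$b_range), N0_range = unlist(sc$N0_range),
    growth_rate = sc$growth_rate, seed = sc$seed)
  de <- raw$design
  design <- plating_design(
    schedule = unlist(de$schedule), culture_volume_ml = de$culture_volume_ml,
    spot_volume_ml = de$spot_volume_ml,
    late_volumes_ml = unlist(de$late_volumes_ml),
    target_count_range = unlist(de$target_count_range),
    max_dilution_steps = de$max_dilution_steps, late_time_h = de$late_time_h)
  ft <- raw$fit
  fit <- fit_config(n_starts = ft$n_starts, use_sann = ft$use_sann,
                    maxit = ft$maxit, seed = ft$seed,
                    detection_time_h = ft$detection_time_h)
  pipeline_config(input = raw$input, scenario = scenario, design = design,
                  fit = fit, tau = raw$tau,
                  detection_bound = raw$detection_bound, n_perm = raw$n_perm,
                  seed = raw$seed, out_dir = raw$out_dir,
                  verbose = raw$verbose)
}

# Flatten a list of persister_fit objects to one row per replicate.
.fits_to_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(strain = f$strain, treatment = f$treatment,
               replicate = f$replicate,
               c1 = f$obs_hat$c1, c2 = f$obs_hat$c2,
               l1 = f$obs_hat$l1, l2 = f$obs_hat$l2,
               loglik = f$loglik,
               fp_min = f$fraction$fp_min, fp_mid = f$fp_mid,
               fp_max = f$fraction$fp_max,
               m = f$mech_hat$m, a = f$mech_hat$a, b = f$mech_hat$b,
               slow_fraction = f$slow_fraction, N0_hat = f$N0_hat,
               converged = f$converged,
               detection_limited = f$detection_limited,
               fp_bound = f$fp_bound)
  }))
}

.log_line <- function(con, verbose, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 sprintf(fmt, ...))
  if (!is.null(con)) writeLines(msg, con)
  if (verbose) message(msg)
}

#' Run the full persister-quantification pipeline
#'
#' Composes the stages: simulate (when no input table is given) -> fit every
#' replicate -> summarise per strain x treatment -> cross-antibiotic
#' correlations -> combination-treatment classification (when single drugs and
#' their pairs are both present) -> parameter-determinant correlations.
#' Identical config and seed reproduce identical outputs.  When
#' `config$out_dir` is set, writes `cfu.csv` (simulated runs), `truth.csv`,
#' `fits.csv`, `summaries.csv`, `correlations.csv`, `combination_calls.csv`,
#' `determinants.csv` and a plain-text `run.log` with seeds and convergence
#' statistics.
#'
#' @param config A [pipeline_config()].
#' @return A list with `fits` (table), `summaries`, `correlations`,
#'   `combination_calls` (or `NULL`), `determinants`, `truth` (or `NULL` for
#'   real data), and `n_failed` (curves whose fit errored).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  con <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(config$out_dir, "run.log"), open = "wt")
    on.exit(close(con), add = TRUE)
  }
  .log_line(con, config$verbose, "pipeline start (seed %d)", config$seed)

  truth <- NULL
  if (is.null(config$input)) {
    study <- generate_study(config$scenario, config$design)
    truth <- study$truth
    tmp <- tempfile(fileext = ".csv")
    write_cfu_table(study$cfu, tmp)
    curves <- read_cfu_table(tmp)
    unlink(tmp)
    if (!is.null(config$out_dir)) {
      write_cfu_table(study$cfu, file.path(config$out_dir, "cfu.csv"))
      utils::write.csv(truth, file.path(config$out_dir, "truth.csv"),
                       row.names = FALSE)
    }
    .log_line(con, config$verbose,
              "simulated %d curves (%d strains, scenario seed %d, %s fractions)",
              length(curves), config$scenario$n_strains,
              config$scenario$seed, config$scenario$fraction_model)
  } else {
    curves <- read_cfu_table(config$input)
    .log_line(con, config$verbose, "read %d curves from %s",
              length(curves), config$input)
  }

  fits <- list()
  n_failed <- 0L
  for (cv in curves) {
    f <- tryCatch(fit_replicate(cv, config$fit), error = function(e) e)
    if (inherits(f, "error")) {
      n_failed <- n_failed + 1L
      .log_line(con, config$verbose, "fit failed (%s/%s/%s): %s",
                cv$strain, cv$treatment, cv$replicate, conditionMessage(f))
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  if (length(fits) == 0)
    stop("fit stage: no curve could be fitted", call. = FALSE)
  fit_table <- .fits_to_table(fits)
  .log_line(con, config$verbose, "fitted %d/%d curves (%d converged)",
            length(fits), length(curves), sum(fit_table$converged))

  key <- paste(fit_table$strain, fit_table$treatment, sep = "/")
  summaries <- do.call(rbind, lapply(split(seq_along(fits), key),
                                     function(idx) summarize_strain(fits[idx])))
  rownames(summaries) <- NULL

  correlations <- tryCatch(
    cross_antibiotic_correlations(summaries, n_perm = config$n_perm,
                                  seed = derive_seed(config$seed, "correlations")),
    error = function(e) {
      .log_line(con, config$verbose, "correlation stage skipped: %s",
                conditionMessage(e))
      NULL
    })

  combo_calls <- NULL
  combos <- unique(summaries$treatment[grepl("\\+", summaries$treatment)])
  if (length(combos) > 0) {
    rows <- lapply(combos, function(cmb) {
      drugs <- strsplit(cmb, "+", fixed = TRUE)[[1]]
      strains <- unique(summaries$strain[summaries$treatment == cmb])
      do.call(rbind, lapply(strains, function(s) {
        getf <- function(tr) {
          r <- summaries[summaries$strain == s & summaries$treatment == tr, ]
          if (nrow(r) == 1 && isTRUE(r$available)) 10^r$mean_log10_fp else NA_real_
        }
        fA <- getf(drugs[1]); fB <- getf(drugs[2]); fAB <- getf(cmb)
        if (anyNA(c(fA, fB, fAB))) return(NULL)
        cc <- tryCatch(
          classify_combination(fA, fB, fAB, tau = config$tau,
                               detection_bound = config$detection_bound),
          error = function(e) NULL)
        if (is.null(cc)) return(NULL)
        cbind(data.frame(strain = s, pair = cmb), cc)
      }))
    })
    combo_calls <- do.call(rbind, rows)
  }

  determinants <- tryCatch(
    parameter_determinants(fit_table[fit_table$converged, ],
                           n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "determinants")),
    error = function(e) NULL)

  if (!is.null(config$out_dir)) {
    utils::write.csv(fit_table, file.path(config$out_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                     row.names = FALSE)
    if (!is.null(correlations))
      utils::write.csv(correlations,
                       file.path(config$out_dir, "correlations.csv"),
                       row.names = FALSE)
    if (!is.null(combo_calls))
      utils::write.csv(combo_calls,
                       file.path(config$out_dir, "combination_calls.csv"),
                       row.names = FALSE)
    if (!is.null(determinants))
      utils::write.csv(determinants,
                       file.path(config$out_dir, "determinants.csv"),
                       row.names = FALSE)
  }
  .log_line(con, config$verbose, "pipeline done")

  list(fits = fit_table, summaries = summaries, correlations = correlations,
       combination_calls = combo_calls, determinants = determinants,
       truth = truth, n_failed = n_failed)
}
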