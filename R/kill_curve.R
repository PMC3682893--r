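#' A single replicate's antibiotic kill curve
#'
#' One biological replicate of a time-kill assay: raw colony counts at timed
#' samples after drug addition, each with its *effective plated volume*
#' `delta = plated volume x serial-dilution factor` (ml), so that under Poisson
#' sampling the expected count at time `t` is `N(t) * delta`.
#'
#' @param time_h Sampling times after drug addition (hours, `>= 0`, strictly
#'   increasing).
#' @param cfu Colony counts (non-negative integers).
#' @param volume_ml Effective plated volumes `delta_t` (ml, `> 0`).
#' @param strain,treatment,replicate Identifiers (any scalar coercible to
#'   character).
#'
#' @return An object of class `kill_curve`: list with the identifiers and a
#'   data.frame `data` with columns `time_h`, `cfu`, `volume_ml`.
#' @export
#' @examples
#' kill_curve(time_h = c(0, 1, 2, 3, 4, 20, 24, 28, 48),
#'            cfu = c(120, 45, 30, 25, 21, 18, 17, 15, 9),
#'            volume_ml = c(1e-5, 1e-5, rep(1e-4, 3), rep(0.1, 4)))
kill_curve <- function(time_h, cfu, volume_ml,
                       strain = "strain", treatment = "treatment",
                       replicate = "1") {
  stopifnot(is.numeric(time_h), is.numeric(cfu), is.numeric(volume_ml))
  n <- length(time_h)
  if (length(cfu) != n || length(volume_ml) != n)
    stop("time_h, cfu and volume_ml must have equal length", call. = FALSE)
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing within a curve", call. = FALSE)
  if (any(!is.finite(cfu)) || any(cfu < 0) || any(cfu != round(cfu)))
    stop("cfu must be non-negative integers", call. = FALSE)
  if (any(!is.finite(volume_ml)) || any(volume_ml <= 0))
    stop("effective plated volumes must be > 0", call. = FALSE)
  structure(list(strain = as.character(strain),
                 treatment = as.character(treatment),
                 replicate = as.character(replicate),
                 data = data.frame(time_h = as.numeric(time_h),
                                   cfu = as.integer(round(cfu)),
                                   volume_ml = as.numeric(volume_ml))),
            class = "kill_curve")
}

#' @export
print.kill_curve <- function(x, ...) {
  cat(sprintf("Kill curve: strain %s, treatment %s, replicate %s (%d timepoints, %g-%g h)\n",
              x$strain, x$treatment, x$replicate, nrow(x$data),
              min(x$data$time_h), max(x$data$time_h)))
  invisible(x)
}
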