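#' Serial-dilution plating design
#'
#' Describes how a time-kill assay is sampled: the sampling schedule (4 h of
#' hourly samples after drug addition plus late samples near 20/24/28/48 h),
#' spot plating of serially diluted early samples, and direct plating of
#' larger volumes late, when counts are low.
#'
#' @param schedule Sampling times in hours, strictly increasing from 0.
#' @param culture_volume_ml Culture volume (ml).
#' @param spot_volume_ml Volume of one spotted drop (ml); early samples are
#'   plated as spots of serial 10-fold dilutions.
#' @param late_volumes_ml Allowed directly plated volumes at late timepoints
#'   (ml).
#' @param target_count_range Desired colonies per plate `c(min, max)`.
#' @param max_dilution_steps Largest allowed number of 10-fold dilution steps.
#' @param late_time_h Times `>=` this use the late (large-volume) plating arm.
#' @return A list of class `plating_design`.
#' @export
plating_design <- function(schedule = c(0, 1, 2, 3, 4, 20, 24, 28, 48),
                           culture_volume_ml = 1.5,
                           spot_volume_ml = 0.005,
                           late_volumes_ml = seq(0.1, 0.5, by = 0.1),
                           target_count_range = c(10, 300),
                           max_dilution_steps = 12,
                           late_time_h = 8) {
  stopifnot(is.numeric(schedule), length(schedule) >= 1,
            schedule[1] == 0, !is.unsorted(schedule, strictly = TRUE),
            culture_volume_ml > 0, spot_volume_ml > 0,
            all(late_volumes_ml > 0),
            length(target_count_range) == 2,
            target_count_range[1] > 0,
            target_count_range[2] > target_count_range[1])
  structure(list(schedule = schedule, culture_volume_ml = culture_volume_ml,
                 spot_volume_ml = spot_volume_ml,
                 late_volumes_ml = sort(late_volumes_ml),
                 target_count_range = target_count_range,
                 max_dilution_steps = as.integer(max_dilution_steps),
                 late_time_h = late_time_h),
            class = "plating_design")
}

#' Choose effective plated volumes along a kill curve
#'
#' For every scheduled time, picks the effective plated volume
#' `delta = plated volume x 10^-k` (from the allowed serial-dilution /
#' plated-volume vocabulary of the design) that brings the expected colony
#' count `N(t) * delta` into the target range where possible.  Early samples
#' use spotted serial dilutions; late samples may also plate the larger
#' volumes directly, and when even the largest allowed volume undershoots the
#' target (the detection-limit regime) that largest volume is used.  The
#' choice is a deterministic function of the inputs.
#'
#' @param obs An [obs_params()] object (the expected curve).
#' @param design A [plating_design()].
#' @return Numeric vector of effective plated volumes (ml), one per scheduled
#'   time.
#' @export
design_dilutions <- function(obs, design) {
  stopifnot(inherits(obs, "obs_params"), inherits(design, "plating_design"))
  lo <- design$target_count_range[1]; hi <- design$target_count_range[2]
  dil <- 10^-(0:design$max_dilution_steps)
  spot_set <- design$spot_volume_ml * dil
  late_set <- sort(unique(c(as.vector(outer(design$late_volumes_ml, dil)),
                            spot_set)), decreasing = TRUE)
  spot_set <- sort(spot_set, decreasing = TRUE)
  vapply(design$schedule, function(t) {
    expected <- total_cfu(obs, t)
    allowed <- if (t >= design$late_time_h) late_set else spot_set
    counts <- expected * allowed
    in_range <- which(counts >= lo & counts <= hi)
    if (length(in_range) > 0) return(allowed[in_range[1]])
    if (all(counts < lo)) return(allowed[1])     # undershoot even at max volume
    # overshoot/gap: take the volume whose expectation is closest to the range
    dist <- pmax(lo - counts, counts - hi, 0)
    allowed[which.min(dist)]
  }, numeric(1))
}
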