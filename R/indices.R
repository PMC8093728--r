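#' Prey-capture probability model
#'
#' Logistic model giving the probability that a benthic dive ends in a prey
#' capture, as a function of descent rate (m/s) and dive duration (s):
#' `p = plogis(intercept + coef_descent_rate * descent_rate +
#' coef_duration * duration)`. The shipped default coefficients are
#' unvalidated synthetic placeholders on the scale of video-calibrated
#' relationships for shelf-foraging otariids; replace them with
#' deployment-specific calibrated values for real analyses.
#'
#' @param intercept,coef_descent_rate,coef_duration finite numeric
#'   coefficients.
#' @param note provenance string carried into reports.
#' @return object of class `capture_model`.
#' @export
capture_model <- function(intercept = -2, coef_descent_rate = 1.2,
                          coef_duration = 0.004,
                          note = "unvalidated synthetic defaults") {
  stopifnot(is.finite(intercept), is.finite(coef_descent_rate),
            is.finite(coef_duration))
  structure(list(intercept = intercept,
                 coef_descent_rate = coef_descent_rate,
                 coef_duration = coef_duration, note = note),
            class = "capture_model")
}

#' Per-dive prey-capture probability
#'
#' Applies a [capture_model()] to benthic dives. The calibration behind
#' such models is benthic-only, so applying it to pelagic dives is an error.
#'
#' @param dives data.frame with `descent_rate`, `duration` and (if present)
#'   `is_benthic`; all rows must be benthic.
#' @param model a [capture_model()].
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
capture_probability <- function(dives, model = capture_model()) {
  stopifnot(inherits(model, "capture_model"))
  if (!is.null(dives$is_benthic) && !all(dives$is_benthic)) {
    stop("capture probabilities are defined for benthic dives only")
  }
  plogis(model$intercept +
           model$coef_descent_rate * dives$descent_rate +
           model$coef_duration * dives$duration)
}

#' Foraging trip success and efficiency indices
#'
#' For the benthic dives of one trip: the Foraging Trip Success Index
#' (FTSI) is the sum of predicted per-dive capture probabilities divided by
#' the summed benthic dive duration in hours; the Foraging Trip Efficiency
#' Index (FTEI) is the same probability sum divided by the benthic dive
#' rate (summed benthic vertical distance, m, over time at sea, h).
#'
#' @param dives benthic dives of one trip (`descent_rate`, `duration`,
#'   `vertical_distance`; `is_benthic` all TRUE if present).
#' @param trip_duration_h time at sea, hours (denominator of the benthic
#'   dive rate).
#' @param model a [capture_model()].
#' @return one-row data.frame: `ftsi`, `ftei`, `benthic_dive_rate`,
#'   `sum_capture_prob`, `n_benthic`.
#' @export
trip_indices <- function(dives, trip_duration_h, model = capture_model()) {
  if (nrow(dives) == 0L) stop("trip has no benthic dives")
  stopifnot(trip_duration_h > 0)
  p <- capture_probability(dives, model)
  dur_h <- sum(dives$duration) / 3600
  rate <- sum(dives$vertical_distance) / trip_duration_h
  data.frame(
    ftsi = sum(p) / dur_h,
    ftei = sum(p) / rate,
    benthic_dive_rate = rate,
    sum_capture_prob = sum(p),
    n_benthic = nrow(dives)
  )
}
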