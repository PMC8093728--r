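#' Zero-offset correction of a depth series
#'
#' Pressure sensors drift, so raw "surface" readings wander away from 0 m.
#' The correction estimates a slowly varying surface baseline as a low
#' quantile of the depth record over successive windows (linearly
#' interpolated between window centres), subtracts it, and clips the result
#' at 0 m. The quantile must sit below the fraction of time the animal
#' spends at the surface.
#'
#' @param depth data.frame with columns `time` (numeric seconds or POSIXct,
#'   strictly increasing) and `depth_m`.
#' @param window baseline window length, seconds (default 3 h).
#' @param quantile surface quantile of the window (default 0.05).
#' @return the input data.frame with `depth_m` corrected.
#' @export
zero_offset_correct <- function(depth, window = 3 * 3600, quantile = 0.05) {
  stopifnot(nrow(depth) > 0, all(diff(as.numeric(depth$time)) > 0))
  tt <- as.numeric(depth$time)
  dt <- if (nrow(depth) > 1) median(diff(tt)) else 1
  if (window < 3 * dt) stop("zero-offset window shorter than 3 samples")
  blk <- floor((tt - tt[1]) / window)
  base_b <- tapply(depth$depth_m, blk, stats::quantile, probs = quantile,
                   names = FALSE)
  ctr_b <- tapply(tt, blk, function(z) mean(range(z)))
  base <- if (length(base_b) == 1L) rep(base_b, length(tt)) else
    approx(ctr_b, base_b, xout = tt, rule = 2)$y
  depth$depth_m <- pmax(0, depth$depth_m - base)
  depth
}

#' Detect dives in a (zero-offset-corrected) depth series
#'
#' A dive is a maximal contiguous run of samples at or below `threshold`
#' metres; excursions that never reach the threshold are discarded as
#' surface activity. Per-dive phase metrics are attached via
#' [dive_phases()]: bottom phase is the set of samples at >= 80% of the
#' dive's maximum depth, descent rate is maximum depth over time from dive
#' start to the first bottom sample, and vertical distance is twice the
#' maximum depth.
#'
#' @param depth data.frame with `time` (sorted) and `depth_m` columns;
#'   should already be zero-offset corrected.
#' @param threshold minimum dive depth, m (default 5).
#' @param daylight_window local clock hours `c(start, end)`; a dive is a
#'   daylight dive when its start falls inside the window.
#' @param utc_offset_h local clock offset from UTC in hours (only used when
#'   `time` is an absolute timestamp).
#' @return data.frame of dives: `start`, `end`, `duration`, `max_depth`,
#'   `bottom_time`, `descent_rate`, `vertical_distance`, `is_daylight`.
#' @export
detect_dives <- function(depth, threshold = 5, daylight_window = c(7, 18),
                         utc_offset_h = 0) {
  tt <- as.numeric(depth$time)
  if (is.unsorted(tt, strictly = TRUE)) stop("depth timestamps must be strictly increasing")
  dt <- if (length(tt) > 1) median(diff(tt)) else 1
  wet <- depth$depth_m >= threshold
  if (!any(wet)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), max_depth = numeric(0),
                      bottom_time = numeric(0), descent_rate = numeric(0),
                      vertical_distance = numeric(0), is_daylight = logical(0)))
  }
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- lapply(which(keep), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    ph <- if (i1 - i0 >= 2L) {
      dive_phases(tt[i0:i1], depth$depth_m[i0:i1], sample_interval = dt)
    } else {
      # 1-2 sample spike dive: the whole excursion is "bottom"
      md <- max(depth$depth_m[i0:i1])
      c(descent_rate = md / dt, bottom_time = tt[i1] - tt[i0] + dt,
        vertical_distance = 2 * md)
    }
    data.frame(start = tt[i0], end = tt[i1],
               duration = tt[i1] - tt[i0] + dt,
               max_depth = max(depth$depth_m[i0:i1]),
               bottom_time = ph[["bottom_time"]],
               descent_rate = ph[["descent_rate"]],
               vertical_distance = ph[["vertical_distance"]])
  })
  dv <- do.call(rbind, out)
  local_h <- (dv$start / 3600 + utc_offset_h) %% 24
  dv$is_daylight <- local_h >= daylight_window[1] & local_h < daylight_window[2]
  dv
}

#' Phase metrics for one dive
#'
#' @param time,depth numeric vectors of the dive's samples (>= 3 samples).
#' @param bottom_frac bottom phase = samples with depth >= `bottom_frac` x
#'   maximum depth (default 0.8).
#' @param sample_interval sampling interval in seconds; inferred from `time`
#'   when omitted.
#' @return named numeric vector: `descent_rate` (m/s), `bottom_time` (s),
#'   `vertical_distance` (m).
#' @export
dive_phases <- function(time, depth, bottom_frac = 0.8,
                        sample_interval = NULL) {
  if (length(time) < 3L) stop("a dive needs at least 3 samples")
  if (is.null(sample_interval)) sample_interval <- median(diff(time))
  maxd <- max(depth)
  bot <- which(depth >= bottom_frac * maxd)
  bottom_time <- time[bot[length(bot)]] - time[bot[1]] + sample_interval
  desc_t <- time[bot[1]] - time[1]
  descent_rate <- if (desc_t > 0) maxd / desc_t else maxd / sample_interval
  c(descent_rate = descent_rate, bottom_time = bottom_time,
    vertical_distance = 2 * maxd)
}

#' Per-trip dive behaviour summary
#'
#' @param dives data.frame of dives within one trip; must carry an
#'   `is_benthic` column (see [fit_benthic_split()]) and `is_daylight`.
#' @param trip_duration_h time at sea for the trip, hours.
#' @return one-row data.frame: `n_dives`, `prop_benthic`, `prop_daylight`,
#'   `dive_rate` (vertical metres per hour: sum of per-dive vertical
#'   distances over time at sea), `modal_depth` (mode of 1-m-binned maximum
#'   depths; ties go to the deeper bin).
#' @export
trip_dive_summary <- function(dives, trip_duration_h) {
  if (nrow(dives) == 0L) stop("a trip must contain at least one dive")
  stopifnot(trip_duration_h > 0, !is.null(dives$is_benthic))
  bins <- floor(dives$max_depth) # 1 m bins, label = lower edge
  tab <- table(bins)
  best <- max(tab)
  modal <- max(as.numeric(names(tab)[tab == best])) # tie -> deeper bin
  data.frame(
    n_dives = nrow(dives),
    prop_benthic = mean(dives$is_benthic),
    prop_daylight = mean(dives$is_daylight),
    dive_rate = sum(dives$vertical_distance) / trip_duration_h,
    modal_depth = modal + 0.5
  )
}
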