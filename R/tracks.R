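#' Forward speed filter for GPS fixes
#'
#' Single-pass McConnell-style filter: the first fix is always retained; each
#' subsequent fix is dropped when the great-circle speed implied from the
#' previous *retained* fix exceeds `vmax`.
#'
#' @param track data.frame with `time` (numeric seconds or POSIXct,
#'   increasing), `lon`, `lat`.
#' @param vmax maximum plausible travel speed, m/s (default 6).
#' @return the filtered track (same columns).
#' @export
speed_filter <- function(track, vmax = 6) {
  stopifnot(nrow(track) >= 2)
  tt <- as.numeric(track$time)
  keep <- logical(nrow(track))
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:nrow(track)) {
    d <- geosphere::distGeo(c(track$lon[last], track$lat[last]),
                            c(track$lon[i], track$lat[i]))
    dtm <- tt[i] - tt[last]
    if (dtm > 0 && d / dtm <= vmax) {
      keep[i] <- TRUE
      last <- i
    }
  }
  if (sum(keep) < 2) stop("speed filter removed almost every fix; corrupt track?")
  track[keep, , drop = FALSE]
}

#' Linear interpolation of a track at a fixed time step
#'
#' Interpolates linearly in a local azimuthal-equidistant frame centred on
#' `origin` and converts back to lon/lat, so interpolated points lie on the
#' projected straight segments between fixes. Original fix timestamps are
#' retained in the output.
#'
#' @param track speed-filtered track (`time`, `lon`, `lat`).
#' @param step interpolation interval, seconds (default 10).
#' @param origin projection centre `c(lon, lat)`, typically the colony.
#' @return data.frame `time`, `lon`, `lat`, `x`, `y` (projected km).
#' @export
interpolate_track <- function(track, step = 10, origin) {
  if (nrow(track) < 2) stop("cannot interpolate a single-fix track")
  tt <- as.numeric(track$time)
  xy <- project_aeq(track$lon, track$lat, origin)
  grid <- seq(tt[1], tt[length(tt)], by = step)
  tout <- sort(unique(c(grid, tt)))
  xi <- approx(tt, xy[, "x"], xout = tout)$y
  yi <- approx(tt, xy[, "y"], xout = tout)$y
  ll <- unproject_aeq(xi, yi, origin)
  data.frame(time = tout, lon = ll[, "lon"], lat = ll[, "lat"],
             x = xi, y = yi)
}

#' Flag fixes inside haul-out buffers and detect haul-out periods
#'
#' Any fix within `buffer_km` of a known haul-out site (the colony included)
#' is flagged `excluded`. Dry periods — runs of fixes with no depth record
#' deeper than 0.5 m and no appreciable movement — lasting at least
#' `min_dry` minutes are flagged `haulout`.
#'
#' @param track data.frame `time`, `lon`, `lat`.
#' @param sites data.frame with `lon`, `lat` of haul-out sites; must include
#'   the colony.
#' @param depth optional depth series (`time`, `depth_m`) used as the
#'   wet/dry proxy; without it only the spatial buffers are applied.
#' @param buffer_km exclusion buffer radius, km (default 1).
#' @param min_dry minimum haul-out duration, minutes (default 10).
#' @return the track with logical columns `excluded` and `haulout` added.
#' @export
exclude_haulouts <- function(track, sites, depth = NULL, buffer_km = 1,
                             min_dry = 10) {
  if (is.null(sites) || nrow(sites) == 0L) stop("haul-out site list is empty")
  tt <- as.numeric(track$time)
  excl <- rep(FALSE, nrow(track))
  for (k in seq_len(nrow(sites))) {
    excl <- excl | gc_dist_km(track$lon, track$lat,
                              c(sites$lon[k], sites$lat[k])) <= buffer_km
  }
  dry <- rep(FALSE, nrow(track))
  if (!is.null(depth) && nrow(depth)) {
    dtt <- as.numeric(depth$time)
    # a fix is wet when any depth sample within half a fix interval is > 0.5 m
    half <- if (nrow(track) > 1) median(diff(tt)) / 2 else 300
    wet_t <- dtt[depth$depth_m > 0.5]
    if (length(wet_t)) {
      nearest <- findInterval(tt, wet_t)
      dlo <- ifelse(nearest >= 1, tt - wet_t[pmax(nearest, 1)], Inf)
      dhi <- ifelse(nearest < length(wet_t),
                    wet_t[pmin(nearest + 1L, length(wet_t))] - tt, Inf)
      dry <- pmin(dlo, dhi) > half
    } else {
      dry <- rep(TRUE, nrow(track))
    }
  }
  haul <- rep(FALSE, nrow(track))
  if (any(dry)) {
    r <- rle(dry)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    for (k in which(r$values)) {
      if (tt[e[k]] - tt[s[k]] >= min_dry * 60) haul[s[k]:e[k]] <- TRUE
    }
  }
  track$excluded <- excl
  track$haulout <- haul
  track
}

#' Segment a track into foraging trips
#'
#' Candidate at-sea bouts are maximal runs of fixes outside every haul-out /
#' colony buffer and not flagged as hauled out. A bout becomes a foraging
#' trip when its in-water duration (bout span minus interior haul-out time)
#' is at least `min_hours` and it contains at least one detected dive. Trip
#' fixes are interpolated at `interp_step` seconds and each dive is joined
#' to its nearest-in-time interpolated fix.
#'
#' @param track output of [exclude_haulouts()] (needs `excluded`,`haulout`).
#' @param dives data.frame of dives from [detect_dives()] for the same
#'   individual.
#' @param colony `c(lon, lat)`; also the projection origin.
#' @param min_hours minimum trip duration, hours (default 6).
#' @param interp_step interpolation step for trip fixes, seconds (default 10).
#' @return list of trips; each trip is a list with `start`, `end`,
#'   `duration_h` (in-water hours), `fixes` (interpolated data.frame) and
#'   `dives` (with joined `lon`, `lat`, `x`, `y`).
#' @export
segment_trips <- function(track, dives, colony, min_hours = 6,
                          interp_step = 10, buffer_km = 1) {
  stopifnot(!is.null(track$excluded), !is.null(track$haulout))
  tt <- as.numeric(track$time)
  atsea <- !track$excluded & !track$haulout
  counts <- c(bouts = 0L, dropped_short = 0L, dropped_no_dive = 0L,
              merged = 0L)
  if (!any(atsea)) return(structure(list(), counts = counts))
  r <- rle(atsea)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  trips <- list()
  for (k in which(r$values)) {
    i0 <- s[k]; i1 <- e[k]
    counts["bouts"] <- counts["bouts"] + 1L
    if (i1 - i0 < 1L) { counts["dropped_short"] <- counts["dropped_short"] + 1L; next }
    span_h <- (tt[i1] - tt[i0]) / 3600
    # interior haul-out time has already split the run; bouts interrupted by
    # a haul-out are merged back when the gap is a flagged haul-out (trip
    # continues after resting) rather than colony attendance
    seg <- track[i0:i1, , drop = FALSE]
    if (span_h < min_hours) { counts["dropped_short"] <- counts["dropped_short"] + 1L; next }
    dv <- dives[dives$start >= tt[i0] & dives$start <= tt[i1], , drop = FALSE]
    if (nrow(dv) == 0L) { counts["dropped_no_dive"] <- counts["dropped_no_dive"] + 1L; next }
    fixes <- interpolate_track(seg, step = interp_step, origin = colony)
    idx <- vapply(dv$start, function(ts) which.min(abs(fixes$time - ts)), 1L)
    dv$lon <- fixes$lon[idx]; dv$lat <- fixes$lat[idx]
    dv$x <- fixes$x[idx]; dv$y <- fixes$y[idx]
    trips[[length(trips) + 1L]] <- list(
      start = tt[i0], end = tt[i1], duration_h = span_h,
      fixes = fixes, dives = dv
    )
  }
  # merge bouts separated only by haul-out periods: the trip is one colony-
  # to-colony excursion and its duration excludes the haul-out time
  if (length(trips) > 1L) {
    merged <- list(trips[[1L]])
    for (k in 2:length(trips)) {
      prev <- merged[[length(merged)]]
      gap_idx <- tt > prev$end & tt < trips[[k]]$start
      at_colony <- gc_dist_km(track$lon[gap_idx], track$lat[gap_idx],
                              colony) <= buffer_km
      gap_is_haulout <- any(gap_idx) && !any(at_colony) &&
        all(track$haulout[gap_idx] | track$excluded[gap_idx]) &&
        any(track$haulout[gap_idx])
      if (gap_is_haulout) {
        counts["merged"] <- counts["merged"] + 1L
        prev$end <- trips[[k]]$end
        prev$duration_h <- prev$duration_h + trips[[k]]$duration_h
        prev$fixes <- rbind(prev$fixes, trips[[k]]$fixes)
        prev$dives <- rbind(prev$dives, trips[[k]]$dives)
        merged[[length(merged)]] <- prev
      } else {
        merged[[length(merged) + 1L]] <- trips[[k]]
      }
    }
    trips <- merged
  }
  out <- trips[vapply(trips, function(tr) tr$duration_h >= min_hours,
                      logical(1))]
  structure(out, counts = counts)
}

#' Spatial metrics of one foraging trip
#'
#' @param trip a trip list from [segment_trips()].
#' @param colony `c(lon, lat)`.
#' @return one-row data.frame: `total_distance` (horizontal path length plus
#'   summed dive vertical distances, km), `horizontal_distance` (km),
#'   `max_range` (km, great-circle), `bearing_distal` (degrees clockwise
#'   from true north to the most distal fix, in \[0, 360)).
#' @export
trip_spatial_metrics <- function(trip, colony) {
  fx <- trip$fixes
  rng <- gc_dist_km(fx$lon, fx$lat, colony)
  i_max <- which.max(rng)
  horiz <- path_length_km(fx$lon, fx$lat)
  vert_km <- if (nrow(trip$dives)) sum(trip$dives$vertical_distance) / 1000 else 0
  data.frame(
    total_distance = horiz + vert_km,
    horizontal_distance = horiz,
    max_range = rng[i_max],
    bearing_distal = gc_bearing(fx$lon[i_max], fx$lat[i_max], colony)
  )
}
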