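# Shared fixture builders. Everything is generated in code; seeds are fixed
# per test at the call site.

# Small, fast population: few individuals, short trips.
small_sim_config <- function(n_individuals = 4, trips = 3, seed = 7, ...) {
  sim_config(
    n_individuals = n_individuals,
    trips_per_individual = trips,
    trip_duration_meanlog = log(18),
    trip_duration_range_h = c(12, 30),
    seed = seed,
    ...
  )
}

# Sampled trapezoid dive profile appended to a surface trace.
# Returns data.frame(time, depth_m) sampled at `dt` seconds.
trapezoid_trace <- function(max_depth = 50, descent_s = 40, bottom_s = 80,
                            ascent_s = 40, dt = 5, lead_s = 60, tail_s = 60,
                            t0 = 0) {
  tt <- seq(t0, t0 + lead_s + descent_s + bottom_s + ascent_s + tail_s,
            by = dt)
  rel <- tt - t0 - lead_s
  depth <- numeric(length(tt))
  i <- rel > 0 & rel <= descent_s
  depth[i] <- max_depth * rel[i] / descent_s
  i <- rel > descent_s & rel <= descent_s + bottom_s
  depth[i] <- max_depth
  i <- rel > descent_s + bottom_s & rel < descent_s + bottom_s + ascent_s
  depth[i] <- max_depth * (descent_s + bottom_s + ascent_s - rel[i]) / ascent_s
  data.frame(time = tt, depth_m = depth)
}

# Independent brute-force dive scanner: marks maximal runs of depth >=
# threshold and reports start/end times and max depth, nothing shared with
# detect_dives() internals.
brute_force_dives <- function(trace, threshold = 5) {
  idx <- which(trace$depth_m >= threshold)
  if (!length(idx)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      max_depth = numeric(0)))
  }
  grp <- cumsum(c(1, diff(idx) > 1))
  do.call(rbind, lapply(split(idx, grp), function(ii) {
    data.frame(start = trace$time[ii[1]], end = trace$time[ii[length(ii)]],
               max_depth = max(trace$depth_m[ii]))
  }))
}

# Random wiggly depth trace for property tests.
random_trace <- function(n = 500, dt = 5) {
  depth <- pmax(0, stats::filter(rnorm(n, 2, 8), rep(1, 5), sides = 1,
                                 circular = TRUE))
  data.frame(time = seq(0, by = dt, length.out = n),
             depth_m = as.numeric(depth))
}

# Straight-line GPS track at constant speed (m/s) along a bearing.
straight_track <- function(n = 20, speed = 2, bearing = 90, dt = 600,
                           origin = c(lon = 146.3, lat = -39.17)) {
  d <- (seq_len(n) - 1) * speed * dt
  p <- geosphere::destPoint(rbind(origin), bearing, d)
  data.frame(time = (seq_len(n) - 1) * dt, lon = p[, 1], lat = p[, 2])
}

# Normalized random discrete UD on a small grid (for Bhattacharyya oracles).
random_ud <- function(ncell = 30, extent = 10) {
  ij <- unique(data.frame(ix = sample(-extent:extent, ncell, TRUE),
                          iy = sample(-extent:extent, ncell, TRUE)))
  p <- runif(nrow(ij))
  ij$p <- p / sum(p)
  ij
}

# Balanced Gaussian one-way data with true repeatability R.
gaussian_rpt_data <- function(R, n_ind = 50, n_trip = 8) {
  id <- gl(n_ind, n_trip, labels = sprintf("I%02d", seq_len(n_ind)))
  y <- rep(rnorm(n_ind, 0, sqrt(R)), each = n_trip) +
    rnorm(n_ind * n_trip, 0, sqrt(1 - R))
  data.frame(individual_id = id, y = y)
}
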