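#' Configuration for the synthetic biologging generator
#'
#' Builds the parameter set for [simulate_population()]. Defaults emulate a
#' colony of lactating adult female fur seals making multi-day, benthic-
#' dominated foraging trips over a 60--70 m continental shelf: ~34
#' individuals with 3--12 trips each, trips of roughly 2--11 days, GPS fixes
#' every 10 min, depth sampled every 5 s, and ~75% of dives reaching the
#' seafloor.
#'
#' Individual heterogeneity is injected through latent per-individual means
#' for trip bearing (degrees), log trip duration and logit benthic
#' propensity, drawn with between-individual variance `sigma_alpha2` and
#' per-trip deviations with within-individual variance `sigma_eps2` (each a
#' named vector over `bearing`, `log_duration`, `logit_benthic`, on the
#' behaviour's modelling scale: deg^2, log-hours^2, logit^2). The implied
#' intraclass correlation `sigma_alpha2 / (sigma_alpha2 + sigma_eps2)` is the
#' simulation truth that downstream repeatability estimators must recover.
#'
#' @param n_individuals number of simulated individuals.
#' @param trips_per_individual integer count, or length-2 range sampled
#'   uniformly per individual. Must allow at least 3 trips.
#' @param gps_interval GPS sampling interval, seconds.
#' @param depth_interval depth sampling interval, seconds (1 or 5).
#' @param colony `c(lon, lat)` of the breeding colony (degrees).
#' @param utc_offset_h local clock offset from UTC, hours (used by the
#'   daylight window).
#' @param daylight_window local clock hours `c(start, end)` defining daylight.
#' @param bathymetry function of projected `(x, y)` km returning seafloor
#'   depth in m; the default is a smooth 60--70 m shelf.
#' @param bearing_mean population mean trip bearing, degrees from north.
#' @param sigma_alpha2,sigma_eps2 named numeric vectors of between- and
#'   within-individual variances for `bearing`, `log_duration`,
#'   `logit_benthic`.
#' @param trip_duration_meanlog mean of log trip duration (hours).
#' @param trip_duration_range_h trip durations clamped to this range (hours).
#' @param benthic_propensity_mean population mean probability that a dive is
#'   benthic.
#' @param dive_duration_mean_s,dive_duration_sd_s dive duration distribution.
#' @param surface_gap_meanlog,surface_gap_sdlog log-normal post-dive surface
#'   interval (median `exp(meanlog)` seconds).
#' @param travel_speed_ms mean transit speed, m/s; realised speeds are capped
#'   at `speed_cap_ms` so clean tracks pass a 6 m/s filter untouched.
#' @param speed_cap_ms hard speed cap, m/s.
#' @param ars_speed_ms movement speed during area-restricted search, m/s.
#' @param patch_jitter_km SD of trip-to-trip jitter of the foraging patch
#'   around the individual's habitual patch axis; controls site fidelity.
#' @param transit_diving logical; when `FALSE`, dives occur only during the
#'   area-restricted-search phase at the distal patch rather than
#'   throughout the trip (useful for scenarios requiring spatially compact
#'   dive clusters).
#' @param gps_error_km SD of isotropic GPS measurement noise, km.
#' @param attendance_mean_h mean colony attendance between trips, hours.
#' @param haulout_sites optional data.frame `lon, lat` of haul-out sites away
#'   from the colony.
#' @param haulout_prob per-trip probability of a haul-out visit on the return
#'   leg (requires `haulout_sites`).
#' @param haulout_duration_h range of haul-out visit durations, hours.
#' @param start_utc POSIXct deployment start.
#' @param seed integer RNG seed; fixing it fixes every output byte.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 34L,
                       trips_per_individual = c(3L, 12L),
                       gps_interval = 600,
                       depth_interval = 5,
                       colony = c(lon = 146.30, lat = -39.17),
                       utc_offset_h = 10,
                       daylight_window = c(7, 18),
                       bathymetry = NULL,
                       bearing_mean = 203.5,
                       sigma_alpha2 = c(bearing = 1225, log_duration = 0.14,
                                        logit_benthic = 1.2),
                       sigma_eps2 = c(bearing = 625, log_duration = 0.06,
                                      logit_benthic = 0.30),
                       trip_duration_meanlog = log(95),
                       trip_duration_range_h = c(48, 264),
                       benthic_propensity_mean = 0.75,
                       dive_duration_mean_s = 155,
                       dive_duration_sd_s = 35,
                       surface_gap_meanlog = log(90),
                       surface_gap_sdlog = 0.6,
                       travel_speed_ms = 0.8,
                       speed_cap_ms = 2,
                       ars_speed_ms = 0.25,
                       patch_jitter_km = 3,
                       transit_diving = TRUE,
                       gps_error_km = 0.03,
                       attendance_mean_h = 20,
                       haulout_sites = NULL,
                       haulout_prob = 0,
                       haulout_duration_h = c(1, 3),
                       start_utc = as.POSIXct("2015-06-01 00:00:00", tz = "UTC"),
                       seed = 1L) {
  if (is.null(bathymetry)) {
    bathymetry <- function(x, y) 65 + 3 * sin(x / 15) + 2 * cos(y / 19)
  }
  need <- c("bearing", "log_duration", "logit_benthic")
  stopifnot(
    n_individuals >= 0,
    gps_interval > 0, depth_interval > 0,
    all(need %in% names(sigma_alpha2)), all(need %in% names(sigma_eps2)),
    all(sigma_alpha2 >= 0), all(sigma_eps2 >= 0),
    benthic_propensity_mean >= 0, benthic_propensity_mean <= 1,
    haulout_prob >= 0, haulout_prob <= 1,
    is.function(bathymetry)
  )
  if (max(trips_per_individual) < 3) {
    stop("each individual must be able to complete at least 3 trips")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Wrap degrees into [0, 360).
wrap_deg <- function(x) x %% 360

# Logit-scale intercept whose logistic-normal mixture has mean `p` when the
# latent variance is `v` (undoes the Jensen shrinkage of plogis).
logit_intercept_for_mean <- function(p, v) {
  if (v <= 0) return(qlogis(p))
  f <- function(b) {
    stats::integrate(function(z) plogis(b + sqrt(v) * z) * stats::dnorm(z),
                     -8, 8)$value - p
  }
  stats::uniroot(f, c(qlogis(p) - 6, qlogis(p) + 6))$root
}

# Two-factor morphometrics model near published colony means: a girth/mass
# size factor and a length factor (r = 0.5 between them). Mass and standard
# length load on the same factors as axillary girth and axis length strongly
# enough (0.9 x 0.85) that the |r| > 0.7 collinearity screen removes them.
sim_morphometrics <- function(ids) {
  n <- length(ids)
  f1 <- rnorm(n)
  f2 <- 0.5 * f1 + sqrt(0.75) * rnorm(n)
  load <- function(f, lambda) lambda * f + sqrt(1 - lambda^2) * rnorm(n)
  data.frame(
    individual_id = ids,
    mass_kg = 70.4 + 4.1 * load(f1, 0.90),
    standard_length_cm = 151.4 + 2.9 * load(f2, 0.90),
    flipper_length_cm = 42.5 + 0.6 * (0.3 * f1 + 0.3 * f2 + sqrt(0.73) * rnorm(n)),
    axis_length_cm = 63.2 + 1.7 * load(f2, 0.85),
    axillary_girth_cm = 99.2 + 2.3 * load(f1, 0.85),
    stringsAsFactors = FALSE
  )
}

# Piecewise-linear trapezoid dive profile evaluated at offsets `tt` (s) into
# a dive of duration `dur` reaching `maxd` m. `fr` = c(descent, bottom,
# ascent) phase fractions.
trapezoid_depth <- function(tt, dur, maxd, fr) {
  u <- tt / dur
  d <- numeric(length(u))
  i1 <- u < fr[1]
  i2 <- u >= fr[1] & u < fr[1] + fr[2]
  i3 <- u >= fr[1] + fr[2]
  d[i1] <- maxd * u[i1] / fr[1]
  d[i2] <- maxd
  d[i3] <- maxd * pmax(0, 1 - u[i3]) / fr[3]
  d
}

# One trip's GPS path in projected km: correlated-random-walk outbound leg
# along `bearing_deg`, area-restricted loop at the distal patch, straight
# return (with optional haul-out stop), Brownian-bridge wiggle on the return.
# Returns list(t = seconds into trip, x, y, dry = logical haul-out flag,
# patch = c(x, y), haulout_span = c(t0, t1) or NULL).
sim_trip_path <- function(dur_s, bearing_deg, cfg, haulout_xy = NULL) {
  dt <- cfg$gps_interval
  tt <- seq(0, dur_s, by = dt)
  n <- length(tt)
  n_out <- max(2L, floor(0.35 * n))
  n_ars <- max(2L, floor(0.30 * n))
  n_ret <- n - n_out - n_ars
  if (n_ret < 2L) n_ret <- 2L

  # outbound CRW: heading = bearing + integrated wrapped-normal turning noise
  head_rad <- (bearing_deg + cumsum(rnorm(n_out, 0, 4))) * pi / 180
  spd <- pmin(cfg$speed_cap_ms, rlnorm(n_out, log(cfg$travel_speed_ms), 0.15))
  step <- spd * dt / 1000
  x_out <- cumsum(step * sin(head_rad))
  y_out <- cumsum(step * cos(head_rad))

  # area-restricted search: slow isotropic random walk around the patch
  px <- x_out[n_out]; py <- y_out[n_out]
  ang <- runif(n_ars, 0, 2 * pi)
  s_ars <- cfg$ars_speed_ms * dt / 1000
  x_ars <- px + cumsum(s_ars * cos(ang))
  y_ars <- py + cumsum(s_ars * sin(ang))

  # return: straight to the colony (via a haul-out if drawn), bridge noise
  rx <- x_ars[n_ars]; ry <- y_ars[n_ars]
  dry <- rep(FALSE, n)
  haulout_span <- NULL
  if (!is.null(haulout_xy)) {
    n_stop <- max(2L, round(runif(1, cfg$haulout_duration_h[1],
                                  cfg$haulout_duration_h[2]) * 3600 / dt))
    n_leg1 <- max(2L, floor((n_ret - n_stop) / 2))
    n_leg2 <- n_ret - n_stop - n_leg1
    if (n_leg2 < 2L) { n_leg2 <- 2L; n_stop <- n_ret - n_leg1 - n_leg2 }
    x_ret <- c(seq(rx, haulout_xy[1], length.out = n_leg1),
               rep(haulout_xy[1], n_stop) + rnorm(n_stop, 0, 0.02),
               seq(haulout_xy[1], 0, length.out = n_leg2))
    y_ret <- c(seq(ry, haulout_xy[2], length.out = n_leg1),
               rep(haulout_xy[2], n_stop) + rnorm(n_stop, 0, 0.02),
               seq(haulout_xy[2], 0, length.out = n_leg2))
    i0 <- n_out + n_ars + n_leg1
    dry[(i0 + 1):(i0 + n_stop)] <- TRUE
    haulout_span <- c(tt[i0 + 1], tt[i0 + n_stop])
  } else {
    x_ret <- seq(rx, 0, length.out = n_ret)
    y_ret <- seq(ry, 0, length.out = n_ret)
    bb <- function(m) { # Brownian bridge, zero at both ends
      w <- cumsum(rnorm(m, 0, 0.4))
      w - seq_along(w) / m * w[m]
    }
    x_ret <- x_ret + bb(n_ret)
    y_ret <- y_ret + bb(n_ret)
  }
  x <- c(x_out, x_ars, x_ret)[seq_len(n)]
  y <- c(y_out, y_ars, y_ret)[seq_len(n)]
  x[n] <- 0; y[n] <- 0
  list(t = tt, x = x, y = y, dry = dry, patch = c(px, py),
       haulout_span = haulout_span)
}

# Dive sequence for one trip: start offsets, durations, benthic labels,
# max depths and locations (seafloor looked up at the dive's along-track
# position). Dives pause during haul-out spans and near the colony.
sim_trip_dives <- function(path, dur_s, p_benthic, cfg) {
  starts <- durs <- maxd <- dx <- dy <- numeric(0)
  benthic <- logical(0)
  if (isTRUE(cfg$transit_diving)) {
    t <- 0.03 * dur_s; t_stop <- 0.97 * dur_s
  } else {
    t <- 0.36 * dur_s; t_stop <- 0.64 * dur_s
  }
  while (t < t_stop) {
    d <- min(400, max(60, rnorm(1, cfg$dive_duration_mean_s,
                                cfg$dive_duration_sd_s)))
    gap <- min(1200, max(20, rlnorm(1, cfg$surface_gap_meanlog,
                                    cfg$surface_gap_sdlog)))
    mid <- t + d / 2
    in_haulout <- !is.null(path$haulout_span) &&
      mid >= path$haulout_span[1] - 600 && mid <= path$haulout_span[2] + 600
    if (!in_haulout && t + d < t_stop) {
      xx <- approx(path$t, path$x, xout = mid, rule = 2)$y
      yy <- approx(path$t, path$y, xout = mid, rule = 2)$y
      if (sqrt(xx^2 + yy^2) > 1.2) { # no dives inside the colony buffer
        sf <- cfg$bathymetry(xx, yy)
        b <- runif(1) < p_benthic
        md <- if (b) sf else runif(1, 0.3, 0.7) * sf
        starts <- c(starts, t); durs <- c(durs, d)
        benthic <- c(benthic, b); maxd <- c(maxd, md)
        dx <- c(dx, xx); dy <- c(dy, yy)
      }
    }
    t <- t + d + gap
  }
  data.frame(start_s = starts, duration_s = durs, is_benthic = benthic,
             max_depth = maxd, x = dx, y = dy)
}

# Depth trace for one trip at cfg$depth_interval: 0 m at the surface,
# trapezoid profiles during dives (benthic bottom fraction 0.5, pelagic 0.15).
sim_trip_depth <- function(dives, dur_s, cfg) {
  dt <- cfg$depth_interval
  tt <- seq(0, dur_s, by = dt)
  depth <- numeric(length(tt))
  if (nrow(dives)) {
    for (k in seq_len(nrow(dives))) {
      fr <- if (dives$is_benthic[k]) c(0.25, 0.5, 0.25) else c(0.425, 0.15, 0.425)
      i0 <- ceiling(dives$start_s[k] / dt) + 1L
      i1 <- min(length(tt), floor((dives$start_s[k] + dives$duration_s[k]) / dt) + 1L)
      if (i1 >= i0) {
        depth[i0:i1] <- trapezoid_depth(tt[i0:i1] - dives$start_s[k],
                                        dives$duration_s[k],
                                        dives$max_depth[k], fr)
      }
    }
  }
  data.frame(t = tt, depth = depth)
}

#' Simulate a population of central-place foragers with known ground truth
#'
#' Generates GPS tracks (10-min fixes with measurement noise), depth series
#' (1 or 5 s trapezoid dive profiles over a 60--70 m shelf), morphometrics
#' near published colony means, and a `truth` record holding every latent
#' quantity downstream stages are supposed to recover: per-individual mean
#' bearing / log trip duration / logit benthic propensity, per-dive benthic
#' labels, per-trip boundaries and patch locations, and the realised
#' intraclass correlation of each behaviour obtained by direct variance
#' decomposition of the simulated draws.
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_population` with elements `gps`, `depth`
#'   (data.frames over all individuals), `morphometrics`, `truth` (list:
#'   `individuals`, `trips`, `dives`, `realized_r`), and `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  ids <- sprintf("ID%02d", seq_len(n))

  morpho <- sim_morphometrics(ids)

  # latent per-individual means
  sa <- cfg$sigma_alpha2; se <- cfg$sigma_eps2
  mu_bear <- wrap_deg(cfg$bearing_mean + rnorm(n, 0, sqrt(sa[["bearing"]])))
  mu_ldur <- cfg$trip_duration_meanlog + rnorm(n, 0, sqrt(sa[["log_duration"]]))
  lben0 <- logit_intercept_for_mean(
    cfg$benthic_propensity_mean,
    sa[["logit_benthic"]] + se[["logit_benthic"]])
  mu_lben <- lben0 + rnorm(n, 0, sqrt(sa[["logit_benthic"]]))

  ntrips <- if (length(cfg$trips_per_individual) == 1L) {
    rep(as.integer(cfg$trips_per_individual), n)
  } else {
    sample(seq(cfg$trips_per_individual[1], cfg$trips_per_individual[2]),
           n, replace = TRUE)
  }

  gps_l <- list(); depth_l <- list(); trips_l <- list(); dives_l <- list()
  dev_bear <- dev_ldur <- dev_lben <- numeric(0)
  dev_id <- character(0)
  t0_num <- as.numeric(cfg$start_utc)

  for (i in seq_len(n)) {
    clock <- t0_num + runif(1, 0, 6 * 3600) # stagger deployments
    for (j in seq_len(ntrips[i])) {
      eb <- rnorm(1, 0, sqrt(se[["bearing"]]))
      ed <- rnorm(1, 0, sqrt(se[["log_duration"]]))
      ep <- rnorm(1, 0, sqrt(se[["logit_benthic"]]))
      dev_bear <- c(dev_bear, eb); dev_ldur <- c(dev_ldur, ed)
      dev_lben <- c(dev_lben, ep); dev_id <- c(dev_id, ids[i])

      dur_h <- min(cfg$trip_duration_range_h[2],
                   max(cfg$trip_duration_range_h[1], exp(mu_ldur[i] + ed)))
      dur_s <- round(dur_h * 3600)
      bearing <- wrap_deg(mu_bear[i] + eb)
      p_ben <- plogis(mu_lben[i] + ep)

      ho_xy <- NULL
      if (!is.null(cfg$haulout_sites) && runif(1) < cfg$haulout_prob) {
        k <- sample(nrow(cfg$haulout_sites), 1)
        ho_xy <- as.numeric(project_aeq(cfg$haulout_sites$lon[k],
                                        cfg$haulout_sites$lat[k], cfg$colony))
      }
      path <- sim_trip_path(dur_s, bearing, cfg, ho_xy)
      dv <- sim_trip_dives(path, dur_s, p_ben, cfg)
      dp <- sim_trip_depth(dv, dur_s, cfg)

      # colony attendance before the trip: fixes at the colony, dry sensor
      att_s <- round(max(2, rlnorm(1, log(cfg$attendance_mean_h), 0.3)) * 3600)
      att_t <- seq(0, att_s, by = cfg$gps_interval)
      trip_start <- clock + att_s + cfg$gps_interval

      ll_att <- unproject_aeq(rnorm(length(att_t), 0, 0.05),
                              rnorm(length(att_t), 0, 0.05), cfg$colony)
      ll_trip <- unproject_aeq(path$x + rnorm(length(path$x), 0, cfg$gps_error_km),
                               path$y + rnorm(length(path$y), 0, cfg$gps_error_km),
                               cfg$colony)
      gps_l[[length(gps_l) + 1L]] <- data.frame(
        individual_id = ids[i],
        time = c(clock + att_t, trip_start + path$t),
        lon = c(ll_att[, "lon"], ll_trip[, "lon"]),
        lat = c(ll_att[, "lat"], ll_trip[, "lat"]),
        stringsAsFactors = FALSE
      )
      att_td <- seq(0, att_s, by = cfg$depth_interval)
      depth_l[[length(depth_l) + 1L]] <- data.frame(
        individual_id = ids[i],
        time = c(clock + att_td, trip_start + dp$t),
        depth_m = c(numeric(length(att_td)), dp$depth),
        stringsAsFactors = FALSE
      )
      patch_ll <- unproject_aeq(path$patch[1], path$patch[2], cfg$colony)
      trips_l[[length(trips_l) + 1L]] <- data.frame(
        individual_id = ids[i], trip = j,
        start = trip_start, end = trip_start + dur_s,
        duration_true_h = dur_s / 3600,
        bearing_true = bearing,
        benthic_propensity = p_ben,
        patch_x = path$patch[1], patch_y = path$patch[2],
        patch_lon = patch_ll[1, "lon"], patch_lat = patch_ll[1, "lat"],
        seafloor_patch = cfg$bathymetry(path$patch[1], path$patch[2]),
        had_haulout = !is.null(ho_xy),
        stringsAsFactors = FALSE
      )
      if (nrow(dv)) {
        dives_l[[length(dives_l) + 1L]] <- data.frame(
          individual_id = ids[i], trip = j,
          start = trip_start + dv$start_s,
          duration_s = dv$duration_s,
          max_depth = dv$max_depth,
          is_benthic = dv$is_benthic,
          x = dv$x, y = dv$y,
          stringsAsFactors = FALSE
        )
      }
      clock <- trip_start + dur_s + max(cfg$gps_interval, cfg$depth_interval)
    }
  }

  realized_r <- function(mu, dev) {
    # between = variance of drawn individual means, within = variance of
    # the per-trip deviations actually used
    vb <- if (length(mu) > 1) var(mu) else 0
    vw <- if (length(dev) > 1) var(dev) else 0
    if (vb + vw == 0) return(NA_real_)
    vb / (vb + vw)
  }
  truth <- list(
    individuals = data.frame(
      individual_id = ids, bearing_mu = mu_bear, log_duration_mu = mu_ldur,
      logit_benthic_mu = mu_lben, n_trips = ntrips, stringsAsFactors = FALSE
    ),
    trips = do.call(rbind, trips_l),
    dives = do.call(rbind, dives_l),
    realized_r = data.frame(
      behavior = c("bearing", "log_duration", "logit_benthic"),
      r = c(realized_r(mu_bear, dev_bear),
            realized_r(mu_ldur, dev_ldur),
            realized_r(mu_lben, dev_lben)),
      stringsAsFactors = FALSE
    )
  )
  out <- list(
    gps = if (length(gps_l)) do.call(rbind, gps_l) else
      data.frame(individual_id = character(0), time = numeric(0),
                 lon = numeric(0), lat = numeric(0)),
    depth = if (length(depth_l)) do.call(rbind, depth_l) else
      data.frame(individual_id = character(0), time = numeric(0),
                 depth_m = numeric(0)),
    morphometrics = morpho,
    truth = truth,
    config = cfg
  )
  class(out) <- "sim_population"
  out
}

iso8601 <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Write a simulated population to CSV fixtures
#'
#' One `gps_<id>.csv` and `depth_<id>.csv` per individual, plus
#' `morphometrics.csv` and `truth_*.csv` tables. Timestamps are written as
#' ISO-8601 UTC and round-trip losslessly through [read_gps()] /
#' [read_depth()].
#'
#' @param sim a `sim_population` from [simulate_population()].
#' @param dir output directory (created if missing).
#' @return invisibly, the character vector of files written.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(d, f) {
    p <- file.path(dir, f)
    write.csv(d, p, row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }
  for (id in unique(sim$gps$individual_id)) {
    g <- sim$gps[sim$gps$individual_id == id, ]
    wr(data.frame(individual_id = g$individual_id,
                  timestamp = iso8601(g$time), lon = g$lon, lat = g$lat),
       sprintf("gps_%s.csv", id))
    d <- sim$depth[sim$depth$individual_id == id, ]
    wr(data.frame(individual_id = d$individual_id,
                  timestamp = iso8601(d$time), depth_m = d$depth_m),
       sprintf("depth_%s.csv", id))
  }
  wr(sim$morphometrics, "morphometrics.csv")
  tr <- sim$truth$trips
  if (!is.null(tr) && nrow(tr)) {
    tr$start <- iso8601(tr$start); tr$end <- iso8601(tr$end)
  }
  dv <- sim$truth$dives
  if (!is.null(dv) && nrow(dv)) dv$start <- iso8601(dv$start)
  wr(sim$truth$individuals, "truth_individuals.csv")
  if (!is.null(tr)) wr(tr, "truth_trips.csv")
  if (!is.null(dv)) wr(dv, "truth_dives.csv")
  wr(sim$truth$realized_r, "truth_realized_r.csv")
  invisible(files)
}
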