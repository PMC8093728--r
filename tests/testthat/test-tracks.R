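origin <- c(lon = 146.3, lat = -39.17)

test_that("projection round-trips and preserves range/bearing", {
  set.seed(4)
  lon <- origin[1] + runif(20, -1, 1)
  lat <- origin[2] + runif(20, -1, 1)
  xy <- project_aeq(lon, lat, origin)
  ll <- unproject_aeq(xy[, "x"], xy[, "y"], origin)
  expect_equal(unname(ll[, "lon"]), lon, tolerance = 1e-9)
  expect_equal(unname(ll[, "lat"]), lat, tolerance = 1e-9)
  expect_equal(sqrt(rowSums(xy^2)), gc_dist_km(lon, lat, origin),
               tolerance = 1e-9)
})

test_that("a clean constant-speed track passes the speed filter untouched", {
  tr <- straight_track(n = 20, speed = 2)
  expect_equal(speed_filter(tr, vmax = 6), tr)
})

test_that("a teleporting fix is removed and later fixes kept", {
  tr <- straight_track(n = 10, speed = 2)
  bad <- tr
  jump <- geosphere::destPoint(c(bad$lon[5], bad$lat[5]), 0, 50 * 600)
  bad$lon[5] <- jump[1]; bad$lat[5] <- jump[2]
  got <- speed_filter(bad, vmax = 6)
  # forward-scan oracle
  keep <- rep(TRUE, 10); last <- 1
  for (i in 2:10) {
    v <- geosphere::distGeo(c(bad$lon[last], bad$lat[last]),
                            c(bad$lon[i], bad$lat[i])) /
      (bad$time[i] - bad$time[last])
    if (v > 6) keep[i] <- FALSE else last <- i
  }
  expect_equal(got, bad[keep, ])
  expect_false(5 %in% as.integer(rownames(got)))
})

test_that("repeated positions (zero speed) are retained", {
  tr <- straight_track(n = 5, speed = 0)
  expect_equal(nrow(speed_filter(tr, vmax = 6)), 5)
})

test_that("interpolation produces the exact 10 s grid with originals preserved", {
  tr <- straight_track(n = 2, speed = 2, dt = 600)
  it <- interpolate_track(tr, step = 10, origin = origin)
  expect_equal(nrow(it), 61)
  expect_equal(it$time, seq(0, 600, 10))
  # midpoint lies at the midpoint of the projected segment
  xy <- project_aeq(tr$lon, tr$lat, origin)
  mid <- it[it$time == 300, ]
  expect_equal(mid$x, mean(xy[, "x"]), tolerance = 1e-9)
  expect_equal(mid$y, mean(xy[, "y"]), tolerance = 1e-9)
})

test_that("interpolated path length matches the original polyline", {
  set.seed(9)
  tr <- straight_track(n = 30, speed = 1.5, bearing = 210)
  tr$lon <- tr$lon + rnorm(30, 0, 0.01)
  it <- interpolate_track(tr, step = 10, origin = origin)
  len_orig <- sum(geosphere::distGeo(cbind(tr$lon[-30], tr$lat[-30]),
                                     cbind(tr$lon[-1], tr$lat[-1])))
  len_int <- sum(geosphere::distGeo(cbind(it$lon[-nrow(it)], it$lat[-nrow(it)]),
                                    cbind(it$lon[-1], it$lat[-1])))
  expect_equal(len_int / len_orig, 1, tolerance = 1e-3)
  expect_error(interpolate_track(tr[1, ], origin = origin), "single-fix")
})

test_that("haul-out buffers exclude nearby fixes and flag long dry periods", {
  site <- data.frame(lon = origin[1] + 0.3, lat = origin[2])
  near <- geosphere::destPoint(rbind(unname(site)), 90, 500)    # 0.5 km
  far <- geosphere::destPoint(rbind(unname(site)), 90, 1500)    # 1.5 km
  tr <- data.frame(time = c(0, 600, 1200),
                   lon = c(near[1], far[1], origin[1] + 0.5),
                   lat = c(near[2], far[2], origin[2]))
  got <- exclude_haulouts(tr, sites = site, buffer_km = 1)
  expect_equal(got$excluded, c(TRUE, FALSE, FALSE))

  # 15 min stationary + dry at the site -> haul-out event
  tr2 <- data.frame(time = seq(0, 1500, 300),
                    lon = rep(site$lon, 6), lat = rep(site$lat, 6))
  dep <- data.frame(time = seq(0, 1500, 5), depth_m = 0)
  got2 <- exclude_haulouts(tr2, sites = site, depth = dep)
  expect_true(all(got2$haulout))
  # wet record suppresses the haul-out flag
  dep_wet <- data.frame(time = seq(0, 1500, 5), depth_m = 10)
  got3 <- exclude_haulouts(tr2, sites = site, depth = dep_wet)
  expect_false(any(got3$haulout))
  expect_error(exclude_haulouts(tr2, sites = site[0, ]), "empty")
})

test_that("trip segmentation enforces the 6 h and 1-dive rules", {
  mk_track <- function(hours) {
    n_out <- ceiling(hours * 6 / 2)
    out <- straight_track(n = n_out, speed = 1.5, bearing = 180, dt = 600)
    back <- out[rev(seq_len(n_out - 1)), ]
    back$time <- out$time[n_out] + seq_len(n_out - 1) * 600
    at_col <- straight_track(n = 3, speed = 0)
    pre <- at_col; pre$time <- -c(1800, 1200, 600)
    post <- at_col; post$time <- max(back$time) + c(600, 1200, 1800)
    tr <- rbind(pre, out, back, post)
    tr$excluded <- gc_dist_km(tr$lon, tr$lat, origin) <= 1
    tr$haulout <- FALSE
    tr
  }
  dive1 <- data.frame(start = 3 * 3600, end = 3 * 3600 + 100, duration = 100,
                      max_depth = 40, bottom_time = 50, descent_rate = 1,
                      vertical_distance = 80, is_daylight = TRUE,
                      is_benthic = TRUE)
  # 5 h at sea with a dive: no trip
  expect_length(segment_trips(mk_track(5), dive1, origin, min_hours = 6), 0)
  # 7 h with one dive: one trip
  trips <- segment_trips(mk_track(7), dive1, origin, min_hours = 6)
  expect_length(trips, 1)
  expect_equal(nrow(trips[[1]]$dives), 1)
  # 7 h but no dives: no trip
  expect_length(segment_trips(mk_track(7), dive1[0, ], origin), 0)
})

test_that("haul-out time inside a trip is excluded from trip duration", {
  # 12 h out, 2 h haul-out at a distant site, 12 h back
  out <- straight_track(n = 72, speed = 1.5, bearing = 180, dt = 600)
  site <- c(out$lon[72], out$lat[72])
  ho_t <- out$time[72] + seq(600, 2 * 3600, 600)
  ho <- data.frame(time = ho_t, lon = site[1], lat = site[2])
  back <- out[rev(seq_len(72)), ]
  back$time <- max(ho_t) + seq_len(72) * 600
  pre <- straight_track(n = 2, speed = 0); pre$time <- c(-1200, -600)
  post <- straight_track(n = 2, speed = 0)
  post$time <- max(back$time) + c(600, 1200)
  tr <- rbind(pre, out, ho, back, post)
  tr$excluded <- gc_dist_km(tr$lon, tr$lat, origin) <= 1 |
    gc_dist_km(tr$lon, tr$lat, site) <= 1
  tr$haulout <- tr$time %in% ho_t
  dives <- data.frame(start = c(2 * 3600, max(ho_t) + 5 * 3600),
                      end = c(2 * 3600 + 100, max(ho_t) + 5 * 3600 + 100),
                      duration = 100, max_depth = 40, bottom_time = 50,
                      descent_rate = 1, vertical_distance = 80,
                      is_daylight = TRUE, is_benthic = TRUE)
  trips <- segment_trips(tr, dives, origin, min_hours = 6)
  expect_length(trips, 1)
  # oracle: sum of in-water spans on either side of the haul-out
  span1 <- (out$time[72] - out$time[1]) / 3600
  span2 <- (max(back$time) - min(back$time)) / 3600
  expect_equal(trips[[1]]$duration_h, span1 + span2, tolerance = 0.2)
  expect_lt(trips[[1]]$duration_h,
            (max(back$time) - out$time[1]) / 3600 - 1.5)
})

test_that("trip spatial metrics: bearing, range, out-and-back distance", {
  out <- straight_track(n = 51, speed = 2, bearing = 180, dt = 500)
  back <- out[rev(seq_len(50)), ]
  back$time <- out$time[51] + seq_len(50) * 500
  tr <- rbind(out, back)
  tr$excluded <- FALSE; tr$haulout <- FALSE
  fixes <- interpolate_track(tr, step = 10, origin = origin)
  trip <- list(fixes = fixes, dives = data.frame()[0, ],
               duration_h = max(tr$time) / 3600)
  trip$dives <- data.frame(vertical_distance = numeric(0))
  m <- trip_spatial_metrics(trip, origin)
  expect_equal(m$bearing_distal, 180, tolerance = 0.5)
  expect_equal(m$max_range, 50, tolerance = 0.1) # 51 fixes x 1 km
  expect_equal(m$total_distance, 2 * m$max_range, tolerance = 0.01)
  expect_gte(m$total_distance, 2 * m$max_range - 0.01)
})

test_that("trips of one individual never overlap in time", {
  sim <- simulate_population(small_sim_config(n_individuals = 2, seed = 23))
  dir <- withr::local_tempdir()
  write_fixtures(sim, dir)
  res <- run_pipeline(pipeline_config(dir, withr::local_tempdir(),
                                      colony = sim$config$colony,
                                      n_perm = 0, n_boot = 0))
  for (id in unique(res$trips$individual_id)) {
    tt <- res$trips[res$trips$individual_id == id, ]
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1) expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
  }
  expect_true(all(res$trips$bearing_distal >= 0 &
                    res$trips$bearing_distal < 360))
  expect_true(all(res$trips$total_distance >=
                    2 * res$trips$max_range - 0.5))
})
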