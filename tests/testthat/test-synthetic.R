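test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_sim_config(n_individuals = 2, seed = 11)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$gps, b$gps)
  expect_identical(a$depth, b$depth)
  expect_identical(a$morphometrics, b$morphometrics)
  expect_identical(a$truth, b$truth)
})

test_that("zero between-individual bearing variance gives one shared expected bearing", {
  cfg <- small_sim_config(
    n_individuals = 5, seed = 3,
    sigma_alpha2 = c(bearing = 0, log_duration = 0.14, logit_benthic = 1.2))
  sim <- simulate_population(cfg)
  expect_equal(unique(sim$truth$individuals$bearing_mu), 203.5)
})

test_that("every simulated individual completes at least 3 trips", {
  sim <- simulate_population(small_sim_config(seed = 5))
  expect_true(all(sim$truth$individuals$n_trips >= 3))
  counts <- table(sim$truth$trips$individual_id)
  expect_true(all(counts >= 3))
})

test_that("morphometrics are drawn near the reference colony means", {
  sim <- simulate_population(sim_config(n_individuals = 200,
                                        trips_per_individual = 3,
                                        trip_duration_meanlog = log(12),
                                        trip_duration_range_h = c(8, 16),
                                        seed = 9))
  m <- sim$morphometrics
  expect_equal(mean(m$mass_kg), 70.4, tolerance = 0.03)
  expect_equal(mean(m$standard_length_cm), 151.4, tolerance = 0.02)
  expect_equal(mean(m$axillary_girth_cm), 99.2, tolerance = 0.02)
  # mass/girth and standard-length/axis-length collinearity is built in
  expect_gt(cor(m$mass_kg, m$axillary_girth_cm), 0.7)
  expect_gt(cor(m$standard_length_cm, m$axis_length_cm), 0.7)
})

test_that("realized repeatability of trip durations tracks the configured variance ratio", {
  # true R = 0.6 on the log scale: sa2 = 0.09, se2 = 0.06
  cfg <- sim_config(
    n_individuals = 50, trips_per_individual = 10,
    trip_duration_meanlog = log(8), trip_duration_range_h = c(1, 48),
    sigma_alpha2 = c(bearing = 1225, log_duration = 0.09, logit_benthic = 1.2),
    sigma_eps2 = c(bearing = 625, log_duration = 0.06, logit_benthic = 0.3),
    seed = 21)
  sim <- simulate_population(cfg)
  # oracle: one-way variance decomposition of the realized log durations
  ld <- log(sim$truth$trips$duration_true_h)
  id <- sim$truth$trips$individual_id
  gm <- tapply(ld, id, mean)
  msw <- mean(tapply(ld, id, var))
  msb <- var(gm) - msw / 10 # balanced one-way: var of means inflated by w/n
  r_oracle <- msb / (msb + msw)
  expect_equal(r_oracle, 0.6, tolerance = 0.1)
  # the generator's own realized-R record agrees with the oracle
  r_rec <- sim$truth$realized_r$r[sim$truth$realized_r$behavior == "log_duration"]
  expect_equal(r_rec, r_oracle, tolerance = 0.1)
})

test_that("raising between-individual variance raises realized repeatability", {
  grid <- c(0.02, 0.09, 0.4)
  med <- sapply(seq_along(grid), function(g) {
    median(replicate(10, {
      cfg <- sim_config(
        n_individuals = 8, trips_per_individual = 3,
        trip_duration_meanlog = log(8), trip_duration_range_h = c(4, 24),
        sigma_alpha2 = c(bearing = 1225, log_duration = grid[g],
                         logit_benthic = 1.2),
        sigma_eps2 = c(bearing = 625, log_duration = 0.06,
                       logit_benthic = 0.3),
        seed = 1000 * g + sample.int(1000, 1))
      sim <- simulate_population(cfg)
      rr <- sim$truth$realized_r
      rr$r[rr$behavior == "log_duration"]
    }))
  })
  expect_true(all(diff(med) > 0))
})

test_that("population benthic fraction matches the configured propensity", {
  cfg <- sim_config(n_individuals = 6, trips_per_individual = 3,
                    trip_duration_meanlog = log(14),
                    trip_duration_range_h = c(10, 20), seed = 13)
  sim <- simulate_population(cfg)
  expect_gt(nrow(sim$truth$dives), 2000)
  expect_equal(mean(sim$truth$dives$is_benthic), 0.75, tolerance = 0.05)
})

test_that("fixtures round-trip losslessly through the readers", {
  sim <- simulate_population(small_sim_config(n_individuals = 2, seed = 17))
  dir <- withr::local_tempdir()
  write_fixtures(sim, dir)
  g <- read_gps(file.path(dir, "gps_ID01.csv"))
  orig <- sim$gps[sim$gps$individual_id == "ID01", ]
  expect_equal(g$time, round(orig$time)) # ISO-8601 carries whole seconds
  expect_equal(g$lon, orig$lon, tolerance = 1e-12)
  d <- read_depth(file.path(dir, "depth_ID01.csv"))
  od <- sim$depth[sim$depth$individual_id == "ID01", ]
  expect_equal(d$depth_m, od$depth_m, tolerance = 1e-12)
  expect_equal(attr(d, "sample_interval"), 5)
  m <- read_morphometrics(file.path(dir, "morphometrics.csv"))
  expect_equal(m$mass_kg, sim$morphometrics$mass_kg, tolerance = 1e-12)
})

test_that("writing an empty population yields a valid header-only morphometrics file", {
  sim <- simulate_population(small_sim_config(n_individuals = 0, seed = 1))
  dir <- withr::local_tempdir()
  write_fixtures(sim, dir)
  expect_length(list.files(dir, "^gps_"), 0)
  m <- read_morphometrics(file.path(dir, "morphometrics.csv"))
  expect_equal(nrow(m), 0)
})

test_that("patch centres reproduce the configured bearing structure", {
  cfg <- small_sim_config(n_individuals = 6, trips = 4, seed = 19)
  sim <- simulate_population(cfg)
  tr <- sim$truth$trips
  patch_bearing <- (atan2(tr$patch_x, tr$patch_y) * 180 / pi) %% 360
  # circular mean of patch bearings should recover the population mean
  rad <- patch_bearing * pi / 180
  mean_b <- (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
  diff <- abs(((mean_b - 203.5 + 180) %% 360) - 180)
  # circular SE of the trip-level draws, inflated for CRW wander
  expect_lt(diff, 3 * sqrt(1225 / 6 + 625 / nrow(tr)) )
})
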