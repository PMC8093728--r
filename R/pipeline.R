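#' Pipeline configuration
#'
#' Collects every threshold of the analysis with its standard default: 5 m
#' dive threshold, 6 m/s speed filter, 10 s interpolation, 1 km buffers and
#' grid, 6 h minimum trip, 10 min haul-out rule, 07:00--18:00 local
#' daylight window, 95% isopleth, AICc selection threshold 4 and |r| > 0.7
#' collinearity limit. Overrides are recorded in the run manifest.
#'
#' @param input_dir directory of `gps_*.csv` / `depth_*.csv` /
#'   `morphometrics.csv` fixtures (see [write_fixtures()]).
#' @param output_dir where outputs are written.
#' @param colony `c(lon, lat)` of the colony (projection origin).
#' @param haulout_sites optional data.frame `lon, lat` of additional
#'   haul-out sites; the colony is always included.
#' @param utc_offset_h local clock offset for the daylight rule.
#' @param dive_threshold_m,zoc_window_s,zoc_quantile dive processing.
#' @param speed_vmax_ms,interp_step_s,buffer_km,min_trip_h,min_dry_min
#'   track processing.
#' @param daylight_window local clock hours.
#' @param cell_km,isopleth spatial fidelity grid.
#' @param aicc_delta,cor_threshold model selection.
#' @param capture a [capture_model()].
#' @param n_perm,n_boot resampling effort for Gaussian repeatability.
#' @param seed RNG seed for the resampling stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            colony = c(lon = 146.30, lat = -39.17),
                            haulout_sites = NULL,
                            utc_offset_h = 10,
                            dive_threshold_m = 5,
                            zoc_window_s = 3 * 3600,
                            zoc_quantile = 0.05,
                            speed_vmax_ms = 6,
                            interp_step_s = 10,
                            buffer_km = 1,
                            min_trip_h = 6,
                            min_dry_min = 10,
                            daylight_window = c(7, 18),
                            cell_km = 1,
                            isopleth = 0.95,
                            aicc_delta = 4,
                            cor_threshold = 0.7,
                            capture = capture_model(),
                            n_perm = 1000,
                            n_boot = 1000,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "capture")]), f)
  unname(tools::md5sum(f))
}

# Fallback benthic labelling for individuals with too few dives for the
# bimodal split: single-mode rule on the mean bottom fraction.
label_dives <- function(dives, min_n = 30) {
  if (nrow(dives) >= min_n) return(classify_dives(dives))
  dives$benthic_index <- benthic_index(dives$max_depth, dives$bottom_time,
                                       dives$duration)
  dives$is_benthic <- mean(dives$bottom_time / dives$duration) >= 0.4
  dives
}

#' Run the full biologging analysis pipeline
#'
#' Chains every stage over a fixture directory: read + zero-offset correct
#' depth, detect dives, speed-filter tracks, flag haul-outs, segment
#' foraging trips, classify dives benthic/pelagic per individual, compute
#' per-trip behaviour metrics and success/efficiency indices, per-individual
#' utilization distributions and FSFI, population repeatability of every
#' behaviour (with AICc-selected morphometric fixed effects), and the four
#' consistency linear models. Outputs (`trips.csv`, `dives.csv`,
#' `fidelity.csv`, `indices.csv`, `repeatability.csv`,
#' `consistency_models.json`, `manifest.json`) go to
#' `config$output_dir`. The run is deterministic given the config and seed,
#' and the manifest accounts for every dropped fix, dive and bout.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `trips`, `dives`, `fidelity`,
#'   `repeatability`, `consistency`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  set.seed(cfg$seed)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  gps_files <- sort(list.files(cfg$input_dir, "^gps_.*\\.csv$",
                               full.names = TRUE))
  if (!length(gps_files)) stop("no gps_*.csv files in input_dir")
  sites <- data.frame(lon = cfg$colony[[1]], lat = cfg$colony[[2]])
  if (!is.null(cfg$haulout_sites)) {
    sites <- rbind(sites, cfg$haulout_sites[c("lon", "lat")])
  }
  morpho_path <- file.path(cfg$input_dir, "morphometrics.csv")
  morpho <- if (file.exists(morpho_path)) read_morphometrics(morpho_path)
            else NULL

  counts <- list()
  trips_rows <- list(); dives_rows <- list(); fidelity_rows <- list()
  uds_by_id <- list(); warn <- character(0)

  for (gf in gps_files) {
    id <- sub("^gps_(.*)\\.csv$", "\\1", basename(gf))
    df <- file.path(cfg$input_dir, sprintf("depth_%s.csv", id))
    gps <- read_gps(gf)
    depth <- read_depth(df)
    depth <- zero_offset_correct(depth, cfg$zoc_window_s, cfg$zoc_quantile)
    dives <- detect_dives(depth, threshold = cfg$dive_threshold_m,
                          daylight_window = cfg$daylight_window,
                          utc_offset_h = cfg$utc_offset_h)
    ftrack <- speed_filter(gps, vmax = cfg$speed_vmax_ms)
    ftrack <- exclude_haulouts(ftrack, sites, depth = depth,
                               buffer_km = cfg$buffer_km,
                               min_dry = cfg$min_dry_min)
    if (nrow(dives)) dives <- label_dives(dives)
    trips <- segment_trips(ftrack, dives, cfg$colony,
                           min_hours = cfg$min_trip_h,
                           interp_step = cfg$interp_step_s,
                           buffer_km = cfg$buffer_km)
    tc <- attr(trips, "counts")
    n_dives_in_trips <- if (length(trips))
      sum(vapply(trips, function(tr) nrow(tr$dives), 1L)) else 0L
    counts[[id]] <- data.frame(
      individual_id = id,
      gps_rows_in = nrow(gps),
      gps_dropped_speed = nrow(gps) - nrow(ftrack),
      fixes_excluded_buffer = sum(ftrack$excluded),
      fixes_haulout = sum(ftrack$haulout & !ftrack$excluded),
      depth_rows_in = nrow(depth),
      dives_detected = nrow(dives),
      dives_in_trips = n_dives_in_trips,
      dives_dropped_outside_trips = nrow(dives) - n_dives_in_trips,
      bouts = unname(tc["bouts"]),
      bouts_dropped_short = unname(tc["dropped_short"]),
      bouts_dropped_no_dive = unname(tc["dropped_no_dive"]),
      bouts_merged_over_haulout = unname(tc["merged"]),
      trips_kept = length(trips),
      stringsAsFactors = FALSE
    )
    if (!length(trips)) {
      warn <- c(warn, sprintf("%s: no foraging trips retained", id))
      next
    }
    uds <- list()
    for (j in seq_along(trips)) {
      tr <- trips[[j]]
      tds <- trip_dive_summary(tr$dives, tr$duration_h)
      tsm <- trip_spatial_metrics(tr, cfg$colony)
      bd <- tr$dives[tr$dives$is_benthic, , drop = FALSE]
      ind <- if (nrow(bd)) trip_indices(bd, tr$duration_h, cfg$capture)
             else data.frame(ftsi = NA_real_, ftei = NA_real_,
                             benthic_dive_rate = NA_real_,
                             sum_capture_prob = NA_real_, n_benthic = 0L)
      uds[[j]] <- kde_ud(dive_time_grid(tr$dives, cfg$cell_km),
                         cell_km = cfg$cell_km, isopleth = cfg$isopleth)
      trips_rows[[length(trips_rows) + 1L]] <- cbind(
        data.frame(individual_id = id, trip = j,
                   start = tr$start, end = tr$end,
                   duration_h = tr$duration_h, stringsAsFactors = FALSE),
        tds, tsm, ind,
        data.frame(n_daylight = sum(tr$dives$is_daylight))
      )
      dv <- tr$dives
      dv$individual_id <- id
      dv$trip <- j
      dives_rows[[length(dives_rows) + 1L]] <- dv
    }
    uds_by_id[[id]] <- uds
    if (length(uds) >= 2) {
      fid <- fsfi(uds)
      fidelity_rows[[length(fidelity_rows) + 1L]] <- data.frame(
        individual_id = id, fsfi = fid$fsfi, n_trips = fid$n_trips,
        stringsAsFactors = FALSE)
    }
  }

  trips_df <- if (length(trips_rows)) do.call(rbind, trips_rows) else NULL
  dives_df <- if (length(dives_rows)) do.call(rbind, dives_rows) else NULL
  fidelity_df <- if (length(fidelity_rows)) do.call(rbind, fidelity_rows)
                 else NULL
  manifest <- list(
    config_hash = config_hash(cfg),
    thresholds = cfg[c("dive_threshold_m", "speed_vmax_ms", "interp_step_s",
                       "buffer_km", "min_trip_h", "min_dry_min", "cell_km",
                       "isopleth", "aicc_delta", "cor_threshold", "n_perm",
                       "n_boot", "seed")],
    stage_counts = do.call(rbind, counts),
    warnings = warn
  )

  rpt_df <- NULL; consistency <- NULL
  if (!is.null(trips_df) && !is.null(morpho) &&
      length(unique(trips_df$individual_id)) >= 2) {
    bt <- merge(trips_df, morpho, by = "individual_id")
    bt$curt_total_distance <- bt$total_distance^(1 / 3)
    bt$curt_duration <- bt$duration_h^(1 / 3)
    bt$curt_dive_rate <- bt$dive_rate^(1 / 3)
    bt$individual_id <- factor(bt$individual_id)
    mcols <- c("mass_kg", "standard_length_cm", "flipper_length_cm",
               "axis_length_cm", "axillary_girth_cm")
    retained <- screen_collinearity(bt[mcols],
                                    threshold = cfg$cor_threshold)
    gaussian_beh <- c("max_range", "curt_total_distance", "curt_duration",
                      "curt_dive_rate", "modal_depth")
    rpt <- list()
    for (b in gaussian_beh) {
      sel <- select_fixed_effects(bt, b, retained, id = "individual_id",
                                  family = "gaussian",
                                  delta = cfg$aicc_delta)
      rpt[[b]] <- repeatability_gaussian(bt, b, sel$covariates,
                                        id = "individual_id",
                                        n_perm = cfg$n_perm,
                                        n_boot = cfg$n_boot)
    }
    bt$n_benthic_int <- round(bt$prop_benthic * bt$n_dives)
    for (b in c("n_benthic_int", "n_daylight")) {
      resp <- sprintf("cbind(%s, n_dives - %s)", b, b)
      sel <- tryCatch(
        select_fixed_effects(bt, resp, retained, id = "individual_id",
                             family = "binomial", delta = cfg$aicc_delta),
        error = function(e) list(covariates = character(0)))
      rpt[[b]] <- repeatability_proportion(bt, b, "n_dives",
                                           sel$covariates,
                                           id = "individual_id")
    }
    names(rpt) <- c("max_range", "total_distance", "duration", "dive_rate",
                    "modal_depth", "prop_benthic", "prop_daylight")
    rpt_df <- do.call(rbind, lapply(names(rpt), function(nm) {
      x <- rpt[[nm]]
      data.frame(behavior = nm, sigma_alpha2 = x$sigma_alpha2,
                 sigma_eps2 = x$sigma_eps2, r = x$r,
                 r_individual = x$r_individual, adjusted = x$adjusted,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 p_perm = x$p_perm, band = x$band,
                 stringsAsFactors = FALSE)
    }))

    profiles <- list()
    for (id in unique(as.character(trips_df$individual_id))) {
      tr_i <- trips_df[trips_df$individual_id == id, , drop = FALSE]
      if (nrow(tr_i) < 3) next
      f <- if (!is.null(fidelity_df) && id %in% fidelity_df$individual_id)
        fidelity_df$fsfi[fidelity_df$individual_id == id] else NA_real_
      profiles[[id]] <- consistency_profile(tr_i, fsfi = f,
                                            individual_id = id)
    }
    profiles_df <- if (length(profiles)) do.call(rbind, profiles) else NULL
    consistency <- tryCatch(
      fit_consistency_models(profiles_df, delta = cfg$aicc_delta),
      error = function(e) {
        warn <<- c(warn, paste("consistency models skipped:",
                               conditionMessage(e)))
        NULL
      })
    manifest$warnings <- warn
  }

  wr <- function(d, f, template) {
    if (is.null(d)) d <- template
    write.csv(d, file.path(cfg$output_dir, f), row.names = FALSE)
  }
  wr(trips_df, "trips.csv",
     data.frame(individual_id = character(0), trip = integer(0)))
  wr(dives_df, "dives.csv",
     data.frame(individual_id = character(0), start = numeric(0)))
  wr(fidelity_df, "fidelity.csv",
     data.frame(individual_id = character(0), fsfi = numeric(0)))
  wr(if (is.null(trips_df)) NULL else
       trips_df[c("individual_id", "trip", "ftsi", "ftei",
                  "benthic_dive_rate", "n_benthic")],
     "indices.csv", data.frame(individual_id = character(0)))
  wr(rpt_df, "repeatability.csv",
     data.frame(behavior = character(0), r = numeric(0)))
  if (!is.null(consistency)) {
    slim <- lapply(consistency, function(m) {
      m[c("response", "formula", "aic", "loglik", "l_ratio", "p", "r2",
          "coefficients")]
    })
    jsonlite::write_json(slim, file.path(cfg$output_dir,
                                         "consistency_models.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    jsonlite::write_json(list(), file.path(cfg$output_dir,
                                           "consistency_models.json"))
  }
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(list(trips = trips_df, dives = dives_df,
                 fidelity = fidelity_df, uds = uds_by_id,
                 repeatability = rpt_df, consistency = consistency,
                 manifest = manifest))
}
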