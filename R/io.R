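parse_iso <- function(x, path, what) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(t))
  if (length(bad)) {
    stop(sprintf("%s: malformed %s timestamp at data row %d ('%s')",
                 path, what, bad[1], x[bad[1]]))
  }
  as.numeric(t)
}

check_monotone <- function(tt, path) {
  if (anyDuplicated(tt)) {
    stop(sprintf("%s: duplicated timestamp at data row %d", path,
                 anyDuplicated(tt)))
  }
  if (is.unsorted(tt)) stop(sprintf("%s: timestamps are not sorted", path))
}

#' Read a GPS fix table
#'
#' Expects columns `individual_id, timestamp, lon, lat` with ISO-8601 UTC
#' timestamps at a nominal 10-min interval. Rows are validated (parseable
#' timestamps, numeric coordinates, strictly increasing time per
#' individual) and returned sorted.
#'
#' @param path CSV file.
#' @return data.frame `individual_id`, `time` (numeric seconds UTC), `lon`,
#'   `lat`.
#' @export
read_gps <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "timestamp", "lon", "lat")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: missing columns %s", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(d$lon))) |
                 !is.finite(suppressWarnings(as.numeric(d$lat))))
  if (length(bad)) stop(sprintf("%s: malformed coordinate at data row %d",
                                path, bad[1]))
  out <- data.frame(individual_id = as.character(d$individual_id),
                    time = parse_iso(d$timestamp, path, "GPS"),
                    lon = as.numeric(d$lon), lat = as.numeric(d$lat),
                    stringsAsFactors = FALSE)
  out <- out[order(out$individual_id, out$time), , drop = FALSE]
  for (id in unique(out$individual_id)) {
    check_monotone(out$time[out$individual_id == id], path)
  }
  rownames(out) <- NULL
  out
}

#' Read a depth sample table
#'
#' Expects `individual_id, timestamp, depth_m` at a 1 or 5 s interval; the
#' interval is auto-detected (median time step) and attached as attribute
#' `sample_interval`.
#'
#' @param path CSV file.
#' @return data.frame `individual_id`, `time`, `depth_m`.
#' @export
read_depth <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "timestamp", "depth_m")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: missing columns %s", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  }
  dep <- suppressWarnings(as.numeric(d$depth_m))
  if (anyNA(dep)) stop(sprintf("%s: malformed depth at data row %d", path,
                               which(is.na(dep))[1]))
  out <- data.frame(individual_id = as.character(d$individual_id),
                    time = parse_iso(d$timestamp, path, "depth"),
                    depth_m = dep, stringsAsFactors = FALSE)
  out <- out[order(out$individual_id, out$time), , drop = FALSE]
  ints <- numeric(0)
  for (id in unique(out$individual_id)) {
    tt <- out$time[out$individual_id == id]
    check_monotone(tt, path)
    if (length(tt) > 1) ints <- c(ints, median(diff(tt)))
  }
  rownames(out) <- NULL
  attr(out, "sample_interval") <- if (length(ints)) median(ints) else NA_real_
  out
}

#' Read a morphometrics table
#' @param path CSV with `individual_id, mass_kg, standard_length_cm,
#'   flipper_length_cm, axis_length_cm, axillary_girth_cm`.
#' @return validated data.frame.
#' @export
read_morphometrics <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "mass_kg", "standard_length_cm",
            "flipper_length_cm", "axis_length_cm", "axillary_girth_cm")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: missing columns %s", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  }
  for (cn in need[-1]) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    if (anyNA(v) && nrow(d)) {
      stop(sprintf("%s: malformed %s at data row %d", path, cn,
                   which(is.na(v))[1]))
    }
    d[[cn]] <- v
  }
  d
}
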