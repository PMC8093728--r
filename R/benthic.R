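#' Bottom-time-weighted depth index of a dive
#'
#' The benthic index is the dive's maximum depth weighted by the proportion
#' of the dive spent in the bottom phase: `max_depth * bottom_time /
#' duration`. For an animal foraging over a shelf the index is bimodal —
#' benthic dives are deep with long flat bottoms (high index), pelagic dives
#' are shallower with brief bottoms (low index).
#'
#' @param max_depth m; @param bottom_time,duration seconds (duration > 0).
#' @return numeric index (same order as inputs), >= 0.
#' @export
benthic_index <- function(max_depth, bottom_time, duration) {
  stopifnot(all(duration > 0))
  max_depth * bottom_time / duration
}

#' Split a dive-index distribution into benthic and pelagic modes
#'
#' Fits a Gaussian kernel density (Silverman bandwidth) to one individual's
#' benthic-index values, takes the two highest local maxima, and places the
#' nadir at the density minimum between them. Dives at or right of the nadir
#' are benthic, dives left of it pelagic — the split is relative to the
#' individual's own dives. When the density has no interior minimum
#' (unimodal data), all dives fall in the single mode and are labelled
#' benthic when the mode's mean bottom-time fraction is at least
#' `fallback_bottom_frac`, pelagic otherwise.
#'
#' @param index numeric vector of per-dive benthic indices (>= 30 values).
#' @param bottom_frac optional vector of bottom_time/duration used only by
#'   the unimodal fallback.
#' @param fallback_bottom_frac threshold for the fallback rule (default 0.4).
#' @return list of class `benthic_split`: `nadir`, `peaks`, `bandwidth`,
#'   `density` (data.frame x, y), `is_benthic` (logical per dive),
#'   `unimodal` flag.
#' @export
fit_benthic_split <- function(index, bottom_frac = NULL,
                              fallback_bottom_frac = 0.4) {
  stopifnot(length(index) >= 30)
  if (sd(index) < sqrt(.Machine$double.eps)) {
    lab <- !is.null(bottom_frac) && mean(bottom_frac) >= fallback_bottom_frac
    return(structure(list(nadir = NA_real_, peaks = unique(index)[1],
                          bandwidth = NA_real_, density = NULL,
                          is_benthic = rep(lab, length(index)),
                          unimodal = TRUE), class = "benthic_split"))
  }
  den <- density(index, bw = "nrd0")
  y <- den$y; x <- den$x
  n <- length(y)
  loc_max <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  if (length(loc_max) >= 2) {
    top2 <- sort(loc_max[order(y[loc_max], decreasing = TRUE)][1:2])
    between <- seq(top2[1], top2[2])
    nadir_i <- between[which.min(y[between])]
    nadir <- x[nadir_i]
    lab <- index >= nadir # ties -> benthic
    return(structure(list(nadir = nadir, peaks = x[top2],
                          bandwidth = den$bw,
                          density = data.frame(x = x, y = y),
                          is_benthic = lab, unimodal = FALSE),
                     class = "benthic_split"))
  }
  if (is.null(bottom_frac)) {
    warning("unimodal index with no bottom fractions supplied; labelling all dives benthic")
    lab <- TRUE
  } else {
    lab <- mean(bottom_frac) >= fallback_bottom_frac
  }
  structure(list(nadir = NA_real_, peaks = x[loc_max], bandwidth = den$bw,
                 density = data.frame(x = x, y = y),
                 is_benthic = rep(isTRUE(lab), length(index)),
                 unimodal = TRUE), class = "benthic_split")
}

#' Label an individual's dives as benthic or pelagic
#'
#' Convenience wrapper: computes the index from the dive table, fits the
#' per-individual bimodal split, and returns the dives with `benthic_index`
#' and `is_benthic` columns attached.
#'
#' @param dives data.frame from [detect_dives()].
#' @inheritParams fit_benthic_split
#' @return the dive table with `benthic_index` and `is_benthic` added; the
#'   fitted split is attached as attribute `"split"`.
#' @export
classify_dives <- function(dives, fallback_bottom_frac = 0.4) {
  idx <- benthic_index(dives$max_depth, dives$bottom_time, dives$duration)
  sp <- fit_benthic_split(idx, bottom_frac = dives$bottom_time / dives$duration,
                          fallback_bottom_frac = fallback_bottom_frac)
  dives$benthic_index <- idx
  dives$is_benthic <- sp$is_benthic
  attr(dives, "split") <- sp
  dives
}
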