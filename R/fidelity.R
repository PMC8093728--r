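#' Accumulate dive time on the 1 km analysis grid
#'
#' Sums each dive's duration into the 1 x 1 km grid cell containing its
#' joined location. Cells are indexed by the integer floor of the projected
#' coordinates (km), so the grid is anchored at the projection origin (the
#' colony) and shared by every trip and individual; the extent grows with
#' the data.
#'
#' @param dives data.frame with `x`, `y` (projected km, from
#'   [segment_trips()]) and `duration` (s).
#' @param cell_km cell edge length, km (default 1).
#' @return data.frame `ix`, `iy` (cell indices), `seconds` (summed dive
#'   time); one row per occupied cell.
#' @export
dive_time_grid <- function(dives, cell_km = 1) {
  stopifnot(nrow(dives) >= 1, !is.null(dives$x), !is.null(dives$y))
  ix <- floor(dives$x / cell_km)
  iy <- floor(dives$y / cell_km)
  key <- paste(ix, iy)
  sec <- tapply(dives$duration, key, sum)
  first <- !duplicated(key)
  ord <- match(names(sec), key[first])
  out <- data.frame(ix = ix[first], iy = iy[first],
                    seconds = as.numeric(sec[match(key[first], names(sec))]))
  out[order(out$ix, out$iy), , drop = FALSE]
}

# Weighted reference bandwidth for a bivariate kernel UD:
# href = sigma_hat * n_eff^(-1/6), sigma_hat = sqrt((var_w(x)+var_w(y))/2),
# n_eff = (sum w)^2 / sum w^2.
href_bandwidth <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  n_eff <- sw^2 / sum(w^2)
  sqrt((vx + vy) / 2) * n_eff^(-1 / 6)
}

#' Kernel utilization distribution of dive time
#'
#' Bivariate Gaussian kernel density of dive time over the 1 km grid:
#' kernels sit at occupied cell centres, weighted by the seconds of dive
#' time in the cell, with the reference bandwidth `href` generalized to
#' weighted data (see Details). The density is evaluated at cell centres
#' over the occupied bounding box padded by 3 bandwidths, truncated to the
#' smallest set of cells holding at least `isopleth` of the mass (the 95%
#' utilization distribution), and renormalized.
#'
#' @details The bandwidth is `href = sigma * n_eff^(-1/6)` with `sigma` the
#' root mean marginal weighted variance and `n_eff = (sum w)^2 / sum(w^2)`
#' the effective number of kernels. A single occupied cell (or zero spatial
#' spread) degenerates to a point mass on that cell.
#'
#' @param grid data.frame from [dive_time_grid()].
#' @param cell_km cell size, km.
#' @param isopleth retained probability mass (default 0.95).
#' @param bandwidth optional fixed bandwidth (km) overriding `href`.
#' @return object of class `ud`: data.frame `ix`, `iy`, `p` (cell
#'   probabilities summing to 1) with attributes `bandwidth`, `cell_km`,
#'   `isopleth`.
#' @export
kde_ud <- function(grid, cell_km = 1, isopleth = 0.95, bandwidth = NULL) {
  stopifnot(nrow(grid) >= 1, all(grid$seconds > 0))
  w <- grid$seconds
  cx <- (grid$ix + 0.5) * cell_km
  cy <- (grid$iy + 0.5) * cell_km
  h <- if (is.null(bandwidth)) href_bandwidth(cx, cy, w) else bandwidth
  if (nrow(grid) == 1L || !is.finite(h) || h <= 0) {
    i_best <- which.max(w)
    out <- data.frame(ix = grid$ix[i_best], iy = grid$iy[i_best], p = 1)
    return(structure(out, bandwidth = 0, cell_km = cell_km,
                     isopleth = isopleth, class = c("ud", "data.frame")))
  }
  pad <- ceiling(3 * h / cell_km)
  gx <- seq(min(grid$ix) - pad, max(grid$ix) + pad)
  gy <- seq(min(grid$iy) - pad, max(grid$iy) + pad)
  ex <- (gx + 0.5) * cell_km
  ey <- (gy + 0.5) * cell_km
  # separable Gaussian: density(Xc) = sum_j w_j K(x - cx_j) K(y - cy_j)
  kx <- outer(ex, cx, function(a, b) exp(-(a - b)^2 / (2 * h^2)))
  ky <- outer(ey, cy, function(a, b) exp(-(a - b)^2 / (2 * h^2)))
  dens <- kx %*% (w * t(ky)) # [x, y]
  p <- as.vector(dens)
  p <- p / sum(p)
  cells <- expand.grid(ix = gx, iy = gy)
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  n_keep <- which(cum >= isopleth)[1]
  keep <- ord[seq_len(n_keep)]
  out <- data.frame(ix = cells$ix[keep], iy = cells$iy[keep], p = p[keep])
  out$p <- out$p / sum(out$p)
  out <- out[order(out$ix, out$iy), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, bandwidth = h, cell_km = cell_km, isopleth = isopleth,
            class = c("ud", "data.frame"))
}

#' Bhattacharyya affinity between two utilization distributions
#'
#' `BA = sum_cells sqrt(p_i * q_i)` over the union of the two cell sets
#' (missing cells contribute 0). BA is 1 for identical distributions, 0 for
#' disjoint supports, and lies in \[0, 1\] by Cauchy-Schwarz.
#'
#' @param ud1,ud2 `ud` objects (or data.frames with `ix`, `iy`, `p`) on the
#'   same grid; probabilities must each sum to 1.
#' @return numeric scalar in \[0, 1\].
#' @export
bhattacharyya <- function(ud1, ud2) {
  for (u in list(ud1, ud2)) {
    if (abs(sum(u$p) - 1) > 1e-8) stop("utilization distribution is not normalized")
  }
  k1 <- paste(ud1$ix, ud1$iy)
  k2 <- paste(ud2$ix, ud2$iy)
  common <- intersect(k1, k2)
  if (!length(common)) return(0)
  sum(sqrt(ud1$p[match(common, k1)] * ud2$p[match(common, k2)]))
}

#' Foraging Site Fidelity Index of one individual
#'
#' Pairwise Bhattacharyya affinity between the dive-time utilization
#' distributions of every unordered pair of the individual's trips, averaged
#' into a single index: 0 means no overlap between any trips, 1 complete
#' overlap of all trips.
#'
#' @param uds list of >= 2 `ud` objects, one per trip, on a common grid.
#' @return list of class `fidelity`: `ba` (symmetric matrix, unit
#'   diagonal), `fsfi` (mean off-diagonal affinity), `n_trips`.
#' @export
fsfi <- function(uds) {
  n <- length(uds)
  if (n < 2) stop("FSFI needs at least 2 trips")
  ba <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ba[i, j] <- ba[j, i] <- bhattacharyya(uds[[i]], uds[[j]])
    }
  }
  structure(list(ba = ba, fsfi = mean(ba[upper.tri(ba)]), n_trips = n),
            class = "fidelity")
}
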