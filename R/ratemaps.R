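#' Firing events by activation thresholding
#'
#' A bottleneck unit is taken to "fire" at the trajectory points where its
#' activation reaches a per-unit percentile threshold (80th percentile by
#' default). The positions of those points are the firing events entering
#' the rate-map estimators.
#'
#' @param activations numeric vector of one unit's activations, aligned
#'   with the trajectory points.
#' @param traj the [trajectory()] the activations were computed on.
#' @param percentile percentile in \[0, 100\] defining the threshold (0
#'   makes every point an event; 100 keeps only the maxima).
#' @param neuron_id optional identifier carried through to reports.
#' @return An object of class `"firing_events"`: `idx` (trajectory point
#'   indices), `positions` (event coordinates), `threshold`, `percentile`,
#'   `neuron_id`.
#' @export
threshold_events <- function(activations, traj, percentile = 80,
                             neuron_id = NA_integer_) {
  if (!is.numeric(percentile) || percentile < 0 || percentile > 100) {
    stop_invalid("`percentile` must be in [0, 100]")
  }
  a <- as.numeric(activations)
  if (length(a) != nrow(traj$positions)) {
    stop_invalid("activations and trajectory lengths differ")
  }
  if (max(a) == min(a)) {
    warning("constant activation: no events")
    idx <- integer(0)
    thr <- NA_real_
  } else {
    thr <- stats::quantile(a, percentile / 100, names = FALSE)
    idx <- which(a >= thr)
  }
  structure(list(idx = idx,
                 positions = traj$positions[idx, , drop = FALSE],
                 threshold = thr, percentile = percentile,
                 neuron_id = neuron_id),
            class = "firing_events")
}

#' @export
print.firing_events <- function(x, ...) {
  cat(sprintf("<firing_events: %d events (>= %g%% percentile, threshold %.4g)>\n",
              length(x$idx), x$percentile, x$threshold))
  invisible(x)
}

# Separable Gaussian smoothing matrix for one axis of a binned map:
# row-stochastic would distort rates, so the kernel is applied unnormalised
# to numerator and denominator alike and the normalisation cancels in the
# ratio.
gauss_smooth_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  i <- seq_len(n)
  K <- exp(-outer(i, i, `-`)^2 / (2 * sigma^2))
  K[abs(outer(i, i, `-`)) > ceiling(3 * sigma)] <- 0
  K
}

bin_index_1d <- function(x, lo, hi, n) {
  ix <- floor((x - lo) / (hi - lo) * n) + 1L
  pmin.int(pmax.int(ix, 1L), n)
}

# Flat bin index of positions over a 2D binning of the chosen coordinate
# pair; exposed internally so the shuffle test can re-bin events cheaply.
bin_index_2d <- function(pos, bounds, bins, dims = c(1, 2)) {
  ix <- bin_index_1d(pos[, dims[1]], bounds[dims[1], 1], bounds[dims[1], 2],
                     bins[1])
  iy <- bin_index_1d(pos[, dims[2]], bounds[dims[2], 1], bounds[dims[2], 2],
                     bins[2])
  (iy - 1L) * bins[1] + ix
}

#' 2D binned firing-rate map
#'
#' Events and occupancy are histogrammed over an `nx x ny` binning of the
#' arena (or of a chosen coordinate plane of a 3D maze), optionally smoothed
#' with a truncated Gaussian kernel, and the rate is the smoothed event
#' count divided by the smoothed occupancy. Bins never visited have rate 0
#' and are flagged unvisited.
#'
#' @param events a [threshold_events()] result.
#' @param traj the matching [trajectory()].
#' @param bins bins per axis (length 2).
#' @param smoothing Gaussian kernel standard deviation in bins (0 disables).
#' @param dims which coordinate columns span the map plane (default x, y).
#' @return An object of class `"rate_map"`: `rate` (nx x ny), `occupancy`
#'   (raw visit counts), `events` (raw event counts), `origin`, `bin_size`,
#'   `dims`, `smoothing`, `visited` (logical matrix).
#' @export
rate_map_2d <- function(events, traj, bins = c(20, 20), smoothing = 1,
                        dims = c(1, 2)) {
  if (any(bins < 2)) stop_invalid("need at least 2 bins per axis")
  bins <- as.integer(bins)
  b <- traj$bounds
  occ_idx <- bin_index_2d(traj$positions, b, bins, dims)
  occ <- matrix(tabulate(occ_idx, bins[1] * bins[2]), bins[1], bins[2])
  ev <- matrix(0, bins[1], bins[2])
  if (length(events$idx) > 0) {
    ev_idx <- bin_index_2d(events$positions, b, bins, dims)
    ev <- matrix(tabulate(ev_idx, bins[1] * bins[2]), bins[1], bins[2])
  }
  Sx <- gauss_smooth_matrix(bins[1], smoothing)
  Sy <- gauss_smooth_matrix(bins[2], smoothing)
  occ_s <- Sx %*% occ %*% Sy
  ev_s <- Sx %*% ev %*% Sy
  rate <- ifelse(occ_s > 0, ev_s / occ_s, 0)
  rate[occ_s == 0] <- 0
  structure(list(rate = rate, occupancy = occ, events = ev,
                 origin = b[dims, 1],
                 bin_size = (b[dims, 2] - b[dims, 1]) / bins,
                 dims = dims, smoothing = smoothing,
                 visited = occ_s > 0),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  d <- dim(x$rate)
  cat(sprintf("<rate_map: %s bins, peak rate %.4g, %.1f%% visited>\n",
              paste(d, collapse = " x "), max(x$rate),
              100 * mean(x$visited)))
  invisible(x)
}

#' @export
plot.rate_map <- function(x, ...) {
  if (length(dim(x$rate)) != 2) stop_invalid("only 2D maps can be plotted")
  graphics::image(x$rate, useRaster = TRUE, asp = 1,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

# Accumulate truncated-Gaussian contributions of points into the voxel grid:
# a point in voxel v contributes exp(-d^2 / (2 sigma^2)) (d in voxel units,
# to the voxel centre) to v and its 26 neighbours only.
accumulate_truncated_gaussian <- function(pos, origin, bin_size, nbins,
                                          sigma) {
  u <- sweep(sweep(pos, 2, origin), 2, bin_size, `/`)  # continuous voxel coord
  vox <- pmin(pmax(floor(u) + 1L, 1L), matrix(nbins, nrow(u), 3, byrow = TRUE))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  total <- numeric(prod(nbins))
  for (k in seq_len(nrow(offs))) {
    tgt <- sweep(vox, 2, offs[k, ], `+`)
    ok <- tgt[, 1] >= 1 & tgt[, 1] <= nbins[1] &
      tgt[, 2] >= 1 & tgt[, 2] <= nbins[2] &
      tgt[, 3] >= 1 & tgt[, 3] <= nbins[3]
    if (!any(ok)) next
    d2 <- rowSums((u[ok, , drop = FALSE] -
                     (tgt[ok, , drop = FALSE] - 0.5))^2)
    w <- exp(-d2 / (2 * sigma^2))
    flat <- (tgt[ok, 3] - 1L) * nbins[1] * nbins[2] +
      (tgt[ok, 2] - 1L) * nbins[1] + tgt[ok, 1]
    agg <- rowsum(w, flat)
    total[as.integer(rownames(agg))] <- total[as.integer(rownames(agg))] + agg
  }
  array(total, dim = nbins)
}

#' 3D voxel firing-rate map
#'
#' The maze volume is divided into voxels (20 x 20 x 20 by default) and the
#' firing rate at voxel centre \eqn{x_j} is the kernel-weighted event count
#' over the kernel-weighted occupancy,
#' \deqn{f(x_j) = \frac{\sum_i g(X_{ij} - x_j)}{\sum_t g(y(t) - x_j)},}
#' where the truncated Gaussian `g` (standard deviation one voxel) is
#' non-zero only for the 26 voxels neighbouring the one containing the
#' point. Voxels with zero kernel-weighted occupancy get rate 0 and are
#' flagged unvisited.
#'
#' @param events a [threshold_events()] result.
#' @param traj the matching [trajectory()].
#' @param nbins voxels per axis (length 3).
#' @param sigma kernel standard deviation in voxel units.
#' @param bounds optional 3 x 2 matrix of the volume covered (defaults to
#'   the trajectory bounds).
#' @param denominator optional precomputed kernel-weighted occupancy array
#'   (identical across units tested on the same trajectory), to avoid
#'   recomputing it per unit.
#' @return An object of class `"rate_map"` with a 3D `rate` array,
#'   `occupancy` (raw point counts per voxel), `events` (raw event counts),
#'   `origin`, `bin_size`, `visited`.
#' @export
rate_map_3d <- function(events, traj, nbins = c(20, 20, 20), sigma = 1,
                        bounds = NULL, denominator = NULL) {
  nbins <- as.integer(nbins)
  if (is.null(bounds)) bounds <- traj$bounds
  origin <- bounds[, 1]
  bin_size <- (bounds[, 2] - bounds[, 1]) / nbins
  den <- if (is.null(denominator)) {
    accumulate_truncated_gaussian(traj$positions, origin, bin_size,
                                  nbins, sigma)
  } else {
    denominator
  }
  num <- if (length(events$idx) > 0) {
    accumulate_truncated_gaussian(events$positions, origin, bin_size,
                                  nbins, sigma)
  } else {
    array(0, dim = nbins)
  }
  rate <- ifelse(den > 0, num / den, 0)
  u <- sweep(sweep(traj$positions, 2, origin), 2, bin_size, `/`)
  vox <- pmin(pmax(floor(u) + 1L, 1L),
              matrix(nbins, nrow(u), 3, byrow = TRUE))
  flat <- (vox[, 3] - 1L) * nbins[1] * nbins[2] +
    (vox[, 2] - 1L) * nbins[1] + vox[, 1]
  occ <- array(tabulate(flat, prod(nbins)), dim = nbins)
  structure(list(rate = rate, occupancy = occ, events = NULL,
                 origin = origin, bin_size = bin_size, dims = 1:3,
                 smoothing = sigma, visited = den > 0),
            class = "rate_map")
}
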