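spatial_info_core <- function(rate, occ) {
  vis <- occ > 0
  if (!any(vis)) stop_undefined("no visited bins")
  P <- occ[vis] / sum(occ[vis])
  R_i <- rate[vis]
  R <- sum(P * R_i)
  if (R <= 0) stop_undefined("overall mean rate is zero")
  pos <- R_i > 0
  sum(P[pos] * (R_i[pos] / R) * log2(R_i[pos] / R))
}

sparsity_core <- function(rate, occ, printed_form = FALSE) {
  vis <- occ > 0
  if (!any(vis)) stop_undefined("no visited bins")
  P <- occ[vis] / sum(occ[vis])
  R_i <- rate[vis]
  R <- sum(P * R_i)
  if (R <= 0) stop_undefined("overall mean rate is zero")
  if (printed_form) {
    sum(P * R_i^2) / R^2
  } else {
    sum(P * R_i)^2 / sum(P * R_i^2)
  }
}

#' Spatial information of a firing-rate map
#'
#' Skaggs spatial information in bits per spike,
#' \deqn{I = \sum_i P_i \frac{R_i}{R} \log_2 \frac{R_i}{R},}
#' where \eqn{P_i} is the occupancy probability of bin i (normalised over
#' visited bins), \eqn{R_i} the bin firing rate and \eqn{R = \sum_i P_i R_i}
#' the overall mean rate. Uniform firing gives 0 bits/spike; firing
#' confined to one of N equally occupied bins gives `log2(N)`.
#'
#' @param map a [rate_map_2d()]/[rate_map_3d()] result, or any list with
#'   `rate` and `occupancy` arrays of matching shape.
#' @return Scalar, bits/spike. Signals an error of class
#'   `"undefined_statistic"` when the mean rate is zero.
#' @export
spatial_information <- function(map) {
  spatial_info_core(map$rate, map$occupancy)
}

#' Sparsity of a firing-rate map
#'
#' Skaggs sparsity \eqn{(\sum_i P_i R_i)^2 / \sum_i P_i R_i^2}, in (0, 1]:
#' 1 for uniform firing over visited bins, `1/N` for firing confined to one
#' of N equally occupied bins. `printed_form = TRUE` instead evaluates
#' \eqn{\sum_i P_i R_i^2 / R^2}, the reciprocal quantity; that form is >= 1
#' for every map and thus cannot fall below a small-sparsity gate, so the
#' Skaggs form is the default used by the classifier.
#'
#' @inheritParams spatial_information
#' @param printed_form evaluate the reciprocal form instead.
#' @return Scalar sparsity.
#' @export
sparsity <- function(map, printed_form = FALSE) {
  sparsity_core(map$rate, map$occupancy, printed_form)
}

#' Graded firing-rate proxy of a bottleneck unit
#'
#' Converts a linear unit's raw activation series into a non-negative
#' firing-rate proxy: the series is mean-centred, its sign is corrected so
#' that the heavier tail points upward (linear units are sign-ambiguous;
#' the third central moment decides), and activity is taken as the amount
#' by which the corrected series exceeds its `threshold_quantile` quantile
#' (rectified at zero). At the default quantile suprathreshold activity
#' occupies about 15% of the samples, comparable to the occupancy fraction
#' of a typical rodent place field in an open arena.
#'
#' @param activations numeric activation series of one unit.
#' @param threshold_quantile quantile of the corrected series used as the
#'   firing threshold.
#' @return Non-negative numeric series of the same length.
#' @export
activation_rate <- function(activations, threshold_quantile = 0.85) {
  a <- as.numeric(activations) - mean(activations)
  if (mean(a^3) < 0) a <- -a
  pmax(a - stats::quantile(a, threshold_quantile, names = FALSE), 0)
}

#' Occupancy-normalised activation map
#'
#' 2D map of the mean of a continuous non-negative rate series per spatial
#' bin (kernel-smoothed numerator over kernel-smoothed occupancy), the
#' continuous analogue of [rate_map_2d()] used for classification and
#' gridness analysis of bottleneck units.
#'
#' @param rate non-negative numeric series aligned with the trajectory
#'   (e.g. from [activation_rate()]).
#' @param traj the matching [trajectory()].
#' @param bins,smoothing,dims as in [rate_map_2d()].
#' @return An object of class `"rate_map"`.
#' @export
activation_map_2d <- function(rate, traj, bins = c(20, 20), smoothing = 1,
                              dims = c(1, 2)) {
  bins <- as.integer(bins)
  bin_flat <- bin_index_2d(traj$positions, traj$bounds, bins, dims)
  occ <- matrix(tabulate(bin_flat, bins[1] * bins[2]), bins[1], bins[2])
  num <- matrix(0, bins[1], bins[2])
  agg <- rowsum(rate, bin_flat)
  num[as.integer(rownames(agg))] <- agg
  Sx <- gauss_smooth_matrix(bins[1], smoothing)
  Sy <- gauss_smooth_matrix(bins[2], smoothing)
  occ_s <- Sx %*% occ %*% Sy
  num_s <- Sx %*% num %*% Sy
  rmap <- ifelse(occ_s > 0, num_s / occ_s, 0)
  b <- traj$bounds
  structure(list(rate = rmap, occupancy = occ, events = NULL,
                 origin = b[dims, 1],
                 bin_size = (b[dims, 2] - b[dims, 1]) / bins,
                 dims = dims, smoothing = smoothing,
                 visited = occ_s > 0),
            class = "rate_map")
}

# Spatial information and sparsity of a shifted rate series, evaluated on
# unsmoothed binned means via a presorted cumulative-sum accumulator (the
# hot loop of the shuffle test). `rate2` is the rate series doubled so a
# circular shift is a plain offset lookup.
stats_from_shifted <- function(rate2, k, TT, ord0, ends, occ_sorted) {
  rr <- rate2[ord0 + (k + 1L)]
  s <- cumsum(rr)
  sums <- diff(c(0, s[ends]))
  rates <- sums / occ_sorted
  P <- occ_sorted / sum(occ_sorted)
  R <- sum(P * rates)
  pos <- rates > 0
  si <- sum(P[pos] * (rates[pos] / R) * log2(rates[pos] / R))
  sp <- R^2 / sum(P * rates^2)
  c(si, sp)
}

#' Circular-shift shuffle null for spatial statistics
#'
#' Breaks the association between activation and position by circularly
#' shifting the unit's firing-rate proxy relative to the trajectory by a
#' uniform random offset (at least `min_shift` samples away from zero in
#' either direction), recomputing spatial information and sparsity for
#' each shuffle. Observed and null statistics are computed by identical
#' machinery on unsmoothed binned rates.
#'
#' @param activations numeric vector of one unit's activations.
#' @param traj the matching [trajectory()].
#' @param n_shuffles number of shuffles (>= 100 for stable percentiles;
#'   1000 by default).
#' @param min_shift minimum shift in samples; defaults to 5% of the series
#'   length.
#' @param seed integer seed.
#' @param rate_quantile firing threshold quantile of [activation_rate()].
#' @param bins,dims spatial binning, as in [rate_map_2d()].
#' @return A list with numeric vectors `spatial_info` and `sparsity` of
#'   length `n_shuffles`, the observed `observed_spatial_info`,
#'   `observed_sparsity` computed identically, and the `shifts` used.
#' @export
shuffle_null <- function(activations, traj, n_shuffles = 1000,
                         min_shift = NULL, seed = 1, rate_quantile = 0.85,
                         bins = c(20, 20), dims = c(1, 2)) {
  TT <- nrow(traj$positions)
  if (is.null(min_shift)) min_shift <- max(1L, floor(0.05 * TT))
  if (TT < 2 * min_shift) stop_invalid("trajectory shorter than 2 * min_shift")
  bins <- as.integer(bins)
  rate <- activation_rate(activations, rate_quantile)
  bin_flat <- bin_index_2d(traj$positions, traj$bounds, bins, dims)
  ord <- order(bin_flat)
  ord0 <- ord - 1L
  occ_all <- tabulate(bin_flat, bins[1] * bins[2])
  occupied <- which(occ_all > 0)
  ends <- cumsum(occ_all[occupied])
  occ_sorted <- occ_all[occupied]
  rate2 <- c(rate, rate)
  obs <- stats_from_shifted(rate2, 0L, TT, ord0, ends, occ_sorted)
  with_seed(seed, {
    shifts <- sample(seq.int(min_shift, TT - min_shift), n_shuffles,
                     replace = TRUE)
    null <- vapply(shifts, stats_from_shifted, numeric(2), rate2 = rate2,
                   TT = TT, ord0 = ord0, ends = ends,
                   occ_sorted = occ_sorted)
  })
  list(spatial_info = null[1, ], sparsity = null[2, ],
       observed_spatial_info = obs[1], observed_sparsity = obs[2],
       shifts = shifts)
}

#' Place-cell classification gates
#'
#' A unit is classified as a place cell when all four gates pass: spatial
#' information above 0.3 bits/spike, sparsity below 0.1, spatial
#' information above the 99th percentile of its shuffle null, and sparsity
#' below the 1st percentile of its shuffle null.
#'
#' @param stats a list with `spatial_info`, `sparsity` (observed scalars)
#'   and `null_spatial_info`, `null_sparsity` (shuffle vectors), e.g.
#'   assembled from [shuffle_null()].
#' @param info_gate,sparsity_gate absolute thresholds of the first two
#'   gates.
#' @return Logical scalar.
#' @export
classify_place_cell <- function(stats, info_gate = 0.3,
                                sparsity_gate = 0.1) {
  si <- stats$spatial_info
  sp <- stats$sparsity
  if (is.na(si) || is.na(sp)) return(FALSE)
  si > info_gate && sp < sparsity_gate &&
    si > stats::quantile(stats$null_spatial_info, 0.99, names = FALSE) &&
    sp < stats::quantile(stats$null_sparsity, 0.01, names = FALSE)
}

#' Spatial autocorrelogram of a 2D rate map
#'
#' Pearson correlation of the map with itself at every integer spatial lag,
#' computed over the overlapping pixels of the shifted copies; lags whose
#' overlap is below `min_overlap` pixels (or whose overlap has zero
#' variance) are undefined (NA). The result is symmetric under lag negation
#' and equals 1 at zero lag.
#'
#' @param map a 2D [rate_map_2d()] result or a numeric matrix.
#' @param min_overlap minimum number of overlapping pixels per lag.
#' @return A `(2 nx - 1) x (2 ny - 1)` matrix of class `"autocorrelogram"`
#'   with attribute `"center"` (index of the zero lag).
#' @export
autocorrelogram <- function(map, min_overlap = 20) {
  lam <- if (inherits(map, "rate_map")) map$rate else as.matrix(map)
  if (length(dim(lam)) != 2) stop_invalid("autocorrelogram needs a 2D map")
  n1 <- nrow(lam); n2 <- ncol(lam)
  out <- matrix(NA_real_, 2 * n1 - 1, 2 * n2 - 1)
  for (tx in -(n1 - 1):(n1 - 1)) {
    xs <- max(1, 1 + tx):min(n1, n1 + tx)
    for (ty in -(n2 - 1):(n2 - 1)) {
      ys <- max(1, 1 + ty):min(n2, n2 + ty)
      if (length(xs) * length(ys) < min_overlap) next
      a <- lam[xs, ys]
      b <- lam[xs - tx, ys - ty]
      sa <- stats::sd(a); sb <- stats::sd(b)
      if (sa == 0 || sb == 0) next
      out[tx + n1, ty + n2] <- stats::cor(as.vector(a), as.vector(b))
    }
  }
  structure(out, center = c(n1, n2), class = c("autocorrelogram", "matrix"))
}

# Rotate a (possibly NA-holed) matrix about its centre by `angle` radians
# using bilinear interpolation; NA wherever any contributing source pixel
# is NA or out of range.
rotate_matrix <- function(M, angle, center = (dim(M) + 1) / 2) {
  n1 <- nrow(M); n2 <- ncol(M)
  grid <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  dx <- grid$i - center[1]; dy <- grid$j - center[2]
  # source coordinate = inverse rotation of target coordinate
  sx <- center[1] + cos(angle) * dx + sin(angle) * dy
  sy <- center[2] - sin(angle) * dx + cos(angle) * dy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- rep(NA_real_, length(sx))
  ok <- x0 >= 1 & x0 + 1 <= n1 & y0 >= 1 & y0 + 1 <= n2
  if (any(ok)) {
    idx <- function(i, j) (j - 1L) * n1 + i
    m <- as.vector(M)
    v00 <- m[idx(x0[ok], y0[ok])]
    v10 <- m[idx(x0[ok] + 1L, y0[ok])]
    v01 <- m[idx(x0[ok], y0[ok] + 1L)]
    v11 <- m[idx(x0[ok] + 1L, y0[ok] + 1L)]
    val[ok] <- v00 * (1 - fx[ok]) * (1 - fy[ok]) +
      v10 * fx[ok] * (1 - fy[ok]) +
      v01 * (1 - fx[ok]) * fy[ok] +
      v11 * fx[ok] * fy[ok]
  }
  matrix(val, n1, n2)
}

# Radius (in lag units) of the first local minimum of the radial mean of
# the autocorrelogram, used to mask out the central peak.
first_radial_minimum <- function(ac) {
  center <- attr(ac, "center")
  n1 <- nrow(ac); n2 <- ncol(ac)
  rr <- sqrt(outer((seq_len(n1) - center[1])^2,
                   (seq_len(n2) - center[2])^2, `+`))
  rmax <- floor(min(n1, n2) / 2)
  prof <- vapply(0:rmax, function(r) {
    sel <- rr >= r - 0.5 & rr < r + 0.5 & !is.na(ac)
    if (!any(sel)) NA_real_ else mean(ac[sel])
  }, numeric(1))
  for (r in 2:(length(prof) - 1)) {
    if (!is.na(prof[r]) && !is.na(prof[r + 1]) && prof[r + 1] >= prof[r]) {
      return(r - 1)
    }
  }
  max(2, floor(rmax / 4))
}

#' Hexagonal and square grid scores
#'
#' Rotate-and-correlate gridness of an autocorrelogram, evaluated on an
#' annulus that excludes the central peak (inner radius at the first
#' minimum of the radial mean):
#' \deqn{HGS = \min[cor(r, r^{60}), cor(r, r^{120})] -
#'   \max[cor(r, r^{30}), cor(r, r^{90}), cor(r, r^{150})]}
#' \deqn{SGS = cor(r, r^{90}) - \max[cor(r, r^{45}), cor(r, r^{135})]}
#' where \eqn{r^\theta} is the autocorrelogram rotated by \eqn{\theta}
#' degrees about the zero lag.
#'
#' @param ac an [autocorrelogram()].
#' @param inner_radius optional annulus inner radius (lag units); computed
#'   from the radial profile when `NULL`.
#' @return A list of class `"grid_scores"` with `hgs`, `sgs`, the rotation
#'   correlations `rot_cor`, and `inner_radius`. Signals
#'   `"undefined_statistic"` for a degenerate (constant) autocorrelogram.
#' @export
grid_scores <- function(ac, inner_radius = NULL) {
  if (all(is.na(ac)) || stats::sd(ac, na.rm = TRUE) == 0) {
    stop_undefined("degenerate autocorrelogram")
  }
  center <- attr(ac, "center")
  if (is.null(center)) center <- (dim(ac) + 1) / 2
  n1 <- nrow(ac); n2 <- ncol(ac)
  rr <- sqrt(outer((seq_len(n1) - center[1])^2,
                   (seq_len(n2) - center[2])^2, `+`))
  if (is.null(inner_radius)) inner_radius <- first_radial_minimum(ac)
  rmax <- floor(min(n1, n2) / 2)
  annulus <- rr > inner_radius & rr <= rmax
  angles <- c(30, 45, 60, 90, 120, 135, 150)
  rot_cor <- vapply(angles, function(a) {
    rot <- rotate_matrix(unclass(ac), a * pi / 180, center)
    sel <- annulus & !is.na(ac) & !is.na(rot)
    if (sum(sel) < 20) return(NA_real_)
    if (stats::sd(ac[sel]) == 0 || stats::sd(rot[sel]) == 0) return(NA_real_)
    stats::cor(ac[sel], rot[sel])
  }, numeric(1))
  names(rot_cor) <- paste0("r", angles)
  hgs <- min(rot_cor["r60"], rot_cor["r120"]) -
    max(rot_cor["r30"], rot_cor["r90"], rot_cor["r150"])
  sgs <- rot_cor["r90"] - max(rot_cor["r45"], rot_cor["r135"])
  structure(list(hgs = unname(hgs), sgs = unname(sgs), rot_cor = rot_cor,
                 inner_radius = inner_radius),
            class = "grid_scores")
}

#' @export
print.grid_scores <- function(x, ...) {
  cat(sprintf("<grid_scores: HGS %.3f, SGS %.3f (annulus inner radius %g)>\n",
              x$hgs, x$sgs, x$inner_radius))
  invisible(x)
}

#' Grid-cell classification
#'
#' Units with a hexagonal grid score above 0.3 are hexagonal grid cells and
#' units with a square grid score above 0.3 are square grid cells (the
#' larger score wins when both pass); downstream analyses keep only the
#' hexagonal class.
#'
#' @param scores a [grid_scores()] result.
#' @param gate score threshold.
#' @return `"hexagonal"`, `"square"` or `"none"`.
#' @export
classify_grid_cell <- function(scores, gate = 0.3) {
  hgs <- scores$hgs; sgs <- scores$sgs
  if (is.na(hgs)) hgs <- -Inf
  if (is.na(sgs)) sgs <- -Inf
  if (hgs > gate && hgs >= sgs) "hexagonal"
  else if (sgs > gate && sgs > hgs) "square"
  else "none"
}

#' Classify all bottleneck units of a trained model
#'
#' Applies the full classification battery to every column of an activation
#' matrix on a flat-arena trajectory: the graded firing-rate proxy of
#' [activation_rate()], spatial information and sparsity on unsmoothed
#' binned rates with their circular-shift shuffle nulls and the four
#' place-cell gates, and the rotational gridness scores (computed on the
#' smoothed activation map) with the hexagonal/square gates.
#'
#' @param activations T x k matrix of bottleneck activations.
#' @param traj the flat-arena [trajectory()].
#' @param rate_quantile firing threshold quantile of [activation_rate()].
#' @param bins spatial binning.
#' @param smoothing kernel width (bins) of the gridness map.
#' @param n_shuffles shuffle count per unit.
#' @param seed integer seed for the shuffle offsets.
#' @return A data frame of class `"unit_classification"` with one row per
#'   unit: `unit`, `spatial_info`, `sparsity`, `null_info_q99`,
#'   `null_sparsity_q01`, `hgs`, `sgs`, `is_place`, `grid_class`.
#' @export
classify_units <- function(activations, traj, rate_quantile = 0.85,
                           bins = c(20, 20), smoothing = 1,
                           n_shuffles = 1000, seed = 1) {
  k <- ncol(activations)
  rows <- lapply(seq_len(k), function(j) {
    a <- activations[, j]
    if (max(a) == min(a)) {
      return(data.frame(unit = j, spatial_info = NA_real_,
                        sparsity = NA_real_, null_info_q99 = NA_real_,
                        null_sparsity_q01 = NA_real_, hgs = NA_real_,
                        sgs = NA_real_, is_place = FALSE,
                        grid_class = "none"))
    }
    nul <- shuffle_null(a, traj, n_shuffles = n_shuffles,
                        seed = child_seed(seed, j),
                        rate_quantile = rate_quantile, bins = bins)
    is_place <- classify_place_cell(list(
      spatial_info = nul$observed_spatial_info,
      sparsity = nul$observed_sparsity,
      null_spatial_info = nul$spatial_info,
      null_sparsity = nul$sparsity))
    map <- activation_map_2d(activation_rate(a, rate_quantile), traj,
                             bins = bins, smoothing = smoothing)
    gs <- tryCatch(grid_scores(autocorrelogram(map)),
                   undefined_statistic = function(e) {
                     list(hgs = NA_real_, sgs = NA_real_)
                   })
    data.frame(unit = j, spatial_info = nul$observed_spatial_info,
               sparsity = nul$observed_sparsity,
               null_info_q99 = stats::quantile(nul$spatial_info, 0.99,
                                               names = FALSE),
               null_sparsity_q01 = stats::quantile(nul$sparsity, 0.01,
                                                   names = FALSE),
               hgs = gs$hgs, sgs = gs$sgs, is_place = is_place,
               grid_class = classify_grid_cell(gs))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("unit_classification", "data.frame")
  out
}

#' @export
print.unit_classification <- function(x, ...) {
  cat(sprintf("<unit_classification: %d units, %d place cells, %d hexagonal grid cells>\n",
              nrow(x), sum(x$is_place), sum(x$grid_class == "hexagonal")))
  NextMethod()
}
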