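#' Second-moment ellipse axes of a 2D field
#'
#' Major and minor axis lengths of the ellipse fitted to a set of 2D
#' points (typically supra-threshold bin centres), from the eigenvalues of
#' their covariance: length = 4 standard deviations along each principal
#' direction, with the minor axis floored at one bin width so collinear
#' bins do not yield a degenerate ellipse.
#'
#' @param points n x 2 matrix of coordinates in maze units (n >= 3).
#' @param bin_width floor for the minor axis.
#' @return A list with `major`, `minor`, `aspect` (= major/minor),
#'   `orientation` (radians of the major axis) and `centroid`.
#' @export
field_axes_2d <- function(points, bin_width = 0) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop_invalid("need at least 3 points")
  cv <- stats::cov(points)
  eg <- eigen(cv, symmetric = TRUE)
  len <- 4 * sqrt(pmax(eg$values, 0))
  len <- pmax(len, bin_width)
  list(major = len[1], minor = len[2], aspect = len[1] / max(len[2], 1e-12),
       orientation = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       centroid = colMeans(points))
}

#' Extract 2D firing fields from a binned rate map
#'
#' Binarises the map at a fraction of its peak rate, labels 8-connected
#' components of supra-threshold bins and keeps those with at least
#' `min_bins` bins; each field's axes come from the second-moment ellipse
#' of its bin centres.
#'
#' @param map a 2D [rate_map_2d()] result.
#' @param rate_threshold binarisation threshold as a fraction of peak rate.
#' @param min_bins minimum component size in bins.
#' @return A list of `"firing_field_2d"` objects with `bins` (flat
#'   indices), `n_bins`, `centroid`, `major`, `minor`, `aspect`,
#'   `orientation`, `bin_centers`.
#' @export
extract_fields_2d <- function(map, rate_threshold = 0.2, min_bins = 3) {
  rate <- map$rate
  peak <- max(rate)
  if (peak <= 0) return(list())
  mask <- rate >= rate_threshold * peak & map$visited
  labels <- label_components(mask, "full")
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_bins)
  lapply(keep, function(lb) {
    idx <- which(labels == lb)
    co <- arrayInd(idx, dim(rate))
    centers <- sweep(sweep(co - 0.5, 2, map$bin_size, `*`), 2, map$origin,
                     `+`)
    ax <- field_axes_2d(centers, bin_width = min(map$bin_size))
    structure(c(list(bins = idx, n_bins = length(idx),
                     bin_centers = centers, dim = dim(rate)), ax),
              class = "firing_field_2d")
  })
}

#' @export
print.firing_field_2d <- function(x, ...) {
  cat(sprintf("<firing_field_2d: %d bins, centroid (%.2f, %.2f), aspect %.2f>\n",
              x$n_bins, x$centroid[1], x$centroid[2], x$aspect))
  invisible(x)
}

# Unwound angular coordinate of a helical trajectory: cumulative unwrap of
# atan2(y, x), shifted to start at 0 and made monotonically non-negative.
helix_unwound_angle <- function(pos) {
  th <- atan2(pos[, 2], pos[, 1])
  dth <- diff(th)
  dth <- (dth + pi) %% (2 * pi) - pi
  un <- cumsum(c(0, dth))
  un <- un - un[1]
  if (un[length(un)] < 0) un <- -un  # descending traversal: unwind forward
  un
}

#' Unwind a helical run into per-coil linear firing profiles
#'
#' Each of the five coils is unwound and divided into 60 angular position
#' bins; the profile is the per-bin event rate (event count over occupancy
#' count) on each coil.
#'
#' @param events a [threshold_events()] result on a helical trajectory.
#' @param traj the helical [trajectory()] (maze_id `"helix_up"` or
#'   `"helix_down"`).
#' @param n_bins position bins per coil.
#' @param n_coils number of coils.
#' @return An object of class `"coil_profile"`: `rate` (n_coils x n_bins),
#'   `events`, `occupancy` (same shape, raw counts), `n_bins`, `n_coils`.
#' @export
unwind_helix <- function(events, traj, n_bins = 60, n_coils = 5) {
  if (!grepl("^helix", traj$maze_id)) {
    stop_invalid("unwind_helix needs a helical trajectory")
  }
  un <- helix_unwound_angle(traj$positions)
  coil <- pmin(pmax(floor(un / (2 * pi)) + 1L, 1L), n_coils)
  bin <- floor((un %% (2 * pi)) / (2 * pi / n_bins)) + 1L
  bin <- pmin(bin, n_bins)
  flat <- (coil - 1L) * n_bins + bin
  occ <- t(matrix(tabulate(flat, n_coils * n_bins), n_bins, n_coils))
  ev <- if (length(events$idx) > 0) {
    t(matrix(tabulate(flat[events$idx], n_coils * n_bins), n_bins, n_coils))
  } else {
    matrix(0L, n_coils, n_bins)
  }
  rate <- ifelse(occ > 0, ev / occ, 0)
  structure(list(rate = rate, events = ev, occupancy = occ,
                 n_bins = n_bins, n_coils = n_coils,
                 point_coil = coil, point_bin = bin,
                 event_idx = events$idx),
            class = "coil_profile")
}

#' @export
print.coil_profile <- function(x, ...) {
  cat(sprintf("<coil_profile: %d coils x %d bins, %d events>\n",
              x$n_coils, x$n_bins, sum(x$events)))
  invisible(x)
}

# Combine coil profiles of several runs (e.g. an up and a down traversal)
# by summing raw counts.
combine_coil_profiles <- function(profiles) {
  ev <- Reduce(`+`, lapply(profiles, `[[`, "events"))
  occ <- Reduce(`+`, lapply(profiles, `[[`, "occupancy"))
  rate <- ifelse(occ > 0, ev / occ, 0)
  structure(list(rate = rate, events = ev, occupancy = occ,
                 n_bins = profiles[[1]]$n_bins,
                 n_coils = profiles[[1]]$n_coils),
            class = "coil_profile")
}

#' Helical firing fields by coil-wise detection and cross-coil merging
#'
#' Detects supra-threshold runs of angular bins on each unwound coil
#' (circular in the bin index) and merges per-coil fields lying at similar
#' (x, y) track positions across coils into single helical fields, since a
#' field at a fixed (x, y) recurs on every coil it spans. Field axes come
#' from the second moments of the member firing-event positions in 3D
#' (major = longest extent, minor = shortest), each extent being 4
#' standard deviations floored at one angular bin's arc length.
#'
#' @param profile a (possibly [combine_coil_profiles()]-combined)
#'   [unwind_helix()] profile.
#' @param event_points optional matrix/data frame with columns `coil`,
#'   `bin`, `x`, `y`, `z` giving each firing event's unwound assignment
#'   and position (see [helix_event_points()]); when omitted, geometry
#'   falls back to angular bin centres at the track-centre radius.
#' @param rate_threshold detection threshold as a fraction of the profile
#'   peak rate.
#' @param smoothing circular Gaussian smoothing (standard deviation in
#'   bins) applied to each coil's profile before detection; 0 disables.
#' @param min_bins minimum run length in bins.
#' @param merge_radius (x, y) distance below which per-coil fields merge.
#' @param track_radius,height,n_coils helix geometry.
#' @return A list of `"helix_field"` objects with `coils`,
#'   `n_coils_spanned`, `segments`, `centroid_xy`, `major`, `minor`,
#'   `aspect`.
#' @export
helix_fields <- function(profile, event_points = NULL, rate_threshold = 0.2,
                         smoothing = 1, min_bins = 2, merge_radius = 0.3,
                         track_radius = 0.75, height = 5, n_coils = 5) {
  rate <- profile$rate
  if (smoothing > 0) {
    rate <- t(apply(rate, 1, smooth_circular, sigma = smoothing))
  }
  peak <- max(rate)
  if (peak <= 0) return(list())
  n_bins <- profile$n_bins
  segs <- list()
  for (c_ in seq_len(n_coils)) {
    above <- rate[c_, ] >= rate_threshold * peak
    if (!any(above)) next
    for (r in circular_runs(above)) {
      if (length(r) < min_bins) next
      segs[[length(segs) + 1]] <- list(coil = c_, bins = r)
    }
  }
  if (length(segs) == 0) return(list())
  seg_xy <- t(vapply(segs, function(s) {
    ang <- (s$bins - 0.5) / n_bins * 2 * pi
    c(mean(track_radius * cos(ang)), mean(track_radius * sin(ang)))
  }, numeric(2)))
  n <- length(segs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # two per-coil fields are "at similar (x, y)" when their angular bin
  # intervals overlap, or their track-plane centroids are close
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      same_spot <- length(intersect(segs[[i]]$bins, segs[[j]]$bins)) > 0 ||
        sqrt(sum((seg_xy[i, ] - seg_xy[j, ])^2)) < merge_radius
      if (same_spot) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  arc <- track_radius * 2 * pi / n_bins
  lapply(unique(roots), function(rt) {
    members <- segs[roots == rt]
    coils <- sort(unique(vapply(members, `[[`, integer(1), "coil")))
    pts <- if (!is.null(event_points)) {
      keyed <- paste(event_points[, "coil"], event_points[, "bin"])
      want <- unlist(lapply(members, function(s) paste(s$coil, s$bins)))
      as.matrix(event_points[keyed %in% want, c("x", "y", "z"),
                             drop = FALSE])
    } else {
      do.call(rbind, lapply(members, function(s) {
        ang <- (s$bins - 0.5) / n_bins * 2 * pi
        un <- (s$coil - 1) * 2 * pi + ang
        cbind(track_radius * cos(ang), track_radius * sin(ang),
              height * un / (n_coils * 2 * pi))
      }))
    }
    geom <- if (!is.null(pts) && nrow(pts) >= 3) {
      eg <- eigen(stats::cov(pts), symmetric = TRUE)
      len <- pmax(4 * sqrt(pmax(eg$values, 0)), arc)
      list(major = len[1], minor = len[3])
    } else {
      list(major = arc, minor = arc)
    }
    structure(list(coils = coils, n_coils_spanned = length(coils),
                   segments = members,
                   centroid_xy = colMeans(seg_xy[roots == rt, ,
                                                 drop = FALSE]),
                   major = geom$major, minor = geom$minor,
                   aspect = geom$major / geom$minor),
              class = "helix_field")
  })
}

#' Event coordinates of unwound helical runs
#'
#' Assembles the per-event (coil, bin, x, y, z) table consumed by
#' [helix_fields()] from one or more unwound runs and their trajectories.
#'
#' @param profiles list of [unwind_helix()] results (one per run).
#' @param trajs matching list of helical trajectories.
#' @return Data frame with columns `coil`, `bin`, `x`, `y`, `z`.
#' @export
helix_event_points <- function(profiles, trajs) {
  do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    idx <- p$event_idx
    data.frame(coil = p$point_coil[idx], bin = p$point_bin[idx],
               x = trajs[[i]]$positions[idx, 1],
               y = trajs[[i]]$positions[idx, 2],
               z = trajs[[i]]$positions[idx, 3])
  }))
}

# Gaussian smoothing of a 1D profile with circular (wrap-around) boundary.
smooth_circular <- function(x, sigma) {
  n <- length(x)
  d <- pmin(abs(seq_len(n) - 1), n - abs(seq_len(n) - 1))
  k <- exp(-d^2 / (2 * sigma^2))
  k[d > ceiling(3 * sigma)] <- 0
  k <- k / sum(k)
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / n
}

# Maximal runs of TRUE in a circular logical vector, as lists of indices.
circular_runs <- function(x) {
  n <- length(x)
  if (all(x)) return(list(seq_len(n)))
  if (!any(x)) return(list())
  # rotate so position 1 is FALSE, find linear runs, rotate back
  off <- which(!x)[1]
  xr <- x[((seq_len(n) + off - 2L) %% n) + 1L]
  r <- rle(xr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(k) {
    ((starts[k]:ends[k] + off - 2L) %% n) + 1L
  })
}

#' Axis-wise spatial information of a 2D map
#'
#' Collapses the rate map into a linear profile by averaging over all
#' columns (for information about the row coordinate) or all rows (for the
#' column coordinate), collapses occupancy by summation, and evaluates the
#' spatial-information formula on the 1D profile. Used on the pegboard to
#' compare horizontal against vertical information content.
#'
#' @param map a 2D [rate_map_2d()] result (dimension 1 = horizontal,
#'   dimension 2 = vertical for a board-plane map).
#' @param axis `"horizontal"` (information about dimension 1) or
#'   `"vertical"` (dimension 2).
#' @return Scalar bits/spike.
#' @export
axis_spatial_information <- function(map, axis = c("horizontal",
                                                   "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") {
    prof <- rowMeans(map$rate)
    occ <- rowSums(map$occupancy)
  } else {
    prof <- colMeans(map$rate)
    occ <- colSums(map$occupancy)
  }
  spatial_info_core(prof, occ)
}

#' Vertical layers spanned by a field
#'
#' Divides the board height into `n_layers` equal layers and counts how
#' many layers the field's bins overlap.
#'
#' @param field a `"firing_field_2d"` whose second map dimension is the
#'   vertical coordinate.
#' @param z_range total vertical extent of the board, length-2.
#' @param n_layers number of layers.
#' @return Integer count in 1..n_layers.
#' @export
count_vertical_layers <- function(field, z_range = c(0, 10), n_layers = 5) {
  co <- arrayInd(field$bins, field$dim)
  bw <- (z_range[2] - z_range[1]) / field$dim[2]
  zlo <- z_range[1] + (co[, 2] - 1) * bw
  zhi <- zlo + bw
  edges <- seq(z_range[1], z_range[2], length.out = n_layers + 1)
  sum(vapply(seq_len(n_layers), function(l) {
    any(zhi > edges[l] & zlo < edges[l + 1])
  }, logical(1)))
}

#' Two-sample and one-sample t tests
#'
#' Classical Student's t tests (pooled variance for two samples,
#' two-sided) as used for the field-geometry comparisons; thin wrappers
#' over [stats::t.test()] returning the statistic, degrees of freedom and
#' p value.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param x numeric sample; `mu` the null mean.
#' @param mu null-hypothesis mean for the one-sample test.
#' @return A list with `t`, `dof`, `p`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_invalid("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, dof = length(a) +
                                          length(b) - 2, p = 1))
    stop_undefined("zero variance in both samples")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value)
}

#' @rdname two_sample_t
#' @export
one_sample_t <- function(x, mu = 1) {
  if (length(x) < 2) stop_invalid("sample needs n >= 2")
  if (stats::sd(x) == 0) {
    if (mean(x) == mu) return(list(t = 0, dof = length(x) - 1, p = 1))
    stop_undefined("zero variance sample")
  }
  ht <- stats::t.test(x, mu = mu)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value)
}
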