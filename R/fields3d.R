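# Label connected components of a logical 2D/3D array by breadth-first
# flood fill. `connectivity` is the maximum Chebyshev neighbourhood:
# "full" links all diagonal neighbours (8 in 2D, 26 in 3D), "face" only
# axis neighbours.
label_components <- function(mask, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  dims <- dim(mask)
  nd <- length(dims)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == "face") {
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  }
  labels <- array(0L, dims)
  idx_all <- which(mask)
  if (length(idx_all) == 0) return(labels)
  coord <- arrayInd(idx_all, dims)
  in_mask <- array(FALSE, dims)
  in_mask[idx_all] <- TRUE
  strides <- cumprod(c(1, dims[-nd]))
  flat_of <- function(co) as.integer((co - 1) %*% strides + 1)
  lab <- 0L
  for (s in seq_along(idx_all)) {
    start <- idx_all[s]
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- matrix(coord[s, ], 1)
    labels[start] <- lab
    while (nrow(queue) > 0) {
      nxt <- NULL
      for (k in seq_len(nrow(offs))) {
        nb <- sweep(queue, 2, offs[k, ], `+`)
        ok <- rowSums(nb >= 1 & nb <= matrix(dims, nrow(nb), nd,
                                             byrow = TRUE)) == nd
        if (!any(ok)) next
        nb <- nb[ok, , drop = FALSE]
        fl <- flat_of(nb)
        new <- in_mask[fl] & labels[fl] == 0L
        if (any(new)) {
          labels[fl[new]] <- lab
          nxt <- rbind(nxt, nb[new, , drop = FALSE])
        }
      }
      queue <- if (is.null(nxt)) matrix(numeric(0), 0, nd) else unique(nxt)
    }
  }
  labels
}

field_geometry <- function(centers, bin_size) {
  centroid <- colMeans(centers)
  cv <- stats::cov(centers)
  if (any(!is.finite(cv))) cv <- matrix(0, ncol(centers), ncol(centers))
  eg <- eigen(cv, symmetric = TRUE)
  extents <- 4 * sqrt(pmax(eg$values, 0))
  floor_len <- min(bin_size)
  extents <- pmax(extents, floor_len)
  list(centroid = centroid, axes = eg$vectors, extents = extents)
}

#' Extract 3D firing fields from a voxel rate map
#'
#' Binarises the map at a fraction of its peak rate, labels 26-connected
#' components of supra-threshold voxels, and keeps components larger than
#' `min_voxels` voxels as firing fields. Each field's centroid and
#' principal axes come from the second moments of its voxel centres; the
#' extent along each axis is 4 standard deviations (+/- 2 SD), floored at
#' one voxel.
#'
#' @param map a [rate_map_3d()] result.
#' @param rate_threshold binarisation threshold as a fraction of the peak
#'   rate.
#' @param min_voxels minimum component size (strictly greater than).
#' @return A list of `"firing_field_3d"` objects, each with `voxels`
#'   (flat indices), `n_voxels`, `centroid`, `axes` (columns, descending
#'   extent), `extents`, `elongation`.
#' @export
extract_fields_3d <- function(map, rate_threshold = 0.2, min_voxels = 50) {
  rate <- map$rate
  peak <- max(rate)
  if (peak <= 0) return(list())
  mask <- rate >= rate_threshold * peak
  labels <- label_components(mask, "full")
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes > min_voxels)
  lapply(keep, function(lb) {
    vox <- which(labels == lb)
    co <- arrayInd(vox, dim(rate))
    centers <- sweep(sweep(co - 0.5, 2, map$bin_size, `*`), 2, map$origin,
                     `+`)
    g <- field_geometry(centers, map$bin_size)
    structure(list(voxels = vox, n_voxels = length(vox),
                   centroid = g$centroid, axes = g$axes,
                   extents = g$extents,
                   elongation = elongation_index(g$extents),
                   dim = dim(rate)),
              class = "firing_field_3d")
  })
}

#' @export
print.firing_field_3d <- function(x, ...) {
  cat(sprintf("<firing_field_3d: %d voxels, centroid (%.2f, %.2f, %.2f), elongation %.2f>\n",
              x$n_voxels, x$centroid[1], x$centroid[2], x$centroid[3],
              x$elongation))
  invisible(x)
}

#' Elongation index of a 3D field
#'
#' Longest principal extent divided by the geometric mean of the other two;
#' 1 for a spherical field, larger for elongated fields.
#'
#' @param field a `"firing_field_3d"` or a numeric vector of three extents.
#' @return Scalar >= 1 when extents are sorted descending.
#' @export
elongation_index <- function(field) {
  ext <- if (inherits(field, "firing_field_3d")) field$extents else field
  ext <- sort(ext, decreasing = TRUE)
  ext[1] / sqrt(ext[2] * ext[3])
}

#' Centroid-distribution shuffle test
#'
#' Tests whether field centroids are uniformly distributed over the maze:
#' the observed per-axis median of the N field centroids is compared with
#' the distribution of medians of N uniform random points in the maze frame
#' (1000 draws by default); the observed median should fall between the
#' 2.5th and 97.5th percentiles of that null.
#'
#' @param fields list of fields from [extract_fields_3d()].
#' @param bounds 3 x 2 maze bounds (in the sampling frame).
#' @param n_shuffles number of null draws.
#' @param seed integer seed.
#' @param rotation,center optional rotation applied to the uniform samples
#'   about `center` (for the tilted lattice, where the maze frame is
#'   rotated in world coordinates).
#' @return A list with `observed` (per-axis medians), `lower`, `upper`
#'   (2.5/97.5 percentiles of the null) and `inside` (logical per axis).
#' @export
centroid_distribution_test <- function(fields, bounds, n_shuffles = 1000,
                                       seed = 1, rotation = NULL,
                                       center = NULL) {
  if (length(fields) == 0) stop_undefined("no fields")
  cent <- t(vapply(fields, function(f) f$centroid, numeric(3)))
  observed <- apply(cent, 2, stats::median)
  N <- nrow(cent)
  with_seed(seed, {
    null_med <- t(vapply(seq_len(n_shuffles), function(s) {
      pts <- cbind(stats::runif(N, bounds[1, 1], bounds[1, 2]),
                   stats::runif(N, bounds[2, 1], bounds[2, 2]),
                   stats::runif(N, bounds[3, 1], bounds[3, 2]))
      if (!is.null(rotation)) {
        pts <- sweep(sweep(pts, 2, center) %*% t(rotation), 2, center, `+`)
      }
      apply(pts, 2, stats::median)
    }, numeric(3)))
  })
  lower <- apply(null_med, 2, stats::quantile, 0.025, names = FALSE)
  upper <- apply(null_med, 2, stats::quantile, 0.975, names = FALSE)
  list(observed = observed, lower = lower, upper = upper,
       inside = observed >= lower & observed <= upper)
}

angle_to_axis <- function(v, axis) {
  ca <- abs(sum(v * axis)) / sqrt(sum(v^2) * sum(axis^2))
  acos(pmin(pmax(ca, -1), 1))
}

#' Field-orientation statistics against one or two axis frames
#'
#' Projects each field's first principal axis onto the unit sphere
#' (antipodally symmetric) and counts the fields oriented within an
#' angular tolerance of each axis of the given frame(s). A chance band per
#' axis comes from drawing the same number of uniformly random orientations
#' `n_uniform` times; when two frames are given, the ratio of counts
#' (first frame / second frame) is compared with the 1st/99th percentiles
#' of its null.
#'
#' @param fields list of fields with an `axes` matrix (first column = first
#'   principal axis).
#' @param frames named list of 3 x 3 orthonormal frames (columns are axes),
#'   e.g. `list(XYZ = diag(3), ABC = rotation)`.
#' @param tolerance angular tolerance in radians (30 degrees by default).
#' @param n_uniform number of null draws.
#' @param seed integer seed.
#' @return A list with per-frame counts, the chance percentiles
#'   (`chance_lower`, `chance_median`, `chance_upper`), and when two frames
#'   are present `ratio`, `ratio_null_q01`, `ratio_null_q99`.
#' @export
orientation_stats <- function(fields, frames = list(XYZ = diag(3)),
                              tolerance = pi / 6, n_uniform = 1000,
                              seed = 1) {
  if (length(fields) == 0) stop_undefined("no fields")
  axes1 <- t(vapply(fields, function(f) f$axes[, 1], numeric(3)))
  N <- nrow(axes1)
  count_along <- function(dirs, frame) {
    vapply(seq_len(ncol(frame)), function(a) {
      sum(apply(dirs, 1, angle_to_axis, axis = frame[, a]) <= tolerance)
    }, numeric(1))
  }
  counts <- lapply(frames, function(fr) count_along(axes1, fr))
  with_seed(seed, {
    null_counts <- vapply(seq_len(n_uniform), function(s) {
      d <- matrix(stats::rnorm(3 * N), N, 3)
      d <- d / sqrt(rowSums(d^2))
      per_frame <- lapply(frames, function(fr) count_along(d, fr))
      c(per_axis = per_frame[[1]][1],
        ratio = if (length(frames) >= 2) {
          sum(per_frame[[1]]) / max(sum(per_frame[[2]]), 1)
        } else NA_real_)
    }, numeric(2))
  })
  out <- list(counts = counts, n_fields = N, tolerance = tolerance,
              chance_lower = stats::quantile(null_counts[1, ], 0.025,
                                             names = FALSE),
              chance_median = stats::median(null_counts[1, ]),
              chance_upper = stats::quantile(null_counts[1, ], 0.975,
                                             names = FALSE))
  if (length(frames) >= 2) {
    out$ratio <- sum(counts[[1]]) / max(sum(counts[[2]]), 1)
    out$ratio_null_q01 <- stats::quantile(null_counts[2, ], 0.01,
                                          names = FALSE)
    out$ratio_null_q99 <- stats::quantile(null_counts[2, ], 0.99,
                                          names = FALSE)
  }
  out
}

# Erode a binary array with a line structuring element of `len` voxels
# along `axis`: a voxel survives iff the window of `len` voxels starting at
# it along that axis is entirely inside the field.
erode_line <- function(vol, axis, len) {
  if (len <= 1) return(vol)
  dims <- dim(vol)
  out <- vol
  for (s in seq_len(len - 1)) {
    shifted <- array(FALSE, dims)
    n <- dims[axis]
    if (s >= n) return(array(FALSE, dims))
    src <- slice.index(vol, axis) > s
    dst <- slice.index(vol, axis) <= n - s
    shifted[dst] <- vol[src]
    out <- out & shifted
  }
  out
}

#' Erosion-connectivity profile of firing-field volumes
#'
#' Morphological erosion of the binary field volumes with line structuring
#' elements of increasing length along each cartesian axis. For each axis
#' and element length the total surviving voxel count (summed over fields)
#' is reported, and expressed as the proportion of all surviving voxels at
#' that length; a field elongated along an axis survives erosion along
#' that axis longer, so its proportion curve rises with element length.
#'
#' @param volumes a list of binary 3D arrays (one per field), or fields
#'   from [extract_fields_3d()] (their voxel masks are reconstructed).
#' @param lengths integer element lengths to evaluate.
#' @return A list with `remaining` (3 x length matrix of voxel counts),
#'   `proportion` (columns summing to 1 where any voxels survive) and
#'   `lengths`.
#' @export
erosion_connectivity <- function(volumes, lengths = 1:10) {
  volumes <- lapply(volumes, function(v) {
    if (inherits(v, "firing_field_3d")) {
      a <- array(FALSE, v$dim)
      a[v$voxels] <- TRUE
      a
    } else {
      v != 0
    }
  })
  remaining <- matrix(0, 3, length(lengths),
                      dimnames = list(c("x", "y", "z"), lengths))
  for (li in seq_along(lengths)) {
    for (ax in 1:3) {
      remaining[ax, li] <- sum(vapply(volumes, function(v) {
        sum(erode_line(v, ax, lengths[li]))
      }, numeric(1)))
    }
  }
  tot <- colSums(remaining)
  proportion <- sweep(remaining, 2, ifelse(tot > 0, tot, 1), `/`)
  list(remaining = remaining, proportion = proportion, lengths = lengths)
}
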