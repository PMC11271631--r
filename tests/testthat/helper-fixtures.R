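# Shared fixtures, all generated in code.

# Minimal trajectory visiting given positions.
toy_trajectory <- function(pos, maze_id = "flat", bounds = NULL) {
  trajectory(pos, maze_id, seed = 0L, bounds = bounds)
}

# Trajectory sweeping an n x n grid of bin centres uniformly (each bin
# visited exactly `reps` times), over a [0, n] x [0, n] arena.
grid_sweep_trajectory <- function(n = 4, reps = 2) {
  centers <- expand.grid(x = seq_len(n) - 0.5, y = seq_len(n) - 0.5)
  pos <- centers[rep(seq_len(nrow(centers)), reps), ]
  toy_trajectory(cbind(pos$x, pos$y, 0),
                 bounds = cbind(c(0, 0, 0), c(n, n, 0)))
}

# Ideal periodic bump pattern on an n x n map: Gaussian bumps at the
# points of a hexagonal or square lattice.
bump_lattice_map <- function(n = 40, type = c("hex", "square"),
                             spacing = 11, sigma = 2) {
  type <- match.arg(type)
  basis <- if (type == "hex") {
    rbind(c(1, 0), c(0.5, sqrt(3) / 2)) * spacing
  } else {
    rbind(c(1, 0), c(0, 1)) * spacing
  }
  centers <- NULL
  for (i in -6:6) for (j in -6:6) {
    centers <- rbind(centers, i * basis[1, ] + j * basis[2, ] + n / 2)
  }
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  val <- rep(0, nrow(xy))
  for (k in seq_len(nrow(centers))) {
    d2 <- (xy$x - centers[k, 1])^2 + (xy$y - centers[k, 2])^2
    val <- val + exp(-d2 / (2 * sigma^2))
  }
  matrix(val, n, n)
}

# A rate_map-like object from explicit rate and occupancy arrays.
fake_map <- function(rate, occupancy = NULL) {
  if (is.null(occupancy)) occupancy <- array(1, dim(rate))
  list(rate = rate, occupancy = occupancy, visited = occupancy > 0,
       origin = rep(0, length(dim(rate))), bin_size = rep(1, length(dim(rate))))
}

# Brute-force evaluation of the voxel rate-map formula: for every voxel
# centre, sum truncated-Gaussian kernel weights over events (numerator)
# and over all trajectory points (denominator). Truncation: a point
# contributes only to voxels within Chebyshev distance 1 of its own voxel.
brute_force_rate_map_3d <- function(ev_pos, traj_pos, bounds, nbins,
                                    sigma = 1) {
  origin <- bounds[, 1]
  bsz <- (bounds[, 2] - bounds[, 1]) / nbins
  vox_of <- function(p) {
    pmin(pmax(floor((p - origin) / bsz) + 1, 1), nbins)
  }
  g <- function(p, jco) {
    u <- (p - origin) / bsz
    if (max(abs(vox_of(p) - jco)) > 1) return(0)
    exp(-sum((u - (jco - 0.5))^2) / (2 * sigma^2))
  }
  out <- array(0, nbins)
  for (j1 in seq_len(nbins[1])) for (j2 in seq_len(nbins[2])) {
    for (j3 in seq_len(nbins[3])) {
      jco <- c(j1, j2, j3)
      den <- sum(apply(traj_pos, 1, g, jco = jco))
      num <- if (nrow(ev_pos) > 0) {
        sum(apply(ev_pos, 1, g, jco = jco))
      } else 0
      out[j1, j2, j3] <- if (den > 0) num / den else 0
    }
  }
  out
}

# Brute-force connected-component labelling by repeated neighbour
# expansion from each unlabelled seed (independent of the BFS in the
# package: scans the full array each pass).
brute_force_labels <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  labels <- array(0L, dims)
  idx <- which(mask)
  lab <- 0L
  for (s in idx) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    comp <- array(FALSE, dims)
    comp[s] <- TRUE
    repeat {
      co <- which(comp)
      grown <- comp
      coords <- arrayInd(idx, dims)
      inco <- arrayInd(co, dims)
      for (r in seq_len(nrow(coords))) {
        if (grown[idx[r]]) next
        d <- abs(sweep(inco, 2, coords[r, ]))
        if (any(apply(d, 1, max) <= 1)) grown[idx[r]] <- TRUE
      }
      if (identical(grown, comp)) break
      comp <- grown
    }
    labels[comp] <- lab
  }
  labels
}
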