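#' Simulated foraging trajectories
#'
#' Constructors and seeded stochastic generators for the trajectories used
#' throughout the package: a flat 2D arena, 5x5x5 climbing lattices (aligned
#' with gravity or tilted), a five-coil helical track, and a vertical
#' pegboard. Positions are in maze units with z the gravity axis; the time
#' step is a fixed arbitrary unit, so velocities are first differences of
#' position.
#'
#' @param positions numeric T x 3 matrix of (x, y, z) positions.
#' @param maze_id one of `"flat"`, `"lattice_aligned"`, `"lattice_tilted"`,
#'   `"helix_up"`, `"helix_down"`, `"pegboard"`.
#' @param seed integer seed the trajectory was generated from.
#' @param bounds 3 x 2 matrix of lower/upper bounds of the maze volume.
#' @param dt scalar time step.
#' @return An object of class `"trajectory"`: a list with elements
#'   `positions`, `dt`, `maze_id`, `seed`, `bounds`.
#' @export
trajectory <- function(positions, maze_id, seed = NA_integer_,
                       bounds = NULL, dt = 1) {
  positions <- as.matrix(positions)
  if (ncol(positions) == 2) positions <- cbind(positions, 0)
  if (ncol(positions) != 3 || nrow(positions) < 2) {
    stop_invalid("`positions` must be a T x 3 matrix with T >= 2")
  }
  colnames(positions) <- c("x", "y", "z")
  if (is.null(bounds)) {
    bounds <- cbind(apply(positions, 2, min), apply(positions, 2, max))
  }
  structure(
    list(positions = positions, dt = dt, maze_id = maze_id,
         seed = seed, bounds = bounds),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s, %d points, seed %s>\n",
              x$maze_id, nrow(x$positions), format(x$seed)))
  b <- x$bounds
  cat(sprintf("  bounds: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              b[1, 1], b[1, 2], b[2, 1], b[2, 2], b[3, 1], b[3, 2]))
  invisible(x)
}

#' Velocities of a trajectory
#'
#' Forward-difference velocities `(positions[t + 1] - positions[t]) / dt`;
#' the last row repeats the previous velocity so the result aligns with the
#' position samples.
#'
#' @param traj a [trajectory()].
#' @return T x 3 matrix of velocities.
#' @export
trajectory_velocities <- function(traj) {
  p <- traj$positions
  v <- diff(p) / traj$dt
  rbind(v, v[nrow(v), , drop = FALSE])
}

#' Flat-arena foraging trajectory
#'
#' Bounded random walk with heading persistence: the heading angle performs
#' a Gaussian random walk while the speed stays constant, and walls reflect
#' the path (implemented by mirror-folding the free path into the box, which
#' is equivalent to specular reflection). The long-run occupancy is
#' approximately uniform over the arena.
#'
#' @param arena_size arena extent in units; a scalar (square) or length-2
#'   vector. The protocols in this package use 5x5, 2x2 and 10x10 arenas.
#' @param n_points number of trajectory points (>= 2).
#' @param seed integer seed.
#' @param step step length per time unit; defaults to 1/100 of the mean
#'   arena side.
#' @param turn_sd standard deviation (radians) of the per-step heading
#'   increment.
#' @return A [trajectory()] with `z = 0` everywhere.
#' @export
generate_flat_trajectory <- function(arena_size = c(5, 5), n_points,
                                     seed = 1, step = NULL, turn_sd = 0.4) {
  if (length(arena_size) == 1) arena_size <- rep(arena_size, 2)
  if (any(!is.finite(arena_size)) || any(arena_size <= 0)) {
    stop_invalid("`arena_size` must be positive")
  }
  n_points <- check_count(n_points, "n_points", min = 2)
  if (is.null(step)) step <- mean(arena_size) / 100
  with_seed(seed, {
    theta <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n_points - 1, 0, turn_sd)))
    x0 <- stats::runif(1, 0, arena_size[1])
    y0 <- stats::runif(1, 0, arena_size[2])
    xf <- x0 + c(0, cumsum(step * cos(theta[-n_points])))
    yf <- y0 + c(0, cumsum(step * sin(theta[-n_points])))
    pos <- cbind(fold_reflect(xf, 0, arena_size[1]),
                 fold_reflect(yf, 0, arena_size[2]),
                 0)
    trajectory(pos, "flat", seed,
               bounds = cbind(c(0, 0, 0), c(arena_size, 0)))
  })
}

# Node walk on the 6 x 6 x 6 lattice {0..5}^3. Aligned mode: vertical hop
# with probability 0.2, otherwise a horizontal hop restricted to a 180-degree
# field of view about the current heading (forward, left or right; never an
# immediate reversal unless nothing else is available). Tilted mode: the
# three lattice axes are chosen with equal probability.
lattice_node_walk <- function(mode = c("aligned", "tilted"), n_hops,
                              seed = 1, p_vertical = 0.2, n_nodes = 6) {
  mode <- match.arg(mode)
  n_hops <- check_count(n_hops, "n_hops", min = 2)
  hi <- n_nodes - 1
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  with_seed(seed, {
    node <- floor(stats::runif(3, 0, n_nodes))
    node <- pmin(node, hi)
    heading <- sample(1:4, 1)
    nodes <- matrix(0, n_hops + 1, 3)
    axes <- integer(n_hops)
    nodes[1, ] <- node
    for (h in seq_len(n_hops)) {
      valid <- vapply(1:6, function(d) {
        all(node + dirs[d, ] >= 0) && all(node + dirs[d, ] <= hi)
      }, logical(1))
      if (mode == "aligned") {
        vert_ok <- which(valid[5:6]) + 4L
        go_vertical <- length(vert_ok) > 0 && stats::runif(1) < p_vertical
        if (go_vertical) {
          d <- if (length(vert_ok) == 1) vert_ok else sample(vert_ok, 1)
        } else {
          hv <- dirs[heading, 1:2]
          fov <- which(valid[1:4] &
                         (dirs[1:4, 1] * hv[1] + dirs[1:4, 2] * hv[2]) >= 0)
          if (length(fov) == 0) fov <- which(valid[1:4])
          d <- if (length(fov) == 1) fov else sample(fov, 1)
          heading <- d
        }
      } else {
        ax_ok <- which(c(any(valid[1:2]), any(valid[3:4]), any(valid[5:6])))
        ax <- if (length(ax_ok) == 1) ax_ok else sample(ax_ok, 1)
        cand <- which(valid[(2 * ax - 1):(2 * ax)]) + 2L * (ax - 1L)
        d <- if (length(cand) == 1) cand else sample(cand, 1)
      }
      node <- node + dirs[d, ]
      nodes[h + 1, ] <- node
      axes[h] <- which(dirs[d, ] != 0)
    }
    list(nodes = nodes, axes = axes)
  })
}

# Cubic-spline smoothing of a hop/node sequence followed by equidistant
# arc-length resampling; positions are clamped to the stated bounds (the
# interpolating spline can overshoot slightly between nodes).
smooth_node_path <- function(nodes, n_points, bounds, dense_factor = 2) {
  tt <- seq_len(nrow(nodes))
  n_dense <- max(10 * nrow(nodes), dense_factor * n_points)
  td <- seq(1, nrow(nodes), length.out = n_dense)
  dense <- vapply(seq_len(ncol(nodes)), function(j) {
    pmin(pmax(stats::splinefun(tt, nodes[, j], method = "natural")(td),
              bounds[j, 1]), bounds[j, 2])
  }, numeric(n_dense))
  resample_arclength(dense, n_points)
}

#' Lattice-maze trajectory
#'
#' Random node walk on a 5x5x5-unit climbing lattice (six bars per axis, so
#' nodes sit on the integer grid 0..5 on each axis), smoothed with a cubic
#' spline and resampled to equidistant points. In the aligned maze the agent
#' hops vertically with probability 0.2 and otherwise horizontally within a
#' 180-degree field of view about its heading; in the tilted maze all three
#' lattice axes are equally probable and the whole maze is rotated
#' (by default 45 degrees about the x axis, about the maze centre).
#'
#' @param mode `"aligned"` or `"tilted"`.
#' @param n_hops number of node-to-node hops (>= 2).
#' @param n_points number of resampled trajectory points.
#' @param seed integer seed.
#' @param tilt_angle rotation angle in radians (tilted mode).
#' @param tilt_axis coordinate axis index of the rotation (1 = x).
#' @return A [trajectory()] with maze_id `"lattice_aligned"` or
#'   `"lattice_tilted"`. For the tilted maze the attribute `"rotation"`
#'   carries the 3 x 3 rotation matrix and `"center"` the rotation centre.
#' @export
generate_lattice_trajectory <- function(mode = c("aligned", "tilted"),
                                        n_hops = 2000, n_points = 50000,
                                        seed = 1, tilt_angle = pi / 4,
                                        tilt_axis = 1) {
  mode <- match.arg(mode)
  n_points <- check_count(n_points, "n_points", min = 2)
  walk <- lattice_node_walk(mode, n_hops, seed)
  bounds <- cbind(c(0, 0, 0), c(5, 5, 5))
  pos <- smooth_node_path(walk$nodes, n_points, bounds)
  if (mode == "aligned") {
    trajectory(pos, "lattice_aligned", seed, bounds = bounds)
  } else {
    R <- rotation_about_axis(tilt_axis, tilt_angle)
    ctr <- c(2.5, 2.5, 2.5)
    rot <- sweep(sweep(pos, 2, ctr) %*% t(R), 2, ctr, `+`)
    rb <- apply(rot, 2, range)
    out <- trajectory(rot, "lattice_tilted", seed, bounds = t(rb))
    attr(out, "rotation") <- R
    attr(out, "center") <- ctr
    out
  }
}

#' Helical-maze trajectory
#'
#' Five-coil helical track rising from the ground to a height of five units.
#' The track is an annulus of inner radius 0.5 and outer radius 1 unit; the
#' agent's radial position wanders randomly within the annulus while the
#' unwound angle advances monotonically, and height varies linearly with the
#' unwound angle (increasing for `"up"`, decreasing for `"down"`; up and
#' down traversals are generated separately). The path is resampled to
#' equidistant points.
#'
#' @param direction `"up"` or `"down"`.
#' @param n_points number of trajectory points (>= 2).
#' @param seed integer seed.
#' @param n_coils,height,r_inner,r_outer helix geometry in maze units.
#' @return A [trajectory()] with maze_id `"helix_up"` or `"helix_down"`.
#' @export
generate_helical_trajectory <- function(direction = c("up", "down"),
                                        n_points = 25000, seed = 1,
                                        n_coils = 5, height = 5,
                                        r_inner = 0.5, r_outer = 1) {
  direction <- match.arg(direction)
  n_points <- check_count(n_points, "n_points", min = 2)
  with_seed(seed, {
    n_dense <- max(2L * n_points, 2000L)
    theta <- seq(0, n_coils * 2 * pi, length.out = n_dense)
    # smooth radial wander: reflected random walk over control points every
    # 6 degrees of track, spline-interpolated in between
    n_ctrl <- 60L * n_coils
    th_ctrl <- seq(0, n_coils * 2 * pi, length.out = n_ctrl)
    r_ctrl <- stats::runif(1, r_inner, r_outer) +
      cumsum(c(0, stats::rnorm(n_ctrl - 1, 0, (r_outer - r_inner) / 5)))
    r <- fold_reflect(stats::splinefun(th_ctrl, r_ctrl,
                                       method = "natural")(theta),
                      r_inner, r_outer)
    frac <- theta / (n_coils * 2 * pi)
    z <- if (direction == "up") height * frac else height * (1 - frac)
    dense <- cbind(r * cos(theta), r * sin(theta), z)
    pos <- resample_arclength(dense, n_points)
    rad <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    scale <- pmin(pmax(rad, r_inner), r_outer) / rad
    pos[, 1:2] <- pos[, 1:2] * scale
    pos[, 3] <- pmin(pmax(pos[, 3], 0), height)
    trajectory(pos, paste0("helix_", direction), seed,
               bounds = cbind(c(-r_outer, -r_outer, 0),
                              c(r_outer, r_outer, height)))
  })
}

# Peg-to-peg hop walk on the pegboard. Pegs sit on a square grid in the YZ
# plane; the agent hops only to neighbouring diagonal pegs, never returning
# to the peg it just left, and its x coordinate (along the peg) is drawn
# uniformly in [0, 1] at each peg.
pegboard_hop_walk <- function(n_hops = 2000, seed = 1, board = c(10, 10),
                              peg_spacing = 2) {
  n_hops <- check_count(n_hops, "n_hops", min = 2)
  n_pegs <- floor(board / peg_spacing) + 1
  with_seed(seed, {
    idx <- matrix(0L, n_hops + 1, 2)
    idx[1, ] <- c(sample.int(n_pegs[1], 1), sample.int(n_pegs[2], 1))
    prev <- c(NA_integer_, NA_integer_)
    steps <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    for (h in seq_len(n_hops)) {
      cand <- sweep(steps, 2, idx[h, ], `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= n_pegs[1] &
        cand[, 2] >= 1 & cand[, 2] <= n_pegs[2] &
        !(cand[, 1] == prev[1] & cand[, 2] == prev[2] & !is.na(prev[1]))
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0) {  # corner dead end: returning is the only move
        cand <- matrix(prev, 1)
      }
      pick <- cand[sample.int(nrow(cand), 1), ]
      prev <- idx[h, ]
      idx[h + 1, ] <- pick
    }
    x <- stats::runif(n_hops + 1, 0, 1)
    hops <- cbind(x,
                  (idx[, 1] - 1) * peg_spacing,
                  (idx[, 2] - 1) * peg_spacing)
    list(hops = hops, idx = idx)
  })
}

#' Pegboard-maze trajectory
#'
#' The pegboard is a vertical 10x10-unit board (YZ plane) with 1-unit pegs
#' protruding along x. The agent hops from peg to neighbouring diagonal peg
#' (2000 hops by default), never immediately backtracking, with its position
#' along the peg drawn uniformly in \[0, 1\]; the hop sequence is smoothed
#' with a cubic spline and interpolated to `n_points` equidistant points.
#'
#' Pegs are spaced `peg_spacing` units apart horizontally and vertically, so
#' the diagonal hop distance in the board plane is `peg_spacing * sqrt(2)`
#' (2\eqn{\sqrt 2} at the default spacing of 2; set `peg_spacing = 1` for a
#' literal \eqn{\sqrt 2} diagonal).
#'
#' @param n_hops number of peg-to-peg hops.
#' @param n_points number of interpolated trajectory points.
#' @param seed integer seed.
#' @param peg_spacing horizontal and vertical peg spacing in units.
#' @return A [trajectory()] with maze_id `"pegboard"`, bounds
#'   1 x 10 x 10 units.
#' @export
generate_pegboard_trajectory <- function(n_hops = 2000, n_points = 100000,
                                         seed = 1, peg_spacing = 2) {
  n_points <- check_count(n_points, "n_points", min = 2)
  walk <- pegboard_hop_walk(n_hops, seed, peg_spacing = peg_spacing)
  bounds <- cbind(c(0, 0, 0), c(1, 10, 10))
  pos <- smooth_node_path(walk$hops, n_points, bounds)
  trajectory(pos, "pegboard", seed, bounds = bounds)
}

#' Read or write a trajectory as columnar text
#'
#' Plain whitespace-separated columns `t x y z` with `#`-prefixed header
#' comments carrying the maze id and seed.
#'
#' @param traj a [trajectory()].
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# maze_id: %s", traj$maze_id), con)
  writeLines(sprintf("# seed: %s", format(traj$seed)), con)
  writeLines(sprintf("# dt: %g", traj$dt), con)
  tab <- cbind(t = (seq_len(nrow(traj$positions)) - 1) * traj$dt,
               traj$positions)
  utils::write.table(tab, con, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key, default = NA) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  seed <- suppressWarnings(as.integer(get_field("seed")))
  dt <- suppressWarnings(as.numeric(get_field("dt", "1")))
  trajectory(as.matrix(tab[, c("x", "y", "z")]),
             maze_id = get_field("maze_id", "flat"),
             seed = seed, dt = if (is.na(dt)) 1 else dt)
}
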