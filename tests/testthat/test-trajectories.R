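test_that("flat-arena trajectory stays in bounds at constant speed", {
  tr <- generate_flat_trajectory(c(5, 5), 20000, seed = 3)
  p <- tr$positions
  expect_equal(nrow(p), 20000)
  expect_true(all(p[, 1] >= 0 & p[, 1] <= 5))
  expect_true(all(p[, 2] >= 0 & p[, 2] <= 5))
  expect_true(all(p[, 3] == 0))
  d <- sqrt(rowSums(diff(p)^2))
  expect_lt(stats::sd(d) / mean(d), 0.05)
})

test_that("flat-arena occupancy covers the arena uniformly", {
  tr <- generate_flat_trajectory(c(5, 5), 100000, seed = 9)
  h <- table(cut(tr$positions[, 1], seq(0, 5, 0.5)),
             cut(tr$positions[, 2], seq(0, 5, 0.5)))
  expect_true(all(h > 0))
})

test_that("two-point flat trajectory is a bounded displacement", {
  tr <- generate_flat_trajectory(c(5, 5), 2, seed = 1)
  expect_equal(nrow(tr$positions), 2)
  expect_lte(sqrt(sum(diff(tr$positions)^2)), sqrt(50))
})

test_that("trajectory generators reject invalid sizes", {
  expect_error(generate_flat_trajectory(c(5, 5), 1, seed = 1),
               class = "invalid_argument")
  expect_error(generate_flat_trajectory(c(-5, 5), 100, seed = 1),
               class = "invalid_argument")
  expect_error(generate_lattice_trajectory("aligned", n_hops = 1, seed = 1),
               class = "invalid_argument")
  expect_error(generate_helical_trajectory("up", 1, seed = 1),
               class = "invalid_argument")
  expect_error(generate_pegboard_trajectory(n_hops = 1, seed = 1),
               class = "invalid_argument")
})

test_that("aligned lattice walk moves vertically 20% of the time", {
  w <- spatialcells3d:::lattice_node_walk("aligned", 10000, seed = 5)
  expect_true(abs(mean(w$axes == 3) - 0.20) < 0.02)
  expect_true(all(w$nodes %in% 0:5))
})

test_that("tilted lattice walk uses the three axes equally", {
  w <- spatialcells3d:::lattice_node_walk("tilted", 10000, seed = 5)
  fr <- tabulate(w$axes, 3) / length(w$axes)
  expect_true(all(abs(fr - 1 / 3) < 0.02))
  expect_true(all(w$nodes %in% 0:5))
})

test_that("tilted trajectory is the rotated node-walk geometry", {
  n_hops <- 200
  tilt <- pi / 4
  tr <- generate_lattice_trajectory("tilted", n_hops, 2000, seed = 8,
                                    tilt_angle = tilt)
  walk <- spatialcells3d:::lattice_node_walk("tilted", n_hops, seed = 8)
  pos0 <- spatialcells3d:::smooth_node_path(walk$nodes, 2000,
                                            cbind(c(0, 0, 0), c(5, 5, 5)))
  R <- spatialcells3d:::rotation_about_axis(1, tilt)
  ctr <- c(2.5, 2.5, 2.5)
  expected <- sweep(sweep(pos0, 2, ctr) %*% t(R), 2, ctr, `+`)
  expect_equal(unname(tr$positions), unname(expected), tolerance = 1e-12)
  expect_equal(det(attr(tr, "rotation")), 1, tolerance = 1e-12)
})

test_that("helical trajectory respects the annulus and height", {
  for (dir in c("up", "down")) {
    tr <- generate_helical_trajectory(dir, 5000, seed = 4)
    r <- sqrt(tr$positions[, 1]^2 + tr$positions[, 2]^2)
    expect_true(all(r >= 0.5 - 1e-9 & r <= 1 + 1e-9))
    expect_equal(range(tr$positions[, 3]), c(0, 5), tolerance = 1e-9)
    un <- spatialcells3d:::helix_unwound_angle(tr$positions)
    expect_equal(max(un), 5 * 2 * pi, tolerance = 1e-6)
    # height varies linearly with the unwound angle
    z <- tr$positions[, 3]
    zl <- if (dir == "up") 5 * un / (10 * pi) else 5 * (1 - un / (10 * pi))
    expect_equal(z, zl, tolerance = 1e-6)
  }
})

test_that("pegboard hops are diagonal, non-backtracking, with x in [0,1]", {
  w <- spatialcells3d:::pegboard_hop_walk(2000, seed = 6)
  expect_true(all(w$hops[, 1] >= 0 & w$hops[, 1] <= 1))
  steps <- diff(w$idx)
  expect_true(all(abs(steps) == 1))  # diagonal moves only
  # no p -> q -> p, except where q is a corner with a single neighbour
  n_pegs <- 6
  is_corner <- function(ij) all(ij %in% c(1, n_pegs))
  for (h in seq_len(nrow(w$idx) - 2)) {
    if (all(w$idx[h, ] == w$idx[h + 2, ])) {
      expect_true(is_corner(w$idx[h + 1, ]))
    }
  }
})

test_that("pegboard trajectory interpolates to the requested points", {
  tr <- generate_pegboard_trajectory(500, 20000, seed = 2)
  expect_equal(nrow(tr$positions), 20000)
  expect_true(all(tr$positions[, 1] >= 0 & tr$positions[, 1] <= 1))
  expect_true(all(tr$positions[, 2] >= 0 & tr$positions[, 2] <= 10))
  expect_true(all(tr$positions[, 3] >= 0 & tr$positions[, 3] <= 10))
})

test_that("same seed reproduces a trajectory bit for bit; seeds differ", {
  for (gen in list(
    function(s) generate_flat_trajectory(c(5, 5), 500, seed = s),
    function(s) generate_lattice_trajectory("aligned", 50, 500, seed = s),
    function(s) generate_helical_trajectory("up", 500, seed = s),
    function(s) generate_pegboard_trajectory(50, 500, seed = s))) {
    expect_identical(gen(11), gen(11))
    expect_false(identical(gen(11)$positions, gen(12)$positions))
  }
})

test_that("trajectory round-trips through columnar text", {
  tr <- generate_flat_trajectory(c(2, 2), 50, seed = 3)
  path <- tempfile(fileext = ".txt")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$maze_id, "flat")
  expect_equal(back$seed, 3L)
  expect_equal(back$positions, tr$positions, tolerance = 1e-6)
  unlink(path)
})

test_that("velocities are forward differences of position", {
  tr <- toy_trajectory(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0)))
  v <- trajectory_velocities(tr)
  expect_equal(v[1, ], c(x = 1, y = 0, z = 0))
  expect_equal(v[2, ], c(x = 0, y = 2, z = 0))
  expect_equal(nrow(v), 3)
})
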