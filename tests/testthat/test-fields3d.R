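ball_mask <- function(n, center, radius) {
  co <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n))
  array(sqrt(rowSums(sweep(co, 2, center)^2)) <= radius, c(n, n, n))
}

map_from_mask <- function(mask, bin_size = 1) {
  nd <- dim(mask)
  list(rate = ifelse(mask, 1, 0), occupancy = array(1, nd),
       origin = rep(0, 3), bin_size = rep(bin_size, 3), visited = !is.na(mask))
}

test_that("a single supra-threshold blob yields one field", {
  mask <- ball_mask(12, c(6, 6, 6), 3.2)
  expect_gt(sum(mask), 50)
  fields <- extract_fields_3d(map_from_mask(mask), 0.5, 50)
  expect_length(fields, 1)
  expect_equal(fields[[1]]$n_voxels, sum(mask))
  expect_equal(fields[[1]]$centroid, c(5.5, 5.5, 5.5), tolerance = 1e-9)
})

test_that("separated blobs yield separate fields; small ones are dropped", {
  mask <- ball_mask(20, c(5, 5, 5), 3.2) | ball_mask(20, c(15, 15, 15), 3.2)
  fields <- extract_fields_3d(map_from_mask(mask), 0.5, 50)
  expect_length(fields, 2)
  # a sub-threshold-size component is filtered out
  mask2 <- ball_mask(20, c(5, 5, 5), 3.2) | ball_mask(20, c(16, 16, 16), 2)
  fields2 <- extract_fields_3d(map_from_mask(mask2), 0.5, 50)
  expect_length(fields2, 1)
  expect_identical(extract_fields_3d(map_from_mask(array(FALSE, c(4, 4, 4)))),
                   list())
})

test_that("component labelling agrees with a brute-force oracle", {
  set.seed(17)
  for (rep in 1:20) {
    mask <- array(stats::runif(5 * 5 * 5) > 0.7, c(5, 5, 5))
    lab <- spatialcells3d:::label_components(mask, "full")
    oracle <- brute_force_labels(mask)
    # same partition up to label permutation
    expect_equal(lab > 0, oracle > 0)
    if (any(mask)) {
      key <- paste(lab[mask], oracle[mask])
      expect_equal(length(unique(key)), length(unique(lab[mask])))
      expect_equal(length(unique(key)), length(unique(oracle[mask])))
    }
  }
})

test_that("elongation is ~1 for balls and matches moments for rods", {
  mask <- ball_mask(16, c(8, 8, 8), 5)
  f <- extract_fields_3d(map_from_mask(mask), 0.5, 50)[[1]]
  expect_equal(f$elongation, 1, tolerance = 0.05)
  # 1 x 1 x 10 rod: the long extent is 4 SD of the voxel centres and the
  # two short extents floor at one voxel
  expect_equal(elongation_index(c(4 * stats::sd(1:10 - 0.5), 1, 1)),
               4 * stats::sd(1:10 - 0.5))
  rod <- array(FALSE, c(3, 3, 12))
  rod[2, 2, 2:11] <- TRUE
  lab <- spatialcells3d:::label_components(rod, "full")
  expect_equal(max(lab), 1)
})

test_that("centroid shuffle test accepts centred fields, rejects corners", {
  bounds <- cbind(c(0, 0, 0), c(5, 5, 5))
  mkfield <- function(centroid) {
    structure(list(centroid = centroid, axes = diag(3),
                   extents = c(2, 1, 1)), class = "firing_field_3d")
  }
  sym <- lapply(1:8, function(i) {
    mkfield(c(2.5, 2.5, 2.5) + 0.3 * (-1)^i * c(1, 0.5, -1))
  })
  res <- centroid_distribution_test(sym, bounds, n_shuffles = 500, seed = 3)
  expect_true(all(res$inside))
  expect_length(res$lower, 3)
  corner <- lapply(1:12, function(i) mkfield(c(0.2, 0.2, 0.2) + i * 1e-3))
  res2 <- centroid_distribution_test(corner, bounds, n_shuffles = 500,
                                     seed = 3)
  expect_false(any(res2$inside))
  expect_error(centroid_distribution_test(list(), bounds),
               class = "undefined_statistic")
})

test_that("orientation counts find axis-aligned fields and a chance band", {
  mk <- function(v) structure(list(axes = cbind(v, c(0, 1, 0), c(1, 0, 0))),
                              class = "firing_field_3d")
  fields <- lapply(1:10, function(i) mk(c(0, 0, 1)))
  res <- orientation_stats(fields, frames = list(XYZ = diag(3)),
                           n_uniform = 300, seed = 2)
  expect_equal(unname(res$counts$XYZ), c(0, 0, 10))
  # uniformly random orientations fall inside the chance band
  set.seed(9)
  rnd <- lapply(1:40, function(i) {
    v <- stats::rnorm(3); mk(v / sqrt(sum(v^2)))
  })
  res2 <- orientation_stats(rnd, frames = list(XYZ = diag(3)),
                            n_uniform = 500, seed = 4)
  expect_true(all(res2$counts$XYZ >= res2$chance_lower - 2 &
                    res2$counts$XYZ <= res2$chance_upper + 2))
  # two frames produce a ratio with null percentiles
  res3 <- orientation_stats(fields, frames = list(
    XYZ = diag(3), ABC = spatialcells3d:::rotation_about_axis(1, pi / 4)),
    n_uniform = 200, seed = 5)
  expect_true(is.finite(res3$ratio_null_q99))
  expect_gt(res3$ratio, res3$ratio_null_q99)
})

test_that("line erosion equals a sliding-window minimum oracle", {
  set.seed(23)
  for (rep in 1:10) {
    vol <- array(stats::runif(4 * 5 * 6) > 0.35, c(4, 5, 6))
    for (ax in 1:3) {
      L <- sample(2:4, 1)
      er <- spatialcells3d:::erode_line(vol, ax, L)
      dims <- dim(vol)
      oracle <- array(FALSE, dims)
      for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
        co <- c(i, j, k)
        if (co[ax] + L - 1 <= dims[ax]) {
          sl <- lapply(1:3, function(d) {
            if (d == ax) co[d]:(co[d] + L - 1) else co[d]
          })
          oracle[i, j, k] <- all(vol[sl[[1]], sl[[2]], sl[[3]]])
        }
      }
      expect_identical(er & TRUE, oracle)
    }
  }
})

test_that("erosion connectivity is monotone and rods survive their axis", {
  rod <- array(FALSE, c(12, 12, 12))
  rod[6, 6, 2:11] <- TRUE  # z-oriented rod
  blob <- ball_mask(12, c(4, 4, 4), 2)
  res <- erosion_connectivity(list(rod, blob), lengths = 1:8)
  expect_true(all(diff(t(res$remaining)) <= 0))
  # the z-rod survives z erosion longer than x or y erosion
  expect_gt(res$remaining[3, 6], res$remaining[1, 6])
  expect_gt(res$remaining[3, 6], res$remaining[2, 6])
  # element length 1 is the identity erosion
  expect_equal(sum(res$remaining[, 1]), 3 * (sum(rod) + sum(blob)))
  expect_equal(unname(colSums(res$proportion))[1], 1)
})
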