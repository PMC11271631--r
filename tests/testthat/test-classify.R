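test_that("spatial information has its closed-form values", {
  # uniform rate over uniform occupancy: zero bits/spike
  expect_equal(spatial_information(fake_map(matrix(3, 5, 5))), 0)
  # firing confined to 1 of N equally occupied bins: log2(N)
  for (N in c(4, 16, 25)) {
    rate <- matrix(0, 1, N); rate[1] <- 7
    expect_equal(spatial_information(fake_map(rate)), log2(N),
                 tolerance = 1e-12)
  }
  expect_error(spatial_information(fake_map(matrix(0, 3, 3))),
               class = "undefined_statistic")
})

test_that("Skaggs sparsity has its closed-form values", {
  expect_equal(sparsity(fake_map(matrix(2, 4, 4))), 1)
  for (N in c(4, 16, 25)) {
    rate <- matrix(0, 1, N); rate[1] <- 3
    expect_equal(sparsity(fake_map(rate)), 1 / N, tolerance = 1e-12)
  }
  # the printed reciprocal form is >= 1 and inverts the Skaggs value here
  rate <- matrix(0, 1, 8); rate[1] <- 3
  expect_equal(sparsity(fake_map(rate), printed_form = TRUE), 8)
})

test_that("information and sparsity are invariant to rate scaling", {
  set.seed(5)
  rate <- matrix(stats::rexp(36), 6, 6)
  occ <- matrix(stats::rpois(36, 20) + 1, 6, 6)
  m1 <- fake_map(rate, occ)
  m2 <- fake_map(rate * 7.3, occ)
  expect_equal(spatial_information(m1), spatial_information(m2),
               tolerance = 1e-12)
  expect_equal(sparsity(m1), sparsity(m2), tolerance = 1e-12)
  # sparsity is 1 iff the rate is constant over visited bins
  expect_lt(sparsity(m1), 1)
})

test_that("the activation-rate proxy is non-negative with upward tail", {
  set.seed(3)
  a <- stats::rnorm(5000)
  r <- activation_rate(a, 0.85)
  expect_true(all(r >= 0))
  expect_equal(mean(r > 0), 0.15, tolerance = 0.01)
  # sign ambiguity: a negated series gives the same proxy
  expect_equal(activation_rate(-(a^3)), activation_rate(a^3),
               tolerance = 1e-12)
})

test_that("the shuffle null is sized and excludes the zero shift", {
  tr <- generate_flat_trajectory(c(5, 5), 4000, seed = 6)
  a <- sin(tr$positions[, 1] * 3) + stats::rnorm(4000, 0, 0.1)
  nul <- shuffle_null(a, tr, n_shuffles = 200, seed = 2, bins = c(10, 10))
  expect_length(nul$spatial_info, 200)
  expect_length(nul$sparsity, 200)
  min_shift <- floor(0.05 * 4000)
  expect_true(all(nul$shifts >= min_shift &
                    nul$shifts <= 4000 - min_shift))
  # spatially tuned activity beats its own shifted null
  expect_gt(nul$observed_spatial_info,
            stats::quantile(nul$spatial_info, 0.99))
  expect_error(shuffle_null(a[1:10], toy_trajectory(tr$positions[1:10, ]),
                            min_shift = 6),
               class = "invalid_argument")
})

test_that("white-noise activation sits inside its null band", {
  tr <- generate_flat_trajectory(c(5, 5), 4000, seed = 8)
  hits <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    a <- stats::rnorm(4000)
    nul <- shuffle_null(a, tr, n_shuffles = 200, seed = s,
                        bins = c(10, 10))
    inside <- nul$observed_spatial_info >
      stats::quantile(nul$spatial_info, 0.025) &&
      nul$observed_spatial_info <
      stats::quantile(nul$spatial_info, 0.975)
    hits <- hits + inside
  }
  expect_gte(hits, 4)
})

test_that("place-cell gates are all required", {
  nul_si <- stats::runif(500, 0.5, 1)
  nul_sp <- stats::runif(500, 0.2, 0.5)
  base <- list(null_spatial_info = nul_si, null_sparsity = nul_sp)
  pass <- c(base, spatial_info = 2, sparsity = 0.05)
  expect_true(classify_place_cell(pass))
  expect_false(classify_place_cell(c(base, spatial_info = 0.2,
                                     sparsity = 0.05)))
  expect_false(classify_place_cell(c(base, spatial_info = 2,
                                     sparsity = 0.15)))
  # fails the null percentile gates
  expect_false(classify_place_cell(c(base, spatial_info = 0.7,
                                     sparsity = 0.05)))
  expect_false(classify_place_cell(list(spatial_info = NA_real_,
                                        sparsity = NA_real_,
                                        null_spatial_info = nul_si,
                                        null_sparsity = nul_sp)))
})

test_that("the autocorrelogram matches a per-lag Pearson oracle", {
  set.seed(21)
  lam <- matrix(stats::runif(144), 12, 12)
  ac <- autocorrelogram(lam, min_overlap = 10)
  expect_equal(ac[12, 12], 1, tolerance = 1e-12)
  # symmetry under lag negation
  expect_equal(ac, ac[23:1, 23:1], ignore_attr = TRUE)
  oracle <- function(tx, ty) {
    v1 <- c(); v2 <- c()
    for (i in 1:12) for (j in 1:12) {
      if (i - tx >= 1 && i - tx <= 12 && j - ty >= 1 && j - ty <= 12) {
        v1 <- c(v1, lam[i, j]); v2 <- c(v2, lam[i - tx, j - ty])
      }
    }
    if (length(v1) < 10) NA_real_ else stats::cor(v1, v2)
  }
  for (tx in c(-7, -2, 0, 3)) for (ty in c(-4, 0, 1, 6)) {
    expect_equal(ac[tx + 12, ty + 12], oracle(tx, ty), tolerance = 1e-10)
  }
  # lags with too little overlap are undefined
  expect_true(is.na(ac[1, 1]))
})

test_that("grid scores diagnose hexagonal and square patterns", {
  hex <- bump_lattice_map(40, "hex")
  gs_hex <- grid_scores(autocorrelogram(hex))
  expect_gt(gs_hex$hgs, 0.3)
  sq <- bump_lattice_map(40, "square")
  gs_sq <- grid_scores(autocorrelogram(sq))
  expect_gt(gs_sq$sgs, 0.3)
  expect_lt(gs_sq$hgs, 0.3)
  # a radially symmetric autocorrelogram scores near zero on both:
  # every rotation correlates equally with the original
  n <- 39
  rr <- sqrt(outer((1:n - 20)^2, (1:n - 20)^2, `+`))
  ac_rad <- structure(cos(rr * 2 * pi / 8) * exp(-rr / 15),
                      center = c(20, 20),
                      class = c("autocorrelogram", "matrix"))
  gs_rad <- grid_scores(ac_rad)
  expect_lt(abs(gs_rad$hgs), 0.1)
  expect_lt(abs(gs_rad$sgs), 0.1)
  expect_error(grid_scores(autocorrelogram(matrix(1, 10, 10))),
               class = "undefined_statistic")
})

test_that("hexagonal gridness is invariant to 60-degree pattern rotation", {
  # restrict both patterns to the inscribed disk so the rotation is an
  # exact symmetry of the support
  disk <- function(M) {
    n <- nrow(M)
    rr <- sqrt(outer((1:n - (n + 1) / 2)^2, (1:n - (n + 1) / 2)^2, `+`))
    M[rr > n / 2 - 1] <- 0
    M
  }
  base <- disk(bump_lattice_map(40, "hex"))
  g0 <- grid_scores(autocorrelogram(base))$hgs
  rot <- spatialcells3d:::rotate_matrix(bump_lattice_map(40, "hex"), pi / 3)
  rot[is.na(rot)] <- 0
  g60 <- grid_scores(autocorrelogram(disk(rot)))$hgs
  expect_lt(abs(g0 - g60), 0.05)
})

test_that("grid-cell labels follow the score gates", {
  expect_equal(classify_grid_cell(list(hgs = 0.5, sgs = 0.1)), "hexagonal")
  expect_equal(classify_grid_cell(list(hgs = 0.1, sgs = 0.5)), "square")
  expect_equal(classify_grid_cell(list(hgs = 0.2, sgs = 0.2)), "none")
  expect_equal(classify_grid_cell(list(hgs = NA_real_, sgs = NA_real_)),
               "none")
})
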