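test_that("field axes follow the second-moment ellipse", {
  # circular blob of points: aspect ~ 1
  set.seed(2)
  th <- stats::runif(500, 0, 2 * pi); rr <- sqrt(stats::runif(500))
  disc <- cbind(rr * cos(th), rr * sin(th))
  ax <- field_axes_2d(disc)
  expect_lt(ax$aspect, 1.2)
  # a 1 x 10 strip of bin centres is ~10x more extended
  strip <- cbind(rep(0.5, 10), 1:10 - 0.5)
  ax2 <- field_axes_2d(strip, bin_width = 1)
  expect_equal(ax2$major, 4 * stats::sd(1:10), tolerance = 1e-9)
  expect_equal(ax2$minor, 1)  # collinear: floored at one bin width
  expect_equal(ax2$aspect, 4 * stats::sd(1:10), tolerance = 1e-9)
  expect_error(field_axes_2d(strip[1:2, ]), class = "invalid_argument")
})

test_that("2D field extraction finds components above threshold", {
  rate <- matrix(0, 20, 20)
  rate[3:6, 3:6] <- 1
  rate[14:16, 12:18] <- 0.8
  map <- fake_map(rate)
  map$visited <- matrix(TRUE, 20, 20)
  fields <- extract_fields_2d(map, rate_threshold = 0.2, min_bins = 3)
  expect_length(fields, 2)
  sizes <- sort(vapply(fields, `[[`, integer(1), "n_bins"))
  expect_equal(sizes, c(16L, 21L))
  # aspect of the elongated component exceeds the square one
  aspects <- vapply(fields, `[[`, numeric(1), "aspect")
  expect_gt(max(aspects), min(aspects))
})

test_that("helix unwinding assigns coils and bins by unwound angle", {
  # synthetic helix at fixed radius, exactly 5 coils over T points
  TT <- 6000
  un <- seq(0, 5 * 2 * pi - 1e-9, length.out = TT)
  pos <- cbind(0.75 * cos(un), 0.75 * sin(un), 5 * un / (10 * pi))
  tr <- trajectory(pos, "helix_up", 1L)
  # an event at the start of coil 3 lands in coil 3, bin 1
  idx3 <- which(un >= 2 * 2 * pi)[1]
  a <- numeric(TT); a[idx3] <- 1
  ev <- threshold_events(a, tr, 99.99)
  prof <- unwind_helix(ev, tr)
  expect_equal(dim(prof$rate), c(5, 60))
  expect_equal(prof$point_coil[idx3], 3L)
  expect_equal(prof$point_bin[idx3], 1L)
  expect_equal(which(prof$events > 0), which(rep(1:5, 60) == 3 &
                                               rep(1:60, each = 5) == 1))
  expect_error(unwind_helix(ev, toy_trajectory(pos)),
               class = "invalid_argument")
})

test_that("uniform events give flat coil profiles summing to event counts", {
  TT <- 12000
  un <- seq(0, 5 * 2 * pi - 1e-9, length.out = TT)
  pos <- cbind(0.75 * cos(un), 0.75 * sin(un), 5 * un / (10 * pi))
  tr <- trajectory(pos, "helix_up", 1L)
  ev <- threshold_events(seq_len(TT) %% 2, tr, 50)
  prof <- unwind_helix(ev, tr)
  for (coil in 1:5) {
    expect_equal(sum(prof$events[coil, ]),
                 sum(ev$idx %in% which(prof$point_coil == coil)))
  }
  expect_equal(sum(prof$occupancy), TT)
  expect_lt(max(prof$rate) - min(prof$rate), 0.15)
})

test_that("helix fields merge across coils and count coils spanned", {
  # events at one angular spot on every coil: one merged field, 5 coils
  TT <- 30000
  un <- seq(0, 5 * 2 * pi - 1e-9, length.out = TT)
  pos <- cbind(0.75 * cos(un), 0.75 * sin(un), 5 * un / (10 * pi))
  tr <- trajectory(pos, "helix_up", 1L)
  ang <- un %% (2 * pi)
  a <- as.numeric(ang > 1 & ang < 1.5)
  ev <- threshold_events(a, tr, 95)
  prof <- unwind_helix(ev, tr)
  ff <- helix_fields(prof, rate_threshold = 0.2)
  expect_length(ff, 1)
  expect_equal(ff[[1]]$n_coils_spanned, 5L)
  # activity restricted to a single coil spans one coil
  a1 <- as.numeric(ang > 1 & ang < 1.5 & un < 2 * pi)
  ev1 <- threshold_events(a1, tr, 99)
  ff1 <- helix_fields(unwind_helix(ev1, tr), rate_threshold = 0.2)
  expect_length(ff1, 1)
  expect_equal(ff1[[1]]$n_coils_spanned, 1L)
})

test_that("axis-wise information separates structured from flat axes", {
  # rate varies along dimension 1 only
  rate <- matrix(rep(c(0, 0, 4, 0, 0, 0, 0, 0, 0, 0), 10), 10, 10)
  map <- fake_map(rate)
  hi <- axis_spatial_information(map, "horizontal")
  vi <- axis_spatial_information(map, "vertical")
  expect_gt(hi, 1)
  expect_equal(vi, 0, tolerance = 1e-12)
  # symmetric map: equal information on both axes
  sym <- fake_map(outer(1:10, 1:10, function(i, j) exp(-((i - 5)^2 +
                                                           (j - 5)^2) / 8)))
  expect_equal(axis_spatial_information(sym, "horizontal"),
               axis_spatial_information(sym, "vertical"), tolerance = 1e-12)
  # 1D closed form: single active bin of N
  one <- fake_map(matrix(c(5, rep(0, 9)), 10, 1))
  expect_equal(axis_spatial_information(one, "horizontal"), log2(10),
               tolerance = 1e-12)
})

test_that("collapsing a map never increases spatial information", {
  set.seed(7)
  for (rep in 1:5) {
    rate <- matrix(stats::rexp(400), 20, 20)
    map <- fake_map(rate)
    full <- spatial_information(map)
    expect_lte(axis_spatial_information(map, "horizontal"), full + 1e-9)
    expect_lte(axis_spatial_information(map, "vertical"), full + 1e-9)
  }
})

test_that("vertical layer counts match an interval-overlap oracle", {
  dimz <- c(20L, 20L)
  mkfield <- function(bins) {
    structure(list(bins = bins, dim = dimz), class = "firing_field_2d")
  }
  # field confined to the bottom fifth
  bottom <- mkfield(which(matrix(rep(1:20, each = 20) <= 4, 20)))
  expect_equal(count_vertical_layers(bottom, c(0, 10), 5), 1L)
  full <- mkfield(seq_len(400))
  expect_equal(count_vertical_layers(full, c(0, 10), 5), 5L)
  set.seed(11)
  for (rep in 1:10) {
    bins <- sample.int(400, 25)
    f <- mkfield(bins)
    got <- count_vertical_layers(f, c(0, 10), 5)
    zcol <- arrayInd(bins, dimz)[, 2]
    zlo <- (zcol - 1) * 0.5; zhi <- zcol * 0.5
    oracle <- sum(vapply(1:5, function(l) {
      any(zhi > (l - 1) * 2 & zlo < l * 2)
    }, logical(1)))
    expect_equal(got, oracle)
  }
})

test_that("t tests match the reference implementation and edge cases", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # textbook pooled-variance example
  a <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  b <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7,
         23.2, 17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 24.0, 13.2)
  r2 <- two_sample_t(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r2$dof, length(a) + length(b) - 2)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-12)
  # one-sample test against sphericity (aspect ratio 1)
  aspects <- c(1.4, 1.7, 1.2, 1.9, 1.5, 1.6)
  r3 <- one_sample_t(aspects, mu = 1)
  ref3 <- stats::t.test(aspects, mu = 1)
  expect_equal(r3$t, unname(ref3$statistic), tolerance = 1e-12)
  expect_error(two_sample_t(c(1, 1), c(2, 2)),
               class = "undefined_statistic")
  expect_error(two_sample_t(1, c(1, 2)), class = "invalid_argument")
})
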