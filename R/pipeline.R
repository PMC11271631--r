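#' Experiment configuration
#'
#' Assembles the full parameter set of one simulation protocol. Defaults
#' reproduce the study conditions per protocol: a 5x5 flat training arena
#' with 20 azimuth x 3 pitch directions for the lattice mazes, a 2x2 arena
#' with 20 azimuths and a single 90-degree pitch for the helix, a 10x10
#' arena (100,000 points) with the same basis for the pegboard; 50,000
#' training points otherwise; a 120- or 40-input linear autoencoder with
#' two 50-unit hidden layers, MSE loss, 10 epochs, 4:1 train/validation
#' split. The path-integration modulation factor defaults to
#' `beta = 15 / L` for an `L x L` arena (3.0 on the 5x5 arena), so field
#' size scales with the environment.
#'
#' @param protocol one of `"lattice_aligned"`, `"lattice_tilted"`,
#'   `"helix"`, `"pegboard"`.
#' @param seed master seed; all stage seeds are derived from it.
#' @param ... overrides of any default element (see Details in the
#'   package vignette).
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(protocol = c("lattice_aligned",
                                           "lattice_tilted", "helix",
                                           "pegboard"),
                              seed = 1, ...) {
  protocol <- match.arg(protocol)
  base <- list(
    protocol = protocol, seed = as.integer(seed),
    n1 = 20, n2 = 3, beta = NULL,
    arena_size = c(5, 5), n_points = 50000,
    hidden = c(50, 50), epochs = 10, train_fraction = 0.8,
    learning_rate = 1e-3, batch_size = 256, encoder_layer = 1,
    percentile = 80, rate_quantile = 0.85, bins = c(20, 20),
    smoothing = 1, n_shuffles = 1000,
    rate_threshold = 0.2, min_voxels = 50, min_bins = 3,
    merge_radius = 0.3,
    lattice_n_hops = 2000, maze_n_points = 50000, tilt_angle = pi / 4,
    helix_points_per_run = 25000, pegboard_n_hops = 2000,
    run_maze_analysis = TRUE)
  if (protocol == "helix") {
    base$n2 <- 1
    base$arena_size <- c(2, 2)
  } else if (protocol == "pegboard") {
    base$n2 <- 1
    base$arena_size <- c(10, 10)
    base$n_points <- 100000
    base$maze_n_points <- 100000
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown) > 0) {
    stop_invalid(paste("unknown config fields:",
                       paste(unknown, collapse = ", ")))
  }
  base[names(dots)] <- dots
  if (is.null(base$beta)) base$beta <- 15 / mean(base$arena_size)
  structure(base, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config: %s, seed %d>\n", x$protocol, x$seed))
  cat(sprintf("  arena %g x %g, %d points, n1 = %d, n2 = %d, beta = %g\n",
              x$arena_size[1], x$arena_size[2], x$n_points, x$n1, x$n2,
              x$beta))
  invisible(x)
}

# Pooled 2D field statistics of a set of units on one map geometry.
flat_field_stats <- function(units, act, traj, cfg) {
  fields <- list()
  for (j in units) {
    ev <- threshold_events(act[, j], traj, cfg$percentile, neuron_id = j)
    map <- rate_map_2d(ev, traj, bins = cfg$bins, smoothing = cfg$smoothing)
    ff <- extract_fields_2d(map, cfg$rate_threshold, cfg$min_bins)
    for (f in ff) f$unit <- j
    fields <- c(fields, ff)
  }
  if (length(fields) == 0) {
    return(list(fields = fields, major = numeric(0), minor = numeric(0),
                aspect = numeric(0)))
  }
  list(fields = fields,
       major = vapply(fields, `[[`, numeric(1), "major"),
       minor = vapply(fields, `[[`, numeric(1), "minor"),
       aspect = vapply(fields, `[[`, numeric(1), "aspect"))
}

analyse_lattice <- function(model, basis, cfg, place_units, seed_maze,
                            seed_analysis) {
  mode <- if (cfg$protocol == "lattice_tilted") "tilted" else "aligned"
  maze <- generate_lattice_trajectory(mode, cfg$lattice_n_hops,
                                      cfg$maze_n_points, seed_maze,
                                      tilt_angle = cfg$tilt_angle)
  enc <- path_integration(maze, basis, cfg$beta)
  act <- encoder_activations(model, enc)
  nbins <- c(20, 20, 20)
  origin <- maze$bounds[, 1]
  bin_size <- (maze$bounds[, 2] - maze$bounds[, 1]) / nbins
  den <- accumulate_truncated_gaussian(maze$positions, origin, bin_size,
                                       nbins, 1)
  fields <- list()
  maps <- list()
  for (j in place_units) {
    ev <- threshold_events(act[, j], maze, cfg$percentile, neuron_id = j)
    map <- rate_map_3d(ev, maze, nbins = nbins, bounds = maze$bounds,
                       denominator = den)
    ff <- extract_fields_3d(map, cfg$rate_threshold, cfg$min_voxels)
    for (f in ff) f$unit <- j
    fields <- c(fields, ff)
  }
  out <- list(maze = maze, n_fields = length(fields), fields = fields)
  if (length(fields) > 0) {
    rot <- attr(maze, "rotation")
    out$centroid_test <- centroid_distribution_test(
      fields, cbind(c(0, 0, 0), c(5, 5, 5)), seed = seed_analysis,
      rotation = rot, center = attr(maze, "center"))
    out$elongation <- vapply(fields, `[[`, numeric(1), "elongation")
    frames <- list(XYZ = diag(3),
                   ABC = rotation_about_axis(1, cfg$tilt_angle))
    if (mode == "tilted") frames <- frames[c("ABC", "XYZ")]
    out$orientation <- orientation_stats(
      fields, frames = frames, seed = child_seed(seed_analysis, 1))
    out$erosion <- erosion_connectivity(fields, lengths = 1:10)
  }
  out
}

analyse_helix <- function(model, basis, cfg, units_by_class, seed_maze) {
  trajs <- list(
    up = generate_helical_trajectory("up", cfg$helix_points_per_run,
                                     child_seed(seed_maze, 1)),
    down = generate_helical_trajectory("down", cfg$helix_points_per_run,
                                       child_seed(seed_maze, 2)))
  encs <- lapply(trajs, path_integration, basis = basis, beta = cfg$beta)
  acts <- lapply(encs, function(e) encoder_activations(model, e))
  per_class <- lapply(units_by_class, function(units) {
    fields <- list()
    for (j in units) {
      profs <- lapply(names(trajs), function(nm) {
        ev <- threshold_events(acts[[nm]][, j], trajs[[nm]],
                               cfg$percentile, neuron_id = j)
        unwind_helix(ev, trajs[[nm]])
      })
      combined <- combine_coil_profiles(profs)
      pts <- helix_event_points(profs, unname(trajs))
      ff <- helix_fields(combined, event_points = pts,
                         rate_threshold = cfg$rate_threshold,
                         merge_radius = cfg$merge_radius)
      for (f in ff) f$unit <- j
      fields <- c(fields, ff)
    }
    if (length(fields) == 0) {
      return(list(fields = fields, major = numeric(0), minor = numeric(0),
                  aspect = numeric(0), coils_spanned = integer(0),
                  pct_five_coils = NA_real_))
    }
    coils <- vapply(fields, `[[`, integer(1), "n_coils_spanned")
    list(fields = fields,
         major = vapply(fields, `[[`, numeric(1), "major"),
         minor = vapply(fields, `[[`, numeric(1), "minor"),
         aspect = vapply(fields, `[[`, numeric(1), "aspect"),
         coils_spanned = coils,
         pct_five_coils = 100 * mean(coils == 5))
  })
  c(list(trajectories = trajs), per_class)
}

analyse_pegboard <- function(model, basis, cfg, units_by_class,
                             seed_maze) {
  maze <- generate_pegboard_trajectory(cfg$pegboard_n_hops,
                                       cfg$maze_n_points, seed_maze)
  enc <- path_integration(maze, basis, cfg$beta)
  act <- encoder_activations(model, enc)
  per_class <- lapply(units_by_class, function(units) {
    fields <- list()
    horiz_info <- vert_info <- numeric(0)
    for (j in units) {
      ev <- threshold_events(act[, j], maze, cfg$percentile,
                             neuron_id = j)
      map <- rate_map_2d(ev, maze, bins = cfg$bins,
                         smoothing = cfg$smoothing, dims = c(2, 3))
      hi <- tryCatch(axis_spatial_information(map, "horizontal"),
                     undefined_statistic = function(e) NA_real_)
      vi <- tryCatch(axis_spatial_information(map, "vertical"),
                     undefined_statistic = function(e) NA_real_)
      horiz_info <- c(horiz_info, hi)
      vert_info <- c(vert_info, vi)
      ff <- extract_fields_2d(map, cfg$rate_threshold, cfg$min_bins)
      for (f in ff) f$unit <- j
      fields <- c(fields, ff)
    }
    if (length(fields) == 0) {
      return(list(fields = fields, major = numeric(0), minor = numeric(0),
                  aspect = numeric(0), layers = integer(0),
                  pct_five_layers = NA_real_, horizontal_info = horiz_info,
                  vertical_info = vert_info))
    }
    layers <- vapply(fields, count_vertical_layers, integer(1),
                     z_range = c(0, 10), n_layers = 5)
    list(fields = fields,
         major = vapply(fields, `[[`, numeric(1), "major"),
         minor = vapply(fields, `[[`, numeric(1), "minor"),
         aspect = vapply(fields, `[[`, numeric(1), "aspect"),
         layers = layers,
         pct_five_layers = 100 * mean(layers == 5),
         horizontal_info = horiz_info, vertical_info = vert_info)
  })
  c(list(maze = maze), per_class)
}

#' Run one full experiment protocol
#'
#' Executes the protocol end to end: generate the flat-arena training
#' trajectory, encode it through the head-direction and path-integration
#' layers, train the linear autoencoder, classify the bottleneck units as
#' place / grid cells on the flat arena, then test the classified units on
#' the protocol's 3D maze and compute its field statistics. Fully
#' deterministic given the master seed (stage seeds are fixed offsets of
#' it).
#'
#' @param config an [experiment_config()].
#' @return An object of class `"experiment_report"` with the unit
#'   classification table, `place_fraction` and `grid_fraction` (over the
#'   bottleneck width), flat-arena field statistics, the maze analysis
#'   (protocol-dependent), and a `headline` named vector of summary
#'   statistics.
#' @export
run_experiment <- function(config) {
  cfg <- config
  s_traj <- child_seed(cfg$seed, 101L)
  s_model <- child_seed(cfg$seed, 202L)
  s_shuffle <- child_seed(cfg$seed, 303L)
  s_maze <- child_seed(cfg$seed, 404L)
  s_analysis <- child_seed(cfg$seed, 505L)

  flat <- generate_flat_trajectory(cfg$arena_size, cfg$n_points, s_traj)
  basis <- preferred_directions(cfg$n1, cfg$n2)
  enc <- path_integration(flat, basis, cfg$beta)
  model <- train_autoencoder(enc, model_config(
    hidden = cfg$hidden, epochs = cfg$epochs,
    train_fraction = cfg$train_fraction,
    learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
    encoder_layer = cfg$encoder_layer, seed = s_model))
  act <- encoder_activations(model, enc)
  cls <- classify_units(act, flat, rate_quantile = cfg$rate_quantile,
                        bins = cfg$bins, smoothing = cfg$smoothing,
                        n_shuffles = cfg$n_shuffles, seed = s_shuffle)
  n_units <- nrow(cls)
  place_units <- cls$unit[cls$is_place]
  grid_units <- cls$unit[cls$grid_class == "hexagonal"]

  flat_stats <- list(
    place = flat_field_stats(place_units, act, flat, cfg),
    grid = flat_field_stats(grid_units, act, flat, cfg))

  maze <- NULL
  if (cfg$run_maze_analysis) {
    maze <- switch(
      cfg$protocol,
      lattice_aligned = ,
      lattice_tilted = analyse_lattice(model, basis, cfg, place_units,
                                       s_maze, s_analysis),
      helix = analyse_helix(model, basis, cfg,
                            list(place = place_units, grid = grid_units),
                            s_maze),
      pegboard = analyse_pegboard(model, basis, cfg,
                                  list(place = place_units,
                                       grid = grid_units),
                                  s_maze))
  }

  headline <- c(place_pct = 100 * length(place_units) / n_units,
                grid_pct = 100 * length(grid_units) / n_units)
  if (!is.null(maze)) {
    if (cfg$protocol %in% c("helix")) {
      headline <- c(headline,
                    place_major_mean = mean(maze$place$major),
                    place_minor_mean = mean(maze$place$minor),
                    place_aspect_mean = mean(maze$place$aspect),
                    place_pct_five_coils = maze$place$pct_five_coils,
                    grid_major_mean = mean(maze$grid$major),
                    grid_minor_mean = mean(maze$grid$minor),
                    grid_aspect_mean = mean(maze$grid$aspect),
                    grid_pct_five_coils = maze$grid$pct_five_coils)
    } else if (cfg$protocol == "pegboard") {
      headline <- c(headline,
                    place_major_mean = mean(maze$place$major),
                    place_minor_mean = mean(maze$place$minor),
                    place_aspect_mean = mean(maze$place$aspect),
                    place_pct_five_layers = maze$place$pct_five_layers,
                    grid_major_mean = mean(maze$grid$major),
                    grid_minor_mean = mean(maze$grid$minor),
                    grid_aspect_mean = mean(maze$grid$aspect),
                    grid_pct_five_layers = maze$grid$pct_five_layers,
                    place_horizontal_info = mean(maze$place$horizontal_info,
                                                 na.rm = TRUE),
                    place_vertical_info = mean(maze$place$vertical_info,
                                               na.rm = TRUE))
    } else {
      headline <- c(headline, n_place_fields = maze$n_fields)
    }
  }

  structure(list(protocol = cfg$protocol, seed = cfg$seed, config = cfg,
                 model = model, classification = cls,
                 n_units = n_units,
                 place_units = place_units, grid_units = grid_units,
                 place_fraction = length(place_units) / n_units,
                 grid_fraction = length(grid_units) / n_units,
                 flat_fields = flat_stats, maze = maze,
                 headline = headline),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: %s, seed %d>\n", x$protocol, x$seed))
  cat(sprintf("  %d/%d units place cells (%.0f%%), %d/%d hexagonal grid cells (%.0f%%)\n",
              length(x$place_units), x$n_units, 100 * x$place_fraction,
              length(x$grid_units), x$n_units, 100 * x$grid_fraction))
  cat("  headline statistics:\n")
  for (nm in names(x$headline)) {
    cat(sprintf("    %-24s %.3f\n", nm, x$headline[nm]))
  }
  invisible(x)
}

#' Replicate an experiment over several seeds
#'
#' Runs [run_experiment()] once per seed and aggregates the headline
#' statistics (mean and standard deviation across replicates).
#'
#' @param config an [experiment_config()]; its seed is replaced per
#'   replicate.
#' @param n_replicates number of replicates (>= 2) when `seeds` is NULL.
#' @param seeds optional explicit vector of master seeds.
#' @return A list of class `"replicate_report"` with `per_replicate`
#'   (data frame, one row per seed), `mean`, `sd` and the replicate
#'   reports.
#' @export
replicate_experiment <- function(config, n_replicates = 5, seeds = NULL) {
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_replicates), function(i) {
      child_seed(config$seed, 1000L + i)
    }, integer(1))
  }
  if (length(seeds) < 2) stop_invalid("need at least 2 replicates")
  reports <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    run_experiment(cfg)
  })
  tab <- do.call(rbind, lapply(reports, function(r) r$headline))
  per <- data.frame(seed = seeds, tab)
  structure(list(per_replicate = per,
                 mean = colMeans(tab, na.rm = TRUE),
                 sd = apply(tab, 2, stats::sd, na.rm = TRUE),
                 reports = reports),
            class = "replicate_report")
}

#' @export
print.replicate_report <- function(x, ...) {
  cat(sprintf("<replicate_report: %d replicates of %s>\n",
              nrow(x$per_replicate), x$reports[[1]]$protocol))
  for (nm in names(x$mean)) {
    cat(sprintf("  %-24s %.3f +/- %.3f\n", nm, x$mean[nm], x$sd[nm]))
  }
  invisible(x)
}
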