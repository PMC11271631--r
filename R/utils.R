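#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state so seeded helpers do not clobber the
# caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic fan-out of a master seed into per-stage child seeds, kept
# within the 32-bit integer range.
child_seed <- function(seed, stage) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + stage) %% 2147483647)
}

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("invalid_argument", "error")))
}

stop_undefined <- function(msg) {
  stop(errorCondition(msg, class = c("undefined_statistic", "error")))
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop_invalid(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

# Fold an unbounded coordinate into [lo, hi] by repeated mirror reflection
# (billiard dynamics): the reflected walk in a box equals the free walk
# composed with this triangle-wave map.
fold_reflect <- function(u, lo, hi) {
  w <- hi - lo
  v <- (u - lo) %% (2 * w)
  lo + ifelse(v > w, 2 * w - v, v)
}

# Proper rotation by `angle` radians about a coordinate axis (1 = x, 2 = y,
# 3 = z).
rotation_about_axis <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  R <- diag(3)
  ix <- setdiff(1:3, axis)
  R[ix[1], ix[1]] <- c_; R[ix[2], ix[2]] <- c_
  R[ix[1], ix[2]] <- -s_; R[ix[2], ix[1]] <- s_
  R
}

# Resample a densely sampled polyline to n equidistant (arc-length) points.
resample_arclength <- function(pos, n_points) {
  d <- sqrt(rowSums(diff(pos)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_points)
  out <- vapply(seq_len(ncol(pos)), function(j) {
    stats::approx(s, pos[, j], xout = target, ties = "ordered")$y
  }, numeric(n_points))
  matrix(out, nrow = n_points)
}
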