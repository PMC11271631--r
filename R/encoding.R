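#' Head-direction basis of preferred directions
#'
#' Builds the matrix of preferred directions of the head-direction layer:
#' `n1` equally spaced azimuth angles \eqn{\theta} spanning 360 degrees
#' crossed with `n2` equally spaced pitch angles \eqn{\phi} spanning 180
#' degrees, mapped to unit vectors
#' \deqn{U_i = (\sin\phi_i \cos\theta_i,\; \sin\phi_i \sin\theta_i,\;
#'   \cos\phi_i).}
#' Azimuths are sampled as \eqn{\theta_i = 2\pi i / n_1}, `i = 0..n1-1`;
#' pitches span the closed interval \[0, \eqn{\pi}\] endpoint-inclusive
#' (`n2 = 3` gives 0, 90 and 180 degrees; at the poles all azimuths map to
#' the same vertical vector, which simply duplicates those features), and
#' a single pitch (`n2 = 1`) sits at 90 degrees (horizontal).
#'
#' @param n1 number of preferred azimuth angles (>= 1).
#' @param n2 number of preferred pitch angles (>= 1).
#' @param phis optional explicit pitch angles (radians), overriding the
#'   default sampling.
#' @return An object of class `"direction_basis"`: a list with `n1`, `n2`,
#'   `thetas`, `phis` and the `(n1 * n2) x 3` unit-vector matrix `U` (azimuth
#'   varying fastest).
#' @export
preferred_directions <- function(n1, n2, phis = NULL) {
  n1 <- check_count(n1, "n1", min = 1)
  n2 <- check_count(n2, "n2", min = 1)
  thetas <- 2 * pi * (seq_len(n1) - 1) / n1
  if (is.null(phis)) {
    phis <- if (n2 == 1) pi / 2 else seq(0, pi, length.out = n2)
  }
  if (length(phis) != n2) stop_invalid("`phis` must have length n2")
  th <- rep(thetas, times = n2)
  ph <- rep(phis, each = n1)
  U <- cbind(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
  colnames(U) <- c("x", "y", "z")
  structure(list(n1 = n1, n2 = n2, thetas = thetas, phis = phis, U = U),
            class = "direction_basis")
}

#' @export
print.direction_basis <- function(x, ...) {
  cat(sprintf("<direction_basis: %d azimuths x %d pitches = %d directions>\n",
              x$n1, x$n2, nrow(x$U)))
  invisible(x)
}

#' Head-direction layer response
#'
#' The response of the i-th head-direction cell to a velocity `v` is the dot
#' product with its preferred direction, `HD_i = v . U_i`.
#'
#' @param velocity numeric 3-vector.
#' @param basis a [preferred_directions()] basis.
#' @return Numeric vector of length `n1 * n2`.
#' @export
hd_response <- function(velocity, basis) {
  if (length(velocity) != 3 || any(!is.finite(velocity))) {
    stop_invalid("`velocity` must be a finite 3-vector")
  }
  drop(basis$U %*% velocity)
}

#' Path-integration layer responses
#'
#' The i-th path-integration neuron integrates the head-direction response
#' over time, `PI_i = cos(beta * integral of v . U_i dt)`; since the
#' integral of velocity is displacement, the closed form is
#' `PI_i = cos(beta * z . U_i)` with `z` the displacement from the
#' trajectory's first point, making the response purely a function of
#' position. The autoencoder input concatenates the cosine and sine terms,
#' `[cos(beta z . U), sin(beta z . U)]`.
#'
#' @param traj a [trajectory()].
#' @param basis a [preferred_directions()] basis.
#' @param beta modulation factor (1/length units, > 0); sets the spatial
#'   period `2 * pi / beta` of the responses along each preferred direction.
#' @return An object of class `"encoded_input"`: a list with `features`
#'   (T x 2m matrix, cosine block then sine block, m = n1 * n2), `m`,
#'   `beta`, `n1`, `n2`.
#' @export
path_integration <- function(traj, basis, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0) {
    stop_invalid("`beta` must be a positive scalar")
  }
  pos <- traj$positions
  if (is.null(pos) || nrow(pos) < 1) stop_invalid("empty trajectory")
  z <- sweep(pos, 2, pos[1, ])
  phase <- beta * (z %*% t(basis$U))
  features <- cbind(cos(phase), sin(phase))
  structure(list(features = features, m = nrow(basis$U), beta = beta,
                 n1 = basis$n1, n2 = basis$n2),
            class = "encoded_input")
}

#' Path-integration cosine responses
#'
#' The cosine block `cos(beta z . U)` of an encoded input.
#'
#' @param enc an [path_integration()] result.
#' @return T x m matrix.
#' @export
pi_values <- function(enc) {
  enc$features[, seq_len(enc$m), drop = FALSE]
}

#' @export
print.encoded_input <- function(x, ...) {
  cat(sprintf("<encoded_input: %d time points, %d directions, beta = %g>\n",
              nrow(x$features), x$m, x$beta))
  invisible(x)
}
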