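#' Autoencoder configuration
#'
#' Hyperparameters of the linear autoencoder. The defaults are the settings
#' used throughout the simulation protocols: two hidden layers of 50 linear
#' units, mean-squared-error loss, 10 training epochs and a contiguous 4:1
#' train/validation split of the time series (contiguous rather than
#' shuffled because adjacent trajectory samples are strongly
#' autocorrelated). The optimiser is Adam with step size 1e-3 and batch
#' size 256.
#'
#' @param hidden sizes of the two hidden layers.
#' @param epochs number of training epochs.
#' @param train_fraction fraction of rows used for training (rest is the
#'   validation block).
#' @param learning_rate,batch_size Adam step size and minibatch size.
#' @param encoder_layer which hidden layer is read out as the bottleneck
#'   (1 or 2); layer 1 is analysed by default.
#' @param seed integer seed for weight initialisation and batch order.
#' @return A list of class `"ae_config"`.
#' @export
model_config <- function(hidden = c(50, 50), epochs = 10,
                         train_fraction = 0.8, learning_rate = 1e-3,
                         batch_size = 256, encoder_layer = 1, seed = 1) {
  stopifnot(length(hidden) == 2, all(hidden >= 1))
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 train_fraction = train_fraction,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 encoder_layer = as.integer(encoder_layer),
                 seed = as.integer(seed)),
            class = "ae_config")
}

ae_init <- function(input_dim, hidden, seed) {
  dims <- c(input_dim, hidden, input_dim)
  with_seed(seed, {
    W <- lapply(1:3, function(l) {
      lim <- 1 / sqrt(dims[l])
      matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim),
             dims[l], dims[l + 1])
    })
    b <- lapply(1:3, function(l) numeric(dims[l + 1]))
    list(W = W, b = b)
  })
}

#' Fit the linear autoencoder
#'
#' Trains the three-layer linear autoencoder (input -> hidden1 -> hidden2 ->
#' reconstruction) on path-integration features by minimising mean squared
#' reconstruction error with Adam. With linear activations the network
#' spans at best the same subspace as PCA with rank equal to the bottleneck
#' width, and its bottleneck units develop the place- and grid-cell-like
#' spatial tuning analysed by the rest of the package.
#'
#' @param features an [path_integration()] encoded input, or a plain numeric
#'   matrix (rows = time points).
#' @param config a [model_config()].
#' @return An object of class `"spatial_autoencoder"`: weights `W` (list of
#'   3 matrices), biases `b`, the `config`, `input_dim`, and `history`
#'   (data frame of per-epoch train/validation MSE).
#' @export
train_autoencoder <- function(features, config = model_config()) {
  X <- if (inherits(features, "encoded_input")) features$features else
    as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (n < 10) stop_invalid("need at least 10 feature rows")
  n_train <- max(1L, floor(config$train_fraction * n))
  Xtr <- X[seq_len(n_train), , drop = FALSE]
  Xva <- if (n_train < n) X[(n_train + 1):n, , drop = FALSE] else NULL

  par <- ae_init(d, config$hidden, config$seed)
  m <- lapply(c(par$W, par$b), function(p) p * 0)
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())

  mse_of <- function(Z) {
    H1 <- sweep(Z %*% par$W[[1]], 2, par$b[[1]], `+`)
    H2 <- sweep(H1 %*% par$W[[2]], 2, par$b[[2]], `+`)
    Y <- sweep(H2 %*% par$W[[3]], 2, par$b[[3]], `+`)
    mean((Y - Z)^2)
  }

  if (config$epochs > 0) {
    with_seed(child_seed(config$seed, 17L), {
      nb <- ceiling(n_train / config$batch_size)
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(n_train)
        ep_loss <- 0
        for (bi in seq_len(nb)) {
          rows <- ord[((bi - 1) * config$batch_size + 1):
                        min(bi * config$batch_size, n_train)]
          Z <- Xtr[rows, , drop = FALSE]
          H1 <- sweep(Z %*% par$W[[1]], 2, par$b[[1]], `+`)
          H2 <- sweep(H1 %*% par$W[[2]], 2, par$b[[2]], `+`)
          Y <- sweep(H2 %*% par$W[[3]], 2, par$b[[3]], `+`)
          E <- Y - Z
          ep_loss <- ep_loss + mean(E^2) * length(rows)
          dY <- 2 * E / length(E)
          g <- vector("list", 6)
          g[[3]] <- crossprod(H2, dY); g[[6]] <- colSums(dY)
          dH2 <- dY %*% t(par$W[[3]])
          g[[2]] <- crossprod(H1, dH2); g[[5]] <- colSums(dH2)
          dH1 <- dH2 %*% t(par$W[[2]])
          g[[1]] <- crossprod(Z, dH1); g[[4]] <- colSums(dH1)
          step <- step + 1L
          corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
          for (k in 1:6) {
            m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g[[k]]
            v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g[[k]]^2
            upd <- lr * (m[[k]] / corr1) / (sqrt(v[[k]] / corr2) + eps)
            if (k <= 3) par$W[[k]] <- par$W[[k]] - upd
            else par$b[[k - 3]] <- par$b[[k - 3]] - upd
          }
        }
        history <- rbind(history, data.frame(
          epoch = ep, train_mse = ep_loss / n_train,
          val_mse = if (is.null(Xva)) NA_real_ else mse_of(Xva)))
      }
    })
  }

  structure(list(W = par$W, b = par$b, config = config, input_dim = d,
                 n_train = n_train, history = history),
            class = "spatial_autoencoder")
}

#' @export
print.spatial_autoencoder <- function(x, ...) {
  cat(sprintf("<spatial_autoencoder: %d-%d-%d-%d linear, %d epochs>\n",
              x$input_dim, x$config$hidden[1], x$config$hidden[2],
              x$input_dim, x$config$epochs))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train MSE %.4g, validation MSE %.4g\n",
                last$train_mse, last$val_mse))
  }
  invisible(x)
}

#' @export
summary.spatial_autoencoder <- function(object, ...) {
  structure(list(model = object), class = "summary.spatial_autoencoder")
}

#' @export
print.summary.spatial_autoencoder <- function(x, ...) {
  print(x$model)
  cat(sprintf("  parameters: %d weights + %d biases; seed %d\n",
              sum(vapply(x$model$W, length, 0L)),
              sum(vapply(x$model$b, length, 0L)), x$model$config$seed))
  if (nrow(x$model$history) > 0) {
    cat("  training history:\n")
    print(x$model$history, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.spatial_autoencoder <- function(object, ...) {
  list(W1 = object$W[[1]], b1 = object$b[[1]],
       W2 = object$W[[2]], b2 = object$b[[2]],
       W3 = object$W[[3]], b3 = object$b[[3]])
}

#' Predictions from the autoencoder
#'
#' @param object a fitted [train_autoencoder()] model.
#' @param newdata an encoded input or feature matrix.
#' @param type `"reconstruction"` for the network output, `"encoder"` for
#'   the bottleneck activations of the configured encoder layer.
#' @param ... unused.
#' @return Numeric matrix (T x input_dim or T x hidden width).
#' @export
predict.spatial_autoencoder <- function(object, newdata,
                                        type = c("reconstruction", "encoder"),
                                        ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "encoded_input")) newdata$features else
    as.matrix(newdata)
  if (ncol(X) != object$input_dim) {
    stop_invalid(sprintf("feature dimension %d does not match input_dim %d",
                         ncol(X), object$input_dim))
  }
  H1 <- sweep(X %*% object$W[[1]], 2, object$b[[1]], `+`)
  if (type == "encoder" && object$config$encoder_layer == 1) return(H1)
  H2 <- sweep(H1 %*% object$W[[2]], 2, object$b[[2]], `+`)
  if (type == "encoder") return(H2)
  sweep(H2 %*% object$W[[3]], 2, object$b[[3]], `+`)
}

#' Bottleneck activations of the encoder layer
#'
#' Convenience wrapper around [predict.spatial_autoencoder()] returning the
#' per-time-point activations of the analysed hidden layer (one column per
#' bottleneck unit).
#'
#' @inheritParams predict.spatial_autoencoder
#' @param features an encoded input or feature matrix.
#' @return T x hidden-width activation matrix.
#' @export
encoder_activations <- function(object, features) {
  predict(object, features, type = "encoder")
}

#' @export
residuals.spatial_autoencoder <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "encoded_input")) newdata$features else
    as.matrix(newdata)
  X - predict(object, newdata, type = "reconstruction")
}

#' @export
fitted.spatial_autoencoder <- function(object, newdata, ...) {
  predict(object, newdata, type = "reconstruction")
}

#' @export
plot.spatial_autoencoder <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::plot(h$epoch, h$train_mse, type = "b", pch = 16,
                 xlab = "epoch", ylab = "MSE",
                 ylim = range(c(h$train_mse, h$val_mse), na.rm = TRUE), ...)
  if (any(!is.na(h$val_mse))) {
    graphics::lines(h$epoch, h$val_mse, type = "b", pch = 1, lty = 2)
    graphics::legend("topright", c("train", "validation"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
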