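#' Architecture of the phase-unwrapping network
#'
#' The unwrapper is a plain fully-convolutional stack: `n_blocks` repetitions
#' of (convolution `kernel_size` x `kernel_size` with `n_features` features,
#' batch normalization, ReLU) followed by a final convolution with 2 output
#' features (the `L` and `A` channels). Same-padding everywhere and no
#' pooling or striding, so the output has the shape of the input and images
#' of any size can be processed. The full-scale architecture is 20 blocks of
#' 32 features; `scale = "reduced"` (6 blocks, 16 features) is a CPU-sized
#' variant used by the test suite and desk-scale demonstrations.
#'
#' @param n_blocks number of conv+BN+ReLU blocks; default 20 (full) or
#'   6 (reduced).
#' @param kernel_size odd convolution kernel side; default 5.
#' @param n_features features per hidden convolution; default 32 (full) or
#'   16 (reduced).
#' @param scale `"full"` or `"reduced"`.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(n_blocks = NULL, kernel_size = 5L,
                         n_features = NULL, scale = c("full", "reduced")) {
  scale <- match.arg(scale)
  if (is.null(n_blocks)) n_blocks <- if (scale == "full") 20L else 6L
  if (is.null(n_features)) n_features <- if (scale == "full") 32L else 16L
  stopifnot(n_blocks >= 1, kernel_size %% 2 == 1, n_features >= 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 kernel_size = as.integer(kernel_size),
                 n_features = as.integer(n_features),
                 n_out_channels = 2L, scale = scale),
            class = "network_spec")
}

#' Training protocol for the unwrapping network
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4,
#' 10 epochs of 12,800 random 121 x 121 vignette pairs. The reduced test
#' protocol overrides these with far smaller values. Channel normalization
#' constants divide the `L` and `A` channels before they enter the network
#' (and are undone on prediction); `L` is normalized by the wavelength so a
#' one-wave jump has unit magnitude.
#'
#' @param learning_rate Adam step size.
#' @param n_epochs number of epochs.
#' @param vignettes_per_epoch vignette pairs drawn per epoch.
#' @param vignette_size crop side length (pixels).
#' @param batch_size minibatch size.
#' @param l_scale,a_scale channel normalization constants for L (um) and A.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, n_epochs = 10L,
                         vignettes_per_epoch = 12800L, vignette_size = 121L,
                         batch_size = 32L, l_scale = 0.450, a_scale = 1) {
  stopifnot(learning_rate > 0, n_epochs >= 1, vignettes_per_epoch >= 1,
            vignette_size >= 1, batch_size >= 1, l_scale > 0, a_scale > 0)
  structure(list(learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 vignettes_per_epoch = as.integer(vignettes_per_epoch),
                 vignette_size = as.integer(vignette_size),
                 batch_size = as.integer(batch_size),
                 l_scale = l_scale, a_scale = a_scale),
            class = "train_config")
}

#' Build an untrained unwrapping network
#'
#' Convolution weights use He initialization (`sd = sqrt(2 / fan_in)`,
#' drawn from the R session RNG, so `set.seed()` makes the build
#' reproducible); batch-norm scales start at 1 and shifts at 0.
#'
#' @param spec a [network_spec].
#' @return object of class `unwrap_net` (untrained).
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  k <- spec$kernel_size
  he <- function(cin, cout) {
    matrix(stats::rnorm(cout * k * k * cin, sd = sqrt(2 / (k * k * cin))),
           nrow = cout)
  }
  layers <- vector("list", spec$n_blocks)
  cin <- spec$n_out_channels
  for (b in seq_len(spec$n_blocks)) {
    cf <- spec$n_features
    layers[[b]] <- list(W = he(cin, cf), b = rep(0, cf),
                        gamma = rep(1, cf), beta = rep(0, cf),
                        run_mean = rep(0, cf), run_var = rep(1, cf))
    cin <- cf
  }
  final <- list(W = he(cin, spec$n_out_channels),
                b = rep(0, spec$n_out_channels))
  structure(list(spec = spec, layers = layers, final = final,
                 norm = list(l_scale = 0.450, a_scale = 1),
                 training_Z = NA_real_, trained = FALSE,
                 loss_history = numeric(0)),
            class = "unwrap_net")
}

#' Number of learnable parameters of the network
#'
#' Convolution weights and biases plus the batch-norm scale/shift pairs
#' (running statistics are buffers, not parameters).
#'
#' @param net an `unwrap_net`.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  n <- 0L
  for (l in net$layers) {
    n <- n + length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  }
  n + length(net$final$W) + length(net$final$b)
}

#' @export
print.unwrap_net <- function(x, ...) {
  cat(sprintf("<unwrap_net> %d blocks x %d features (k=%d), %d parameters, %s\n",
              x$spec$n_blocks, x$spec$n_features, x$spec$kernel_size,
              n_parameters(x),
              if (x$trained) sprintf("trained (Z = %.4g um)", x$training_Z)
              else "untrained"))
  invisible(x)
}

bn_eps <- 1e-5

# Forward pass in training mode over a batch stored as (H, W, C, N) arrays.
# Returns the output batch plus the caches needed for backprop.
net_forward_train <- function(net, x) {
  k <- net$spec$kernel_size
  caches <- vector("list", length(net$layers))
  for (bi in seq_along(net$layers)) {
    l <- net$layers[[bi]]
    N <- dim(x)[4]
    z <- array(0, c(dim(x)[1], dim(x)[2], nrow(l$W), N))
    for (s in seq_len(N)) {
      z[, , , s] <- conv2d_fwd(x[, , , s, drop = FALSE][, , , 1], l$W, l$b, k)
    }
    cf <- nrow(l$W)
    m <- length(z) / cf
    mu <- apply(z, 3, mean)
    va <- apply(z, 3, function(v) mean((v - mean(v))^2))
    xhat <- z
    for (c in seq_len(cf)) {
      xhat[, , c, ] <- (z[, , c, ] - mu[c]) / sqrt(va[c] + bn_eps)
    }
    y <- xhat
    for (c in seq_len(cf)) {
      y[, , c, ] <- l$gamma[c] * xhat[, , c, ] + l$beta[c]
    }
    mask <- y > 0
    y[!mask] <- 0
    caches[[bi]] <- list(input = x, z = z, xhat = xhat, mu = mu, va = va,
                         mask = mask, m = m)
    x <- y
  }
  N <- dim(x)[4]
  out <- array(0, c(dim(x)[1], dim(x)[2], net$spec$n_out_channels, N))
  for (s in seq_len(N)) {
    out[, , , s] <- conv2d_fwd(x[, , , s, drop = FALSE][, , , 1],
                               net$final$W, net$final$b, k)
  }
  list(out = out, caches = caches, last_hidden = x)
}

# Backward pass: returns gradients in the same structure as the parameters.
net_backward <- function(net, fwd, dout) {
  k <- net$spec$kernel_size
  N <- dim(dout)[4]
  x <- fwd$last_hidden
  dW_f <- matrix(0, nrow(net$final$W), ncol(net$final$W))
  db_f <- rep(0, length(net$final$b))
  dx <- array(0, dim(x))
  for (s in seq_len(N)) {
    g <- conv2d_bwd(x[, , , s, drop = FALSE][, , , 1], net$final$W, k,
                    dout[, , , s, drop = FALSE][, , , 1])
    dW_f <- dW_f + g$dW
    db_f <- db_f + g$db
    dx[, , , s] <- g$dx
  }
  grads <- list(final = list(W = dW_f, b = db_f),
                layers = vector("list", length(net$layers)))
  for (bi in rev(seq_along(net$layers))) {
    l <- net$layers[[bi]]
    cache <- fwd$caches[[bi]]
    dy <- dx
    dy[!cache$mask] <- 0
    cf <- length(l$gamma)
    m <- cache$m
    dgamma <- numeric(cf); dbeta <- numeric(cf)
    dz <- array(0, dim(cache$z))
    for (c in seq_len(cf)) {
      dyc <- dy[, , c, ]
      xh <- cache$xhat[, , c, ]
      dgamma[c] <- sum(dyc * xh)
      dbeta[c] <- sum(dyc)
      dxh <- dyc * l$gamma[c]
      inv_sd <- 1 / sqrt(cache$va[c] + bn_eps)
      # standard batch-norm backward over the m = N*H*W elements
      dz[, , c, ] <- inv_sd / m *
        (m * dxh - sum(dxh) - xh * sum(dxh * xh))
    }
    xin <- cache$input
    dW <- matrix(0, nrow(l$W), ncol(l$W))
    db <- rep(0, nrow(l$W))
    dx <- array(0, dim(xin))
    for (s in seq_len(N)) {
      g <- conv2d_bwd(xin[, , , s, drop = FALSE][, , , 1], l$W, k,
                      dz[, , , s, drop = FALSE][, , , 1])
      dW <- dW + g$dW
      db <- db + g$db
      dx[, , , s] <- g$dx
    }
    grads$layers[[bi]] <- list(W = dW, b = db, gamma = dgamma, beta = dbeta)
  }
  grads
}

# Inference-mode forward for a single (H, W, 2) array, using running
# batch-norm statistics.
net_forward_infer <- function(net, x) {
  k <- net$spec$kernel_size
  for (l in net$layers) {
    z <- conv2d_fwd(x, l$W, l$b, k)
    cf <- nrow(l$W)
    for (c in seq_len(cf)) {
      z[, , c] <- l$gamma[c] * (z[, , c] - l$run_mean[c]) /
        sqrt(l$run_var[c] + bn_eps) + l$beta[c]
    }
    z[z < 0] <- 0
    x <- z
  }
  conv2d_fwd(x, net$final$W, net$final$b, k)
}

maps_to_input <- function(maps, norm) {
  array(c(maps$L / norm$l_scale, maps$A / norm$a_scale),
        dim = c(dim(maps$L), 2L))
}

#' Train the unwrapping network
#'
#' Adam optimization of the mean-squared error between predicted and
#' ground-truth `(L, A)` vignettes. Each epoch draws
#' `config$vignettes_per_epoch` random crops from the supplied training
#' pairs (identical windows for input and target) and iterates minibatches;
#' batch-norm uses batch statistics during training and updates running
#' statistics (momentum 0.1) that inference uses afterwards. All randomness
#' flows through the R session RNG, so `set.seed()` makes a run
#' reproducible. If the loss becomes non-finite, training aborts and the
#' last finite-loss epoch's weights are returned.
#'
#' @param net an `unwrap_net` from [build_network()].
#' @param pairs list of training pairs (`input`/`target` [sample_maps]),
#'   e.g. from [build_training_set()]; full images or pre-cut vignettes.
#' @param config a [train_config].
#' @param training_Z the sample-sensor distance (um) the training holograms
#'   were simulated at; stored with the model (the unwrapper is Z-specific).
#' @param validation_pairs optional held-out vignette pairs; the mean
#'   validation loss per epoch is logged alongside the training loss.
#' @return the trained `unwrap_net`, with `loss_history` (one row per
#'   epoch: `epoch`, `train_loss`, optional `val_loss`).
#' @export
train_unwrapper <- function(net, pairs, config = train_config(),
                            training_Z = NA_real_,
                            validation_pairs = NULL) {
  stopifnot(inherits(net, "unwrap_net"), inherits(config, "train_config"))
  net$norm <- list(l_scale = config$l_scale, a_scale = config$a_scale)
  dims <- dim(pairs[[1]]$input$L)
  vsize <- min(config$vignette_size, dims[1], dims[2])

  adam_m <- list(); adam_v <- list()
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0

  update <- function(param, grad, key) {
    if (is.null(adam_m[[key]])) {
      adam_m[[key]] <<- grad * 0
      adam_v[[key]] <<- grad * 0
    }
    m <- b1 * adam_m[[key]] + (1 - b1) * grad
    v <- b2 * adam_v[[key]] + (1 - b2) * grad^2
    adam_m[[key]] <<- m
    adam_v[[key]] <<- v
    mh <- m / (1 - b1^step)
    vh <- v / (1 - b2^step)
    param - config$learning_rate * mh / (sqrt(vh) + eps)
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  checkpoint <- net

  for (epoch in seq_len(config$n_epochs)) {
    vigs <- extract_vignettes(pairs, size = vsize,
                              n = config$vignettes_per_epoch)
    n_batches <- ceiling(length(vigs) / config$batch_size)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      sel <- vigs[((bi - 1) * config$batch_size + 1):
                    min(bi * config$batch_size, length(vigs))]
      N <- length(sel)
      x <- array(0, c(vsize, vsize, 2L, N))
      y <- array(0, c(vsize, vsize, 2L, N))
      for (s in seq_len(N)) {
        x[, , , s] <- maps_to_input(sel[[s]]$input, net$norm)
        y[, , , s] <- maps_to_input(sel[[s]]$target, net$norm)
      }
      fwd <- net_forward_train(net, x)
      resid <- fwd$out - y
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        warning("training loss became non-finite; returning last checkpoint",
                call. = FALSE)
        checkpoint$loss_history <- history
        return(checkpoint)
      }
      epoch_loss <- epoch_loss + loss * N
      dout <- 2 * resid / length(resid)
      grads <- net_backward(net, fwd, dout)
      step <- step + 1
      net$final$W <- update(net$final$W, grads$final$W, "final.W")
      net$final$b <- update(net$final$b, grads$final$b, "final.b")
      for (li in seq_along(net$layers)) {
        for (p in c("W", "b", "gamma", "beta")) {
          net$layers[[li]][[p]] <- update(net$layers[[li]][[p]],
                                          grads$layers[[li]][[p]],
                                          paste0("layer", li, ".", p))
        }
        # running statistics from the last processed batch
        cache <- fwd$caches[[li]]
        net$layers[[li]]$run_mean <-
          0.9 * net$layers[[li]]$run_mean + 0.1 * cache$mu
        net$layers[[li]]$run_var <-
          0.9 * net$layers[[li]]$run_var + 0.1 * cache$va
      }
    }
    train_loss <- epoch_loss / length(vigs)
    val_loss <- NA_real_
    if (!is.null(validation_pairs)) {
      vl <- 0
      tmp <- net
      tmp$trained <- TRUE
      for (vp in validation_pairs) {
        pred <- net_forward_infer(tmp, maps_to_input(vp$input, net$norm))
        vl <- vl + mean((pred - maps_to_input(vp$target, net$norm))^2)
      }
      val_loss <- vl / length(validation_pairs)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    checkpoint <- net
  }
  net$trained <- TRUE
  net$training_Z <- training_Z
  net$loss_history <- history
  net
}

#' Predict unwrapped maps from a wrapped first reconstruction
#'
#' Normalizes the input maps with the model's stored constants, runs the
#' fully-convolutional network in inference mode (frozen batch-norm running
#' statistics) at the input's own resolution, and de-normalizes the two
#' output channels back to physical units.
#'
#' @param object a trained `unwrap_net`.
#' @param maps wrapped [sample_maps] (e.g. a first-reconstruction result).
#' @param ... unused.
#' @return predicted [sample_maps] with the same shape and pitch.
#' @export
predict.unwrap_net <- function(object, maps, ...) {
  stopifnot(inherits(maps, "sample_maps"))
  if (min(dim(maps$L)) < object$spec$kernel_size) {
    stop("input smaller than the convolution kernel footprint")
  }
  out <- net_forward_infer(object, maps_to_input(maps, object$norm))
  sample_maps(out[, , 1] * object$norm$l_scale,
              out[, , 2] * object$norm$a_scale,
              maps$pixel_pitch)
}
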