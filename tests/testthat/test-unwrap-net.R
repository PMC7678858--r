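test_that("network construction matches the architecture contract", {
  set.seed(50)
  spec <- network_spec(scale = "reduced")
  expect_equal(spec$n_blocks, 6L)
  expect_equal(spec$n_features, 16L)
  net <- build_network(spec)

  # closed-form parameter count: conv weights + biases + BN scale/shift
  k <- spec$kernel_size
  expected <- 0L
  cin <- 2L
  for (b in seq_len(spec$n_blocks)) {
    expected <- expected + k * k * cin * spec$n_features +
      spec$n_features + 2L * spec$n_features
    cin <- spec$n_features
  }
  expected <- expected + k * k * cin * 2L + 2L
  expect_equal(n_parameters(net), expected)

  # full-scale spec builds and counts correctly too
  full <- build_network(network_spec())
  expect_equal(full$spec$n_blocks, 20L)
  kf <- 5L
  expected_full <- (kf^2 * 2 * 32 + 32 + 64) +
    19L * (kf^2 * 32 * 32 + 32 + 64) + (kf^2 * 32 * 2 + 2)
  expect_equal(n_parameters(full), expected_full)

  # fully convolutional: output shape equals input shape at any size
  net$trained <- TRUE
  for (sz in list(c(17L, 23L), c(48L, 48L), c(121L, 121L))) {
    m <- sample_maps(matrix(0.1, sz[1], sz[2]), matrix(-0.1, sz[1], sz[2]),
                     1.67)
    out <- predict(net, m)
    expect_equal(dim(out$L), sz)
    expect_equal(dim(out$A), sz)
  }
  expect_error(predict(net, sample_maps(matrix(0, 3, 3), matrix(0, 3, 3),
                                        1.67)), "kernel footprint")
})

test_that("backpropagation matches finite differences on a tiny network", {
  set.seed(51)
  spec <- network_spec(n_blocks = 2L, kernel_size = 3L, n_features = 4L,
                       scale = "reduced")
  net <- build_network(spec)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  y <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  loss_of <- function(net) {
    fwd <- holocell:::net_forward_train(net, x)
    mean((fwd$out - y)^2)
  }
  fwd <- holocell:::net_forward_train(net, x)
  resid <- fwd$out - y
  grads <- holocell:::net_backward(net, fwd, 2 * resid / length(resid))

  h <- 1e-6
  check <- function(getter, setter, g, idx) {
    for (i in idx) {
      np <- net; np <- setter(np, i, getter(net, i) + h)
      nm <- net; nm <- setter(nm, i, getter(net, i) - h)
      fd <- (loss_of(np) - loss_of(nm)) / (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-4)
    }
  }
  # a few weights of the first conv, the final conv, and BN parameters
  check(function(n, i) n$layers[[1]]$W[i],
        function(n, i, ...) { n$layers[[1]]$W[i] <- ..1; n },
        grads$layers[[1]]$W, c(1, 7, 20))
  check(function(n, i) n$final$W[i],
        function(n, i, ...) { n$final$W[i] <- ..1; n },
        grads$final$W, c(2, 11))
  check(function(n, i) n$layers[[2]]$gamma[i],
        function(n, i, ...) { n$layers[[2]]$gamma[i] <- ..1; n },
        grads$layers[[2]]$gamma, c(1, 3))
  check(function(n, i) n$layers[[2]]$beta[i],
        function(n, i, ...) { n$layers[[2]]$beta[i] <- ..1; n },
        grads$layers[[2]]$beta, c(2))
})

test_that("training reduces the loss deterministically", {
  set.seed(52)
  pitch <- 1.67
  # toy mapping: target L is input L plus a constant offset
  pairs <- lapply(1:6, function(i) {
    L <- matrix(runif(32 * 32, 0, 0.2), 32, 32)
    list(input = sample_maps(L, matrix(-0.05, 32, 32), pitch),
         target = sample_maps(L + 0.1, matrix(-0.05, 32, 32), pitch))
  })
  spec <- network_spec(n_blocks = 3L, kernel_size = 3L, n_features = 8L,
                       scale = "reduced")
  cfg <- train_config(learning_rate = 1e-3, n_epochs = 3,
                      vignettes_per_epoch = 40, vignette_size = 16,
                      batch_size = 8)
  set.seed(53)
  net0 <- build_network(spec)
  net <- train_unwrapper(net0, pairs, cfg, training_Z = 1270)
  hist <- net$loss_history
  expect_equal(nrow(hist), 3)
  expect_lt(hist$train_loss[3], hist$train_loss[1])
  expect_true(net$trained)
  expect_equal(net$training_Z, 1270)

  set.seed(53)
  net_b <- train_unwrapper(build_network(spec), pairs, cfg,
                           training_Z = 1270)
  expect_identical(net$loss_history$train_loss,
                   net_b$loss_history$train_loss)
  expect_identical(net$final$W, net_b$final$W)
})

test_that("prediction is pure, bounded, and tiles consistently", {
  set.seed(54)
  net <- build_network(network_spec(n_blocks = 3L, kernel_size = 3L,
                                    n_features = 8L, scale = "reduced"))
  net$trained <- TRUE
  zeros <- sample_maps(matrix(0, 32, 32), matrix(0, 32, 32), 1.67)
  out0 <- predict(net, zeros)
  expect_true(all(is.finite(out0$L)) && all(is.finite(out0$A)))

  m <- random_maps(64)
  m_copy <- m
  full <- predict(net, m)
  expect_identical(m, m_copy)   # input untouched

  # fully-convolutional contract: an overlapping tile reproduces the full
  # prediction away from its borders (margin = receptive field radius)
  tile <- sample_maps(m$L[1:48, 1:48], m$A[1:48, 1:48], 1.67)
  pt <- predict(net, tile)
  margin <- 3 * 1 + 1  # n_blocks * (k-1)/2 + final layer
  inner <- (margin + 1):(48 - margin)
  expect_equal(pt$L[inner, inner], full$L[inner, inner], tolerance = 1e-10)
})
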