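test_that("forward pass applies affine maps and activations per layer", {
  # zero parameters with sigmoid output -> 0.5 everywhere
  net <- network_spec(c(3, 2), "sigmoid", init_seed = 1)
  net$W[[1]][] <- 0; net$b[[1]][] <- 0
  expect_equal(forward_pass(net, c(1, -2, 3)), c(0.5, 0.5))

  # identity linear layer reproduces the input
  id <- network_spec(c(4, 4), "linear", init_seed = 1)
  id$W[[1]] <- diag(4); id$b[[1]][] <- 0
  x <- c(0.3, -1, 2, 0)
  expect_equal(forward_pass(id, x), x)

  # two-layer toy net against hand-computed arithmetic
  toy <- network_spec(c(2, 2, 1), c("tanh", "linear"), init_seed = 1)
  toy$W[[1]] <- matrix(c(1, 0, -1, 2), 2, 2); toy$b[[1]] <- c(0.5, -0.5)
  toy$W[[2]] <- matrix(c(2, 1), 2, 1); toy$b[[2]] <- 0.25
  x <- c(0.2, 0.4)
  h <- tanh(c(0.2 * 1 + 0.4 * 0 + 0.5, 0.2 * -1 + 0.4 * 2 - 0.5))
  expect_equal(forward_pass(toy, x), 2 * h[1] + 1 * h[2] + 0.25)

  expect_error(forward_pass(toy, c(1, 2, 3)), "features")
  expect_error(network_spec(c(3, 2), c("relu", "relu")), "one activation")
  expect_error(network_spec(c(3, 2), "softmax"), "unknown activation")
})

test_that("initialization is reproducible under a seed", {
  n1 <- network_spec(c(5, 8, 2), c("relu", "sigmoid"), init_seed = 7)
  n2 <- network_spec(c(5, 8, 2), c("relu", "sigmoid"), init_seed = 7)
  expect_identical(n1$W, n2$W)
  n3 <- network_spec(c(5, 8, 2), c("relu", "sigmoid"), init_seed = 8)
  expect_false(identical(n1$W, n3$W))
})

test_that("backpropagated gradients match finite differences on tiny nets", {
  fwdc <- mitgan:::net_forward_cache; bwd <- mitgan:::net_backward
  set.seed(3)
  G <- network_spec(c(3, 4, 2), c("tanh", "sigmoid"), init_seed = 5)
  D <- network_spec(c(2, 3, 1), c("leaky_relu", "sigmoid"), init_seed = 6)
  X <- matrix(rnorm(18), 6, 3); Y <- matrix(runif(12), 6, 2)
  eps <- 1e-6
  fd_check <- function(net, loss, analytic) {
    for (l in seq_along(net$W)) for (i in seq_along(net$W[[l]])) {
      up <- net; up$W[[l]][i] <- up$W[[l]][i] + eps
      dn <- net; dn$W[[l]][i] <- dn$W[[l]][i] - eps
      fd <- (loss(up) - loss(dn)) / (2 * eps)
      expect_equal(analytic$gW[[l]][i], fd, tolerance = 1e-4)
    }
  }

  # supervised L2 loss
  cache <- fwdc(G, X)
  out <- cache$A[[length(cache$A)]]
  gL2 <- bwd(G, cache, 2 * (out - Y) / length(Y))
  fd_check(G, function(n) mean((forward_pass(n, X) - Y)^2), gL2)

  # adversarial discriminator loss
  fake <- forward_pass(G, X); M <- nrow(X)
  cr <- fwdc(D, Y); cf <- fwdc(D, fake)
  dr <- cr$A[[3]]; df <- cf$A[[3]]
  gr <- bwd(D, cr, -1 / (M * dr)); gf <- bwd(D, cf, 1 / (M * (1 - df)))
  gD <- list(gW = Map("+", gr$gW, gf$gW))
  fd_check(D, function(n)
    -(mean(log(forward_pass(n, Y))) +
      mean(log(1 - forward_pass(n, fake)))), gD)

  # adversarial generator loss, gradient flowing through the discriminator
  cg <- fwdc(G, X); fake <- cg$A[[3]]
  cf <- fwdc(D, fake); df <- cf$A[[3]]
  gG <- bwd(G, cg, bwd(D, cf, -1 / (M * (1 - df)))$dX)
  fd_check(G, function(n)
    mean(log(1 - forward_pass(D, forward_pass(n, X)))), gG)
})

test_that("supervised training reduces the loss and can memorize a tiny set", {
  corpus <- make_tiny_corpus()
  ctrl <- mit_control(pretrain_epochs = 60, pretrain_batch = 8,
                      learning_rate = 2e-3, seed = 2)
  spec <- network_spec(c(56, 32, small_grid$active_count),
                       c("tanh", "sigmoid"), init_seed = 2)
  fit <- mit_bpnn(corpus$set, spec = spec, control = ctrl)
  h <- fit$history$train_mse
  expect_lt(h[length(h)], h[1])
  out <- predict(fit, corpus$raw)
  expect_true(all(out > 0 & out < 1))   # sigmoid output range

  # memorization: ample epochs on 10 samples drive per-pixel MSE < 1e-3
  ten <- mitgan:::subset_samples(corpus$set, 1:10)
  fit10 <- mit_bpnn(ten, spec = spec,
                    control = mit_control(pretrain_epochs = 2000,
                                          pretrain_batch = 10,
                                          learning_rate = 5e-3,
                                          l2_coeff = 0, seed = 3))
  pred <- forward_pass(fit10$network, ten$voltages)
  expect_lt(mean((pred - ten$conductivities)^2), 1e-3)

  expect_error(mit_bpnn(corpus$raw), "normalized")
})

test_that("training histories are reproducible given config and seed", {
  corpus <- make_tiny_corpus()
  ctrl <- mit_control(pretrain_epochs = 15, pretrain_batch = 8,
                      learning_rate = 1e-3, seed = 9)
  spec <- network_spec(c(56, 16, small_grid$active_count),
                       c("tanh", "sigmoid"), init_seed = 9)
  f1 <- mit_bpnn(corpus$set, spec = spec, control = ctrl)
  f2 <- mit_bpnn(corpus$set, spec = spec, control = ctrl)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$W, f2$network$W)
})
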