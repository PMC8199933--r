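test_that("optimal discriminator is the pointwise density ratio", {
  expect_equal(optimal_discriminator(c(1, 2, 3), c(1, 2, 3)), rep(0.5, 3))
  expect_equal(optimal_discriminator(0.2, 0.6), 0.25)
  expect_equal(optimal_discriminator(c(0.4, 1), c(0, 0)), c(1, 1))
  expect_error(optimal_discriminator(0, 0), "undefined")
  expect_error(optimal_discriminator(-1, 2), "non-negative")
  expect_error(optimal_discriminator(c(1, 2), 1), "equal length")
})

test_that("a toy 1-D GAN drives the discriminator toward 0.5 on real samples", {
  # distribution matching: generator maps uniform noise to a narrow
  # unimodal target density on (0, 1)
  set.seed(31)
  n <- 512
  noise <- matrix(runif(n), n, 1)
  real <- matrix(pmin(pmax(rnorm(n, 0.6, 0.08), 0.01), 0.99), n, 1)
  toy <- structure(list(
    voltages = noise, conductivities = real,
    provenance = vector("list", n), side_count = 1L, field_radius = 0.1,
    background = 0, normalized = TRUE,
    normalization = list(voltage = list(min = 0, max = 1),
                         conductivity = list(min = 0, max = 1)),
    split = list(train = 1:n, validation = integer(0), test = integer(0)),
    seed = 31L), class = "mit_samples")
  ctrl <- mit_control(pretrain_epochs = 0, gan_epochs = 400, gan_batch = 128,
                      learning_rate = 2e-3, gan_fidelity = 0, gan_adversarial = 1,
                                       non_saturating = TRUE,
                      select_best_val = FALSE, seed = 31)
  fit <- mit_gan(toy,
                 gen_spec = network_spec(c(1, 16, 16, 1),
                                         c("tanh", "tanh", "sigmoid"), 31),
                 disc_spec = network_spec(c(1, 16, 1),
                                          c("leaky_relu", "sigmoid"), 32),
                 control = ctrl)
  d_real <- mean(forward_pass(fit$discriminator, real))
  expect_gt(d_real, 0.4)
  expect_lt(d_real, 0.6)
  # the generated density overlaps the target
  fake <- forward_pass(fit$network, noise)
  expect_lt(abs(mean(fake) - mean(real)), 0.1)
})

test_that("generator loss is the discriminator's fake-sample term (antisymmetry)", {
  # the saturating generator objective mean log(1 - D(G(V))) is literally
  # the fake-sample term of the value function, so any generator step that
  # lowers one lowers the other by the same amount
  set.seed(41)
  G <- network_spec(c(4, 8, 3), c("tanh", "sigmoid"), 41)
  D <- network_spec(c(3, 8, 1), c("leaky_relu", "sigmoid"), 42)
  X <- matrix(rnorm(40), 10, 4)
  gen_loss <- function(G) mean(log(1 - forward_pass(D, forward_pass(G, X))))
  value_fake_term <- gen_loss
  before <- gen_loss(G)
  cg <- mitgan:::net_forward_cache(G, X)
  fake <- cg$A[[length(cg$A)]]
  cf <- mitgan:::net_forward_cache(D, fake)
  df <- cf$A[[length(cf$A)]]
  gr <- mitgan:::net_backward(G, cg,
                              mitgan:::net_backward(D, cf,
                                                    -1 / (nrow(X) * (1 - df)))$dX)
  for (l in seq_along(G$W)) G$W[[l]] <- G$W[[l]] - 0.05 * gr$gW[[l]]
  after <- gen_loss(G)
  expect_lt(after, before)
  expect_equal(value_fake_term(G), after)
})

test_that("stopping rule fires immediately for a near-perfect generator", {
  corpus <- make_tiny_corpus()
  spec <- network_spec(c(56, 32, small_grid$active_count),
                       c("tanh", "sigmoid"), init_seed = 12)
  pre <- mit_bpnn(corpus$set, spec = spec,
                  control = mit_control(pretrain_epochs = 300,
                                        pretrain_batch = 16,
                                        learning_rate = 5e-3, seed = 12))
  # pretraining has driven the validation error far below the threshold
  expect_lt(tail(pre$history$val_mse, 1), 0.05)
  fit <- mit_gan(corpus$set, pretrain = pre,
                 control = mit_control(pretrain_epochs = 0, gan_epochs = 50,
                                       gan_batch = 32, learning_rate = 1e-4,
                                       seed = 12))
  expect_identical(fit$stop_reason, "converged")
  expect_lte(length(fit$history$gen_err), 5)
})

test_that("adversarial fine-tuning does not degrade validation MSE materially", {
  corpus <- make_tiny_corpus()
  spec <- network_spec(c(56, 32, small_grid$active_count),
                       c("tanh", "sigmoid"), init_seed = 13)
  ctrl <- mit_control(pretrain_epochs = 80, pretrain_batch = 16,
                      learning_rate = 2e-3, gan_epochs = 30, gan_batch = 32,
                      seed = 13)
  pre <- mit_bpnn(corpus$set, spec = spec, control = ctrl)
  fit <- mit_gan(corpus$set, pretrain = pre, control = ctrl)
  pre_val <- tail(pre$history$val_mse, 1)
  expect_lte(fit$selected_val_mse, 1.2 * pre_val)
})

test_that("reconstruction is deterministic, shaped and localized", {
  corpus <- make_tiny_corpus()
  ctrl <- mit_control(pretrain_epochs = 120, pretrain_batch = 16,
                      learning_rate = 2e-3, gan_epochs = 10, gan_batch = 32,
                      seed = 14)
  fit <- mit_gan(corpus$set,
                 gen_spec = network_spec(c(56, 32, small_grid$active_count),
                                         c("tanh", "sigmoid"), 14),
                 control = ctrl)
  # held-out single-anomaly sample
  truth_spec <- anomaly(0.035, 77)
  ph <- place_anomalies(small_grid, list(truth_spec))
  fr <- forward_project(small_sens, ph)
  img <- reconstruct(fit, fr)
  expect_s3_class(img, "mit_image")
  expect_length(img$values, small_grid$active_count)
  norm <- fit$normalization$conductivity
  expect_true(all(img$values >= norm$min - 1e-9))
  expect_true(all(img$values <= norm$max + 1e-9))
  expect_identical(img$values, reconstruct(fit, fr)$values)

  # centroid of the reconstructed anomaly within two radii of the truth
  w <- pmax(norm$max - img$values, 0)  # weight toward low conductivity
  cen <- colSums(small_grid$pixel_centers * w) / sum(w)
  truth_cen <- mitgan:::anomaly_center(truth_spec)
  expect_lt(sqrt(sum((cen - truth_cen)^2)), 2 * truth_spec$radius)

  # frames must come in raw measurement units
  expect_error(predict(fit, corpus$set), "raw")
})
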