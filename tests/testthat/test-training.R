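fc_only_config <- function() {
  network_config(32L, list(
    layer_spec("fc", node_count = 2L, activation = "none"),
    layer_spec("softmax")))
}

test_that("momentum update follows the classical velocity recursion", {
  cfg <- fc_only_config()
  p <- init_parameters(cfg, scheme = "zero")
  ones <- list(list(dweights = matrix(1, 2, 1024), dbias = rep(1, 2)), NULL)
  # two steps with mu = 0.9, eta = 0.1, g = 1:
  # v1 = -0.1, w1 = -0.1; v2 = -0.19, w2 = -0.29
  p <- momentum_update(p, ones, lr = 0.1, mu = 0.9)
  expect_equal(unique(as.numeric(p[[1]]$weights)), -0.1)
  p <- momentum_update(p, ones, lr = 0.1, mu = 0.9)
  expect_equal(unique(as.numeric(p[[1]]$weights)), -0.29)
  expect_equal(unique(as.numeric(p[[1]]$v_weights)), -0.19)
  expect_equal(unique(p[[1]]$bias), -0.29)
})

test_that("zero momentum reduces to plain SGD and zero gradient is a no-op", {
  cfg <- fc_only_config()
  p0 <- init_parameters(cfg, seed = 401L)
  g <- list(list(dweights = matrix(rnorm(2048), 2, 1024),
                 dbias = rnorm(2)), NULL)
  p1 <- momentum_update(p0, g, lr = 0.05, mu = 0)
  expect_equal(p1[[1]]$weights, p0[[1]]$weights - 0.05 * g[[1]]$dweights)
  zero <- list(list(dweights = matrix(0, 2, 1024), dbias = numeric(2)), NULL)
  p2 <- momentum_update(p0, zero, lr = 0.05, mu = 0)
  expect_identical(p2[[1]]$weights, p0[[1]]$weights)
  bad <- list(list(dweights = matrix(0, 3, 5), dbias = numeric(2)), NULL)
  expect_error(momentum_update(p0, bad, 0.1, 0.9), "mismatch")
})

test_that("learning-rate schedule decays by 5/6 per post-threshold epoch", {
  cfg_const <- training_config(schedule = "constant")
  cfg_decay <- training_config(learning_rate = 5e-4,
                               schedule = "decay_on_precision")
  st <- noduleCNN:::new_training_state(cfg_const)
  expect_equal(update_learning_rate(st, 0.99, cfg_const)$lr, 5e-4)
  st <- noduleCNN:::new_training_state(cfg_decay)
  st <- update_learning_rate(st, 0.80, cfg_decay)
  expect_equal(st$lr, 5e-4)  # threshold never met
  st <- update_learning_rate(st, 0.86, cfg_decay)
  expect_equal(st$lr, 5e-4 * 5 / 6)
  # decay keeps firing even if precision later drops below the threshold
  st <- update_learning_rate(st, 0.70, cfg_decay)
  st <- update_learning_rate(st, 0.90, cfg_decay)
  expect_equal(st$lr, 5e-4 * (5 / 6)^3)
  # one-shot mode decays exactly once
  cfg_once <- training_config(schedule = "decay_on_precision",
                              decay_mode = "one_shot")
  st <- noduleCNN:::new_training_state(cfg_once)
  st <- update_learning_rate(st, 0.9, cfg_once)
  st <- update_learning_rate(st, 0.95, cfg_once)
  expect_equal(st$lr, 5e-4 * 5 / 6)
})

test_that("epochs are deterministic given the seed and shuffle every pass", {
  ds <- generate_dataset(generator_spec(20L, 20L, exams = 4L, seed = 402L))
  cfg <- tiny_config_32()
  tc <- training_config(learning_rate = 0.01, max_epochs = 2L,
                        batch_size = 8L, seed = 403L)
  f1 <- train(ds, cfg, tc)
  f2 <- train(ds, cfg, tc)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$state$history, f2$state$history)
  tc2 <- tc; tc2$seed <- 404L
  f3 <- train(ds, cfg, tc2)
  expect_false(identical(f1$params, f3$params))
})

test_that("batch_size >= n performs exactly one update per epoch", {
  ds <- generate_dataset(generator_spec(10L, 10L, exams = 2L, seed = 405L))
  cfg <- fc_only_config()
  p0 <- init_parameters(cfg, seed = 406L)
  st <- noduleCNN:::new_training_state(
    training_config(learning_rate = 0.01, momentum = 0.9, batch_size = 64L))
  ep <- run_epoch(ds, cfg, p0, st,
                  training_config(learning_rate = 0.01, momentum = 0.9,
                                  batch_size = 64L))
  # with zero initial velocity, one update means w - w0 == v exactly
  expect_equal(ep$params[[1]]$weights - p0[[1]]$weights,
               ep$params[[1]]$v_weights)
  expect_error(run_epoch(dataset_subset(ds, integer(0)), cfg, p0, st,
                         training_config()), "empty")
})

test_that("training precision is the fraction of matched labels", {
  ds <- generate_dataset(generator_spec(12L, 8L, exams = 4L, seed = 407L))
  cfg <- fc_only_config()
  pz <- init_parameters(cfg, scheme = "zero")
  # symmetric logits -> ties -> constant nonnodule predictor
  expect_equal(compute_training_precision(cfg, pz, ds), 8 / 20)
  expect_equal(predict_dataset(cfg, pz, ds), rep(0L, 20L))
})

test_that("training overfits a single example to near-zero loss", {
  ds <- generate_dataset(generator_spec(1L, 0L, seed = 408L))
  tc <- training_config(learning_rate = 0.01, momentum = 0, batch_size = 1L,
                        max_epochs = 60L, seed = 409L)
  fit <- train(ds, default_config_32(), tc)
  loss <- fit$state$history$loss
  expect_true(all(diff(loss[1:10]) < 0))  # strictly decreasing early on
  expect_lt(loss[length(loss)], 0.05)
  expect_equal(compute_training_precision(default_config_32(), fit$params, ds), 1)
})

test_that("termination honors target accuracy, the epoch cap and convergence", {
  ds <- generate_dataset(generator_spec(10L, 10L, exams = 2L, seed = 410L))
  cfg <- tiny_config_32()
  f1 <- train(ds, cfg, training_config(max_epochs = 3L, target_accuracy = 0,
                                       seed = 411L))
  expect_equal(f1$state$epoch, 1L)
  expect_equal(f1$stopped, "target_accuracy")
  f2 <- train(ds, cfg, training_config(max_epochs = 4L, seed = 411L))
  expect_equal(f2$stopped, "max_epochs")
  expect_lte(nrow(f2$state$history), 4L)
  # a vanishing learning rate stalls the loss; the convergence rule fires
  f3 <- train(ds, cfg, training_config(learning_rate = 1e-300,
                                       max_epochs = 50L, seed = 411L))
  expect_equal(f3$stopped, "converged")
  expect_equal(f3$state$epoch, 6L)  # 5 consecutive stalled epochs after the first
})

test_that("a loss-decreasing step direction holds for small plain-SGD steps", {
  set.seed(412)
  ds <- generate_dataset(generator_spec(6L, 6L, exams = 2L, seed = 413L))
  cfg <- tiny_config_32()
  p <- init_parameters(cfg, seed = 414L)
  batch_loss <- function(pp) mean(vapply(seq_len(length(ds)), function(i)
    cross_entropy_loss(nn_forward(cfg, pp, ds$patches[i, , ])$probs,
                       ds$labels[i]), numeric(1)))
  acc <- NULL
  for (i in seq_len(length(ds))) {
    fw <- nn_forward(cfg, p, ds$patches[i, , ])
    acc <- noduleCNN:::sum_grads(acc, nn_backward(cfg, p, fw$cache, ds$labels[i]))
  }
  g <- noduleCNN:::scale_grads(acc, 1 / length(ds))
  p2 <- momentum_update(p, g, lr = 1e-4, mu = 0)
  expect_lt(batch_loss(p2), batch_loss(p))
})

test_that("learned behaviour separates a high-contrast synthetic set", {
  counts <- mirror_ratio_counts(300)
  ds <- generate_dataset(generator_spec(counts[1], counts[2], exams = 10L,
                                        seed = 415L))
  tc <- training_config(learning_rate = 0.005, max_epochs = 10L, seed = 416L)
  fit <- train(ds, tiny_config_32(), tc)
  expect_gte(max(fit$state$history$precision), 0.75)
  expect_lt(fit$state$history$loss[10], fit$state$history$loss[1])
})
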