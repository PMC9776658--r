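test_that("forward pass yields normalized, finite class probabilities", {
  net <- init_network(tiny_model_config(), seed = 3)
  p <- forward_pass(net, tiny_sample(1))
  expect_length(p, 4)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))

  # degenerate all-zero input stays finite
  p0 <- forward_pass(net, array(0, c(12, 12, 3, 4)))
  expect_true(all(is.finite(p0)))
  expect_equal(sum(p0), 1, tolerance = 1e-6)

  expect_error(forward_pass(net, array(0, c(12, 12, 3))), "array")
})

test_that("streams are neither weight-shared nor cross-wired", {
  net <- init_network(tiny_model_config(), seed = 5)
  s <- tiny_sample(2)
  p1 <- forward_pass(net, s)
  # swapping the first two fused images changes the output:
  # streams have their own weights
  s_swap <- s
  s_swap[, , , 1] <- s[, , , 2]
  s_swap[, , , 2] <- s[, , , 1]
  p2 <- forward_pass(net, s_swap)
  expect_gt(max(abs(p1 - p2)), 1e-8)

  # stream isolation: perturbing image 2 leaves stream 1's descriptor alone
  xb <- fallstream:::samples_to_branches(list(s), net$config)
  f1 <- fallstream:::net_forward(net, xb, training = FALSE)
  s_pert <- s
  s_pert[, , , 2] <- pmin(s[, , , 2] * 2, 1)
  xb2 <- fallstream:::samples_to_branches(list(s_pert), net$config)
  f2 <- fallstream:::net_forward(net, xb2, training = FALSE)
  nb_ch <- net$config$branch_conv_filters[length(net$config$branch_conv_filters)]
  expect_equal(f1$cache$concat[, 1:nb_ch], f2$cache$concat[, 1:nb_ch])
  expect_gt(max(abs(f1$cache$concat[, (nb_ch + 1):(2 * nb_ch)] -
                    f2$cache$concat[, (nb_ch + 1):(2 * nb_ch)])), 0)
})

test_that("analytic gradients match numeric differentiation", {
  cfg <- tiny_model_config()
  net <- init_network(cfg, seed = 7)
  samples <- lapply(1:3, function(i) tiny_sample(40 + i, n_images = 2))
  labels <- factor(c("standing", "falling", "other"), levels = fall_phases())
  grads <- compute_gradients(net, samples, labels)
  loss_of <- function(net) {
    xb <- fallstream:::samples_to_branches(samples, net$config)
    fwd <- fallstream:::net_forward(net, xb, training = TRUE)
    -mean(log(fwd$probs[cbind(1:3, as.integer(labels))]))
  }
  eps <- 1e-5
  set.seed(99)
  for (nm in names(grads)) {
    i <- sample(length(net$params[[nm]]), 1)
    n2 <- net
    n2$params[[nm]][i] <- net$params[[nm]][i] + eps
    lp <- loss_of(n2)
    n2$params[[nm]][i] <- net$params[[nm]][i] - eps
    lm <- loss_of(n2)
    num <- (lp - lm) / (2 * eps)
    ana <- grads[[nm]][i]
    if (abs(num) + abs(ana) > 1e-5)
      expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
  }
})

test_that("gradient reaches every learnable parameter of the full model", {
  net <- init_network(model_config(), seed = 2)
  set.seed(13)
  samples <- lapply(1:4, function(i)
    array(runif(128 * 128 * 3 * 4), c(128, 128, 3, 4)))
  labels <- factor(fall_phases(), levels = fall_phases())
  grads <- compute_gradients(net, samples, labels)
  expect_setequal(names(grads), names(net$params))
  dead <- names(grads)[!vapply(grads, function(g) any(g != 0), TRUE)]
  # conv biases feed straight into batchnorm mean-subtraction, so their
  # gradient is identically zero by construction; everything else must move
  expect_true(all(grepl("_conv[0-9]+_b$", dead)),
              info = paste("dead:", paste(dead, collapse = ", ")))
})

test_that("initialization and training are deterministic under a seed", {
  cfg <- tiny_model_config()
  n1 <- init_network(cfg, seed = 42)
  n2 <- init_network(cfg, seed = 42)
  expect_identical(n1$params, n2$params)
  n3 <- init_network(cfg, seed = 43)
  expect_false(identical(n3$params, n1$params))

  set.seed(8)
  samples <- lapply(1:12, function(i) tiny_sample(100 + i))
  labels <- factor(rep(fall_phases(), 3), levels = fall_phases())
  tc <- train_config(epochs = 2, minibatch = 4, seed = 9)
  f1 <- train_network(init_network(cfg, seed = 1), samples, labels, cfg = tc)
  f2 <- train_network(init_network(cfg, seed = 1), samples, labels, cfg = tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)
})

test_that("training reduces loss on a small separable problem", {
  cfg <- tiny_model_config()
  # class-coded constant images: trivially separable
  set.seed(3)
  samples <- lapply(1:24, function(i) {
    cls <- (i - 1) %% 4
    array(cls / 4 + runif(12 * 12 * 3 * 4, 0, 0.05), c(12, 12, 3, 4))
  })
  labels <- factor(fall_phases()[((seq_len(24) - 1) %% 4) + 1],
                   levels = fall_phases())
  fit <- train_network(init_network(cfg, seed = 4), samples, labels,
                       cfg = train_config(epochs = 20, minibatch = 8, seed = 5))
  h <- fit$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  p <- predict_network(fit$net, samples)
  expect_gte(mean(max.col(p) == as.integer(labels)), 0.9)
})
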