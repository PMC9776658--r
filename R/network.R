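## Trainable four-stream network. Dense tensors are R arrays in (H, W, C, N)
## layout; convolution and max-pooling run through the compiled im2col/GEMM
## primitives, batchnorm / relu / GAP / FC layers are vectorized R.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

#' Initialize a trainable four-stream network
#'
#' Allocates all learnable parameters of the model described by a
#' [model_config()]: per-stream convolution kernels and biases, batchnorm
#' scale/shift pairs with running statistics, and the shared fully connected
#' head. Weights use Glorot-uniform initialization from a seedable RNG;
#' biases start at 0, batchnorm at scale 1 / shift 0.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization (NULL uses the current
#'   RNG state).
#' @return An object of class `fall4s_network` holding the parameter list,
#'   batchnorm running statistics, the layer graph and the config.
#' @export
init_network <- function(config = model_config(), seed = 1L) {
  graph <- build_model(config)
  trace <- branch_trace(config)
  convs <- Filter(function(t) t$kind == "conv", trace)
  params <- list(); stats <- list()
  with_local_seed(seed, {
    for (b in seq_len(config$n_branches)) {
      for (tr in convs) {
        i <- tr$index
        k <- tr$kernel
        fan_in <- prod(k) * tr$in_c
        fan_out <- prod(k) * tr$out_c
        params[[sprintf("b%d_conv%d_W", b, i)]] <-
          glorot(c(k[1], k[2], tr$in_c, tr$out_c), fan_in, fan_out)
        params[[sprintf("b%d_conv%d_b", b, i)]] <- numeric(tr$out_c)
        params[[sprintf("b%d_bn%d_g", b, i)]] <- rep(1, tr$out_c)
        params[[sprintf("b%d_bn%d_B", b, i)]] <- numeric(tr$out_c)
        stats[[sprintf("b%d_bn%d_mean", b, i)]] <- numeric(tr$out_c)
        stats[[sprintf("b%d_bn%d_var", b, i)]] <- rep(1, tr$out_c)
      }
    }
    width <- graph$concat_width
    nf <- length(config$fc_widths)
    for (i in seq_len(nf)) {
      out <- config$fc_widths[i]
      params[[sprintf("fc%d_W", i)]] <- glorot(c(width, out), width, out)
      params[[sprintf("fc%d_b", i)]] <- numeric(out)
      if (i < nf) {
        params[[sprintf("fc_bn%d_g", i)]] <- rep(1, out)
        params[[sprintf("fc_bn%d_B", i)]] <- numeric(out)
        stats[[sprintf("fc_bn%d_mean", i)]] <- numeric(out)
        stats[[sprintf("fc_bn%d_var", i)]] <- rep(1, out)
      }
      width <- out
    }
  })
  structure(list(params = params, stats = stats, graph = graph,
                 config = config),
            class = "fall4s_network")
}

#' @export
print.fall4s_network <- function(x, ...) {
  cat(sprintf("<fall4s_network: %d streams, %d layers, %d parameters>\n",
              x$config$n_branches, nrow(x$graph$layers),
              x$graph$total_params))
  invisible(x)
}

BN_MOMENTUM <- 0.9
BN_EPS <- 1e-5

## Batchnorm over a (m x C) matrix whose columns are channels.
bn_mat_forward <- function(m, g, B, run_mean, run_var, training) {
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    run_mean <- BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu
    run_var <- BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(m, 2, mu, "-"), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, g, "*"), 2, B, "+")
  list(y = y, xhat = xhat, invstd = invstd,
       run_mean = run_mean, run_var = run_var)
}

bn_mat_backward <- function(dy, cache, g) {
  m <- nrow(dy)
  dg <- colSums(dy * cache$xhat)
  dB <- colSums(dy)
  k <- g * cache$invstd / m
  dx <- sweep(m * dy, 2, dB, "-") - sweep(cache$xhat, 2, dg, "*")
  sweep(dx, 2, k, "*")
}

gap_forward <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}
gap_backward <- function(ddesc, d) {
  array(rep(as.vector(t(ddesc)) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Forward pass. xb: list of (H,W,3,N) arrays, one per stream.
net_forward <- function(net, xb, training = FALSE) {
  cfg <- net$config
  p <- net$params; st <- net$stats
  nb <- cfg$n_branches
  cache <- list(xb = xb, branch = vector("list", nb))
  descs <- vector("list", nb)
  n_blocks <- length(cfg$branch_conv_filters)
  for (b in seq_len(nb)) {
    x <- xb[[b]]
    bc <- list()
    for (i in seq_len(n_blocks)) {
      s <- cfg$conv_strides[[i]]
      bc[[sprintf("conv%d_in", i)]] <- x
      x <- conv2d_forward(x, p[[sprintf("b%d_conv%d_W", b, i)]],
                          p[[sprintf("b%d_conv%d_b", b, i)]], s[1], s[2])
      bc[[sprintf("conv%d_out", i)]] <- x
      bn <- bn_relu_forward(x,
                            p[[sprintf("b%d_bn%d_g", b, i)]],
                            p[[sprintf("b%d_bn%d_B", b, i)]],
                            st[[sprintf("b%d_bn%d_mean", b, i)]],
                            st[[sprintf("b%d_bn%d_var", b, i)]],
                            training, BN_MOMENTUM, BN_EPS)
      if (training) {
        st[[sprintf("b%d_bn%d_mean", b, i)]] <- bn$run_mean
        st[[sprintf("b%d_bn%d_var", b, i)]] <- bn$run_var
      }
      x <- bn$y
      bc[[sprintf("bn%d", i)]] <- list(mean = bn$mean, invstd = bn$invstd)
      bc[[sprintf("relu%d_out", i)]] <- x
      pw <- cfg$pool_windows[[i]]; ps <- cfg$pool_strides[[i]]
      bc[[sprintf("pool%d_in_dim", i)]] <- dim(x)
      mp <- maxpool_forward(x, pw[1], pw[2], ps[1], ps[2])
      x <- mp$y
      bc[[sprintf("pool%d_idx", i)]] <- mp$idx
    }
    bc$gap_in_dim <- dim(x)
    descs[[b]] <- gap_forward(x)
    cache$branch[[b]] <- bc
  }
  h <- do.call(cbind, descs)
  cache$concat <- h
  nf <- length(cfg$fc_widths)
  for (i in seq_len(nf)) {
    cache[[sprintf("fc%d_in", i)]] <- h
    z <- h %*% p[[sprintf("fc%d_W", i)]]
    z <- sweep(z, 2, p[[sprintf("fc%d_b", i)]], "+")
    if (i < nf) {
      bn <- bn_mat_forward(z, p[[sprintf("fc_bn%d_g", i)]],
                           p[[sprintf("fc_bn%d_B", i)]],
                           st[[sprintf("fc_bn%d_mean", i)]],
                           st[[sprintf("fc_bn%d_var", i)]], training)
      if (training) {
        st[[sprintf("fc_bn%d_mean", i)]] <- bn$run_mean
        st[[sprintf("fc_bn%d_var", i)]] <- bn$run_var
      }
      cache[[sprintf("fc_bn%d", i)]] <- list(xhat = bn$xhat,
                                             invstd = bn$invstd)
      z <- bn$y
      z <- z * (z > 0)
      cache[[sprintf("fc_relu%d_out", i)]] <- z
      h <- z
    } else {
      h <- z
    }
  }
  probs <- softmax_rows(h)
  list(probs = probs, logits = h, cache = cache, stats = st)
}

## Backward pass from one-hot targets Y (N x classes). Returns named grads.
net_backward <- function(net, fwd, Y) {
  cfg <- net$config
  p <- net$params
  cache <- fwd$cache
  n <- nrow(Y)
  grads <- list()
  dz <- (fwd$probs - Y) / n
  nf <- length(cfg$fc_widths)
  for (i in rev(seq_len(nf))) {
    if (i < nf) {
      dz <- dz * (cache[[sprintf("fc_relu%d_out", i)]] > 0)
      bnc <- cache[[sprintf("fc_bn%d", i)]]
      grads[[sprintf("fc_bn%d_g", i)]] <- colSums(dz * bnc$xhat)
      grads[[sprintf("fc_bn%d_B", i)]] <- colSums(dz)
      dz <- bn_mat_backward(dz, bnc, p[[sprintf("fc_bn%d_g", i)]])
    }
    h_in <- cache[[sprintf("fc%d_in", i)]]
    grads[[sprintf("fc%d_W", i)]] <- crossprod(h_in, dz)
    grads[[sprintf("fc%d_b", i)]] <- colSums(dz)
    dz <- dz %*% t(p[[sprintf("fc%d_W", i)]])
  }
  nb <- cfg$n_branches
  n_blocks <- length(cfg$branch_conv_filters)
  last_c <- cfg$branch_conv_filters[n_blocks]
  for (b in seq_len(nb)) {
    bc <- cache$branch[[b]]
    ddesc <- dz[, ((b - 1) * last_c + 1):(b * last_c), drop = FALSE]
    dx <- gap_backward(ddesc, bc$gap_in_dim)
    for (i in rev(seq_len(n_blocks))) {
      dx <- maxpool_backward(dx, bc[[sprintf("pool%d_idx", i)]],
                             as.integer(bc[[sprintf("pool%d_in_dim", i)]]))
      bnc <- bc[[sprintf("bn%d", i)]]
      bb <- bn_relu_backward(bc[[sprintf("conv%d_out", i)]],
                             bc[[sprintf("relu%d_out", i)]], dx,
                             bnc$mean, bnc$invstd,
                             p[[sprintf("b%d_bn%d_g", b, i)]])
      grads[[sprintf("b%d_bn%d_g", b, i)]] <- bb$dg
      grads[[sprintf("b%d_bn%d_B", b, i)]] <- bb$dB
      dx <- bb$dx
      s <- cfg$conv_strides[[i]]
      cb <- conv2d_backward(bc[[sprintf("conv%d_in", i)]],
                            p[[sprintf("b%d_conv%d_W", b, i)]], dx,
                            s[1], s[2])
      grads[[sprintf("b%d_conv%d_W", b, i)]] <- cb$dw
      grads[[sprintf("b%d_conv%d_b", b, i)]] <- cb$db
      dx <- cb$dx
    }
  }
  grads
}

#' One forward/backward pass returning all parameter gradients
#'
#' Mainly for diagnostics: verifies that gradient flows to every learnable
#' parameter (no dead stream).
#'
#' @param net A `fall4s_network`.
#' @param samples List of samples, each an H x W x 3 x n_streams array or
#'   `fused_stack`.
#' @param labels Factor of class labels (levels in model class order).
#' @return Named list of gradient arrays matching `net$params`.
#' @export
compute_gradients <- function(net, samples, labels) {
  xb <- samples_to_branches(samples, net$config)
  Y <- label_onehot(labels, net$config$fc_widths[length(net$config$fc_widths)])
  fwd <- net_forward(net, xb, training = TRUE)
  net_backward(net, fwd, Y)
}

samples_to_branches <- function(samples, config) {
  samples <- lapply(samples, function(s) {
    if (inherits(s, "fused_stack")) stack_to_array(s) else s
  })
  d <- dim(samples[[1]])
  if (length(d) != 4 || d[4] < config$n_branches)
    stop_input("each sample must be an H x W x C x n_streams array")
  n <- length(samples)
  lapply(seq_len(config$n_branches), function(b) {
    out <- array(0, c(d[1], d[2], d[3], n))
    for (i in seq_len(n)) out[, , , i] <- samples[[i]][, , , b]
    out
  })
}

label_onehot <- function(labels, n_classes) {
  idx <- as.integer(labels)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > n_classes))
    stop_input("labels outside the model's class set")
  Y <- matrix(0, length(idx), n_classes)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

#' Class probabilities for one fused stack
#'
#' Runs the network in inference mode on a single sample. Stream k of the
#' network consumes fused image k only.
#'
#' @param net A `fall4s_network`.
#' @param sample A `fused_stack` or H x W x 3 x n_streams array.
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
forward_pass <- function(net, sample) {
  probs <- predict_network(net, list(sample))
  drop(probs)
}

#' Class probabilities for a list of samples
#'
#' @param net A `fall4s_network`.
#' @param samples List of samples (see [forward_pass()]).
#' @param minibatch Inference batch size.
#' @return N x n_classes matrix of probabilities, columns named by
#'   [fall_phases()] when the model has 4 classes.
#' @export
predict_network <- function(net, samples, minibatch = 16L) {
  n <- length(samples)
  nc <- net$config$fc_widths[length(net$config$fc_widths)]
  probs <- matrix(NA_real_, n, nc)
  for (s0 in seq(1, n, by = minibatch)) {
    s1 <- min(s0 + minibatch - 1, n)
    xb <- samples_to_branches(samples[s0:s1], net$config)
    probs[s0:s1, ] <- net_forward(net, xb, training = FALSE)$probs
  }
  if (nc == length(PHASES)) colnames(probs) <- PHASES
  probs
}

#' Training configuration
#'
#' Optimization settings for [train_network()] and [run_cv()]: Adam with the
#' given learning rate and moment decays, plus L2 regularization applied to
#' convolution and FC weights (not biases or batchnorm). The package default
#' is a desk-scale run (10 epochs); the full protocol uses 100 epochs with
#' the same learning rate 0.001, L2 0.0001 and minibatch 8.
#'
#' @param epochs Training epochs.
#' @param minibatch Minibatch size.
#' @param learning_rate Adam step size.
#' @param l2 L2 regularization factor on weights.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed Integer seed controlling shuffling (and fold assignment in
#'   [run_cv()]).
#' @param verbose Print per-epoch progress.
#' @return An object of class `fall4s_train_config`.
#' @export
train_config <- function(epochs = 10L, minibatch = 8L, learning_rate = 1e-3,
                         l2 = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, minibatch >= 1, learning_rate > 0, l2 >= 0)
  structure(list(epochs = as.integer(epochs),
                 minibatch = as.integer(minibatch),
                 learning_rate = learning_rate, l2 = l2,
                 beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "fall4s_train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(net, opt, grads, cfg) {
  opt$t <- opt$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  lr <- cfg$learning_rate
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (nm in names(net$params)) {
    g <- grads[[nm]]
    if (cfg$l2 > 0 && endsWith(nm, "_W")) g <- g + cfg$l2 * net$params[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    net$params[[nm]] <- net$params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + 1e-8)
  }
  list(net = net, opt = opt)
}

#' Train a four-stream network
#'
#' Minibatch Adam with L2 regularization and per-epoch shuffling. When a
#' validation set is supplied, the parameters with the best validation
#' accuracy are kept (checkpoint selection); otherwise the final epoch's
#' parameters are returned.
#'
#' @param net A freshly initialized `fall4s_network`.
#' @param samples,labels Training samples (list) and factor labels.
#' @param val_samples,val_labels Optional validation set.
#' @param cfg A [train_config()].
#' @return List with `net` (trained network) and `history` (per-epoch data
#'   frame of loss and accuracies).
#' @export
train_network <- function(net, samples, labels, val_samples = NULL,
                          val_labels = NULL, cfg = train_config()) {
  stopifnot(inherits(net, "fall4s_network"),
            inherits(cfg, "fall4s_train_config"))
  n <- length(samples)
  nc <- net$config$fc_widths[length(net$config$fc_widths)]
  labels <- as.factor(labels)
  opt <- adam_init(net$params)
  best <- list(acc = -Inf, params = net$params, stats = net$stats)
  history <- vector("list", cfg$epochs)
  with_local_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0
      for (s0 in seq(1, n, by = cfg$minibatch)) {
        idx <- ord[s0:min(s0 + cfg$minibatch - 1, n)]
        xb <- samples_to_branches(samples[idx], net$config)
        Y <- label_onehot(labels[idx], nc)
        fwd <- net_forward(net, xb, training = TRUE)
        net$stats <- fwd$stats
        eps_p <- pmax(fwd$probs[cbind(seq_along(idx), as.integer(labels[idx]))],
                      1e-12)
        ep_loss <- ep_loss - sum(log(eps_p))
        ep_hits <- ep_hits +
          sum(max.col(fwd$probs) == as.integer(labels[idx]))
        grads <- net_backward(net, fwd, Y)
        upd <- adam_step(net, opt, grads, cfg)
        net <- upd$net; opt <- upd$opt
      }
      val_acc <- NA_real_
      if (!is.null(val_samples) && length(val_samples) > 0) {
        vp <- predict_network(net, val_samples)
        vi <- as.integer(factor(val_labels, levels = levels(labels)))
        val_acc <- mean(max.col(vp) == vi)
        if (val_acc >= best$acc) {
          best <- list(acc = val_acc, params = net$params, stats = net$stats)
        }
      }
      history[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n,
                                  train_acc = ep_hits / n, val_acc = val_acc)
      if (cfg$verbose)
        message(sprintf("epoch %3d  loss %.4f  train acc %.3f  val acc %s",
                        ep, ep_loss / n, ep_hits / n,
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
  })
  if (is.finite(best$acc)) {
    net$params <- best$params
    net$stats <- best$stats
  }
  list(net = net, history = do.call(rbind, history))
}
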