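# A 1-D convolutional network for 3-channel kinematic windows:
# [Conv-BN-ReLU, Conv-BN-ReLU, MaxPool, Conv-BN-ReLU, Conv-BN-ReLU,
#  MaxPool, Flatten, FC(1), sigmoid], trained with Adam on binary
# cross-entropy. Implemented directly on BLAS matrix operations
# (im2col convolutions); backpropagation is validated against
# finite-difference gradients in the test suite.

#' CNN hyperparameter configuration
#'
#' @param filters Four positive integers, filters per convolutional block.
#' @param kernels Four positive odd integers, kernel lengths.
#' @param pool_size Max-pool width/stride (pooling after blocks 2 and 4).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Seed controlling initialization and shuffling; training is
#'   deterministic given the seed.
#' @return A `cnn_config`.
#' @export
cnn_config <- function(filters = c(32L, 32L, 64L, 64L),
                       kernels = c(5L, 5L, 5L, 5L),
                       pool_size = 2L, learning_rate = 1e-3,
                       batch_size = 64L, epochs = 30L, seed = 1L) {
  if (length(filters) != 4 || any(filters < 1))
    stopf("filters must be 4 positive integers")
  if (length(kernels) != 4 || any(kernels %% 2 != 1) || any(kernels < 1))
    stopf("kernels must be 4 positive odd integers")
  if (pool_size < 1 || learning_rate <= 0 || batch_size < 1 || epochs < 1)
    stopf("invalid training hyperparameters")
  structure(list(filters = as.integer(filters), kernels = as.integer(kernels),
                 pool_size = as.integer(pool_size),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "cnn_config")
}

# ---- array plumbing --------------------------------------------------------
# im2col_cpp / col2im_cpp / col_scale_shift / bn_backward_cpp live in
# src/conv_ops.cpp; rows of the tap matrix are ordered with the batch
# index fastest, consistent with R's column-major array layout.

max_pool_forward <- function(X, p) {
  d <- dim(X); N <- d[1]; L <- d[2]; F <- d[3]
  Lp <- L %/% p
  idx1 <- seq(1L, by = p, length.out = Lp)
  vals <- X[, idx1, , drop = FALSE]
  arg <- array(1L, c(N, Lp, F))
  if (p > 1) for (j in 2:p) {
    cand <- X[, seq(j, by = p, length.out = Lp), , drop = FALSE]
    upd <- cand > vals
    vals[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(out = vals, arg = arg, in_len = L)
}

max_pool_backward <- function(dout, pool, p) {
  d <- dim(dout); N <- d[1]; Lp <- d[2]; F <- d[3]
  dX <- array(0, c(N, pool$in_len, F))
  for (j in seq_len(p)) {
    tmp <- array(0, c(N, Lp, F))
    mask <- pool$arg == j
    tmp[mask] <- dout[mask]
    dX[, seq(j, by = p, length.out = Lp), ] <- tmp
  }
  dX
}

# ---- model -----------------------------------------------------------------

#' Build an untrained CNN
#'
#' He-initialized weights, batch-norm scale 1 / shift 0. The
#' convolutions carry no bias term: batch normalization immediately
#' recentres each feature map, so the BN shift is the effective bias
#' (the standard Conv-BN parameterization). Initialization is
#' deterministic given `config$seed`.
#'
#' @param config A [cnn_config()].
#' @param input_len Window length in samples (300 for 3 s at 100 Hz).
#' @param in_channels Input channels (3).
#' @return A `cnn_model`; `n_params` holds the trainable parameter count.
#' @export
build_cnn <- function(config, input_len = 300L, in_channels = 3L) {
  stopifnot(inherits(config, "cnn_config"))
  lens <- integer(4)
  L <- as.integer(input_len)
  cin <- as.integer(in_channels)
  chans <- c(cin, config$filters)
  for (i in 1:4) {
    L <- L - config$kernels[i] + 1L
    if (L < 1) stopf("input of %d samples is shorter than the receptive field",
                     input_len)
    lens[i] <- L
    if (i %in% c(2L, 4L)) {
      L <- L %/% config$pool_size
      if (L < 1) stopf("input of %d samples is shorter than the receptive field",
                       input_len)
    }
  }
  flat <- L * config$filters[4]
  with_seed(config$seed, {
    conv <- lapply(1:4, function(i) {
      fan_in <- config$kernels[i] * chans[i]
      list(W = matrix(stats::rnorm(fan_in * chans[i + 1], 0, sqrt(2 / fan_in)),
                      fan_in, chans[i + 1]),
           gamma = rep(1, chans[i + 1]), beta = numeric(chans[i + 1]),
           run_mean = numeric(chans[i + 1]), run_var = rep(1, chans[i + 1]))
    })
    fc <- list(W = matrix(stats::rnorm(flat, 0, sqrt(1 / flat)), flat, 1),
               b = 0)
    n_par <- sum(vapply(1:4, function(i)
      length(conv[[i]]$W) + 2L * length(conv[[i]]$gamma), numeric(1))) +
      flat + 1
    structure(list(conv = conv, fc = fc, config = config,
                   input_len = as.integer(input_len), in_channels = cin,
                   flat_dim = as.integer(flat), n_params = n_par),
              class = "cnn_model")
  })
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

cnn_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- cfg$pool_size
  N <- dim(X)[1]
  cache <- if (training) list(blocks = vector("list", 4), pools = list()) else NULL
  A <- X
  for (i in 1:4) {
    ly <- model$conv[[i]]
    k <- cfg$kernels[i]
    L_in <- dim(A)[2]
    Xc <- im2col_cpp(A, k)
    Z <- Xc %*% ly$W
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(Z * Z) - mu^2
    } else {
      mu <- ly$run_mean
      v <- ly$run_var
    }
    istd <- 1 / sqrt(v + BN_EPS)
    scale <- ly$gamma * istd
    Znorm <- col_scale_shift(Z, scale, ly$beta - mu * scale)
    Act <- pmax(Znorm, 0)
    if (training)
      cache$blocks[[i]] <- list(Xc = Xc,
                                xhat = col_scale_shift(Z, istd, -mu * istd),
                                istd = istd, mask = Znorm > 0, L_in = L_in,
                                mu = mu, v = v)
    Lo <- L_in - k + 1L
    dim(Act) <- c(N, Lo, ncol(Z))
    if (i %in% c(2L, 4L)) {
      pool <- max_pool_forward(Act, p)
      if (training) cache$pools[[as.character(i)]] <- pool
      A <- pool$out
    } else A <- Act
  }
  dim(A) <- c(N, model$flat_dim)
  logits <- as.numeric(A %*% model$fc$W) + model$fc$b
  prob <- stats::plogis(logits)
  if (training) {
    cache$flat <- A
    list(prob = prob, cache = cache)
  } else prob
}

cnn_backward <- function(model, X, cache, dlogits) {
  cfg <- model$config
  p <- cfg$pool_size
  N <- dim(X)[1]
  grads <- list(conv = vector("list", 4), fc = NULL)
  dlog <- matrix(dlogits, N, 1)
  grads$fc <- list(W = crossprod(cache$flat, dlog), b = sum(dlog))
  dA <- dlog %*% t(model$fc$W)
  last_pool <- cache$pools[["4"]]
  dim(dA) <- dim(last_pool$out)
  dA <- max_pool_backward(dA, last_pool, p)
  for (i in 4:1) {
    bc <- cache$blocks[[i]]
    ly <- model$conv[[i]]
    k <- cfg$kernels[i]
    dAct <- dA
    dim(dAct) <- c(length(dAct) / ncol(bc$xhat), ncol(bc$xhat))
    dZn <- dAct * bc$mask
    bb <- bn_backward_cpp(dZn, bc$xhat, ly$gamma, bc$istd)
    grads$conv[[i]] <- list(W = crossprod(bc$Xc, bb$dZ),
                            gamma = bb$dgamma, beta = bb$dbeta)
    if (i > 1) {
      dXc <- bb$dZ %*% t(ly$W)
      dX <- col2im_cpp(dXc, N, bc$L_in, as.integer(nrow(ly$W) / k), k)
      if (i == 3L) {
        # block 3's conv input is pool 1's output: route through the pool
        dX <- max_pool_backward(dX, cache$pools[["2"]], p)
      }
      dA <- dX
    }
  }
  grads
}

# Running batch-norm statistics update (training mode)
cnn_update_running <- function(model, cache) {
  for (i in 1:4) {
    bc <- cache$blocks[[i]]
    ly <- model$conv[[i]]
    model$conv[[i]]$run_mean <- (1 - BN_MOMENTUM) * ly$run_mean + BN_MOMENTUM * bc$mu
    model$conv[[i]]$run_var <- (1 - BN_MOMENTUM) * ly$run_var + BN_MOMENTUM * bc$v
  }
  model
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else
    numeric(length(x))
  st <- list(t = 0L, m = list(), v = list())
  for (i in 1:4) for (nm in c("W", "gamma", "beta")) {
    key <- paste0("conv", i, "_", nm)
    st$m[[key]] <- zero_like(model$conv[[i]][[nm]])
    st$v[[key]] <- st$m[[key]]
  }
  st$m$fc_W <- zero_like(model$fc$W); st$v$fc_W <- st$m$fc_W
  st$m$fc_b <- 0; st$v$fc_b <- 0
  st
}

adam_step <- function(model, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  upd <- function(par, g, key) {
    st$m[[key]] <<- b1 * st$m[[key]] + (1 - b1) * g
    st$v[[key]] <<- b2 * st$v[[key]] + (1 - b2) * g * g
    par - lr * (st$m[[key]] / corr1) / (sqrt(st$v[[key]] / corr2) + eps)
  }
  for (i in 1:4) for (nm in c("W", "gamma", "beta"))
    model$conv[[i]][[nm]] <- upd(model$conv[[i]][[nm]],
                                 grads$conv[[i]][[nm]],
                                 paste0("conv", i, "_", nm))
  model$fc$W <- upd(model$fc$W, grads$fc$W, "fc_W")
  model$fc$b <- upd(model$fc$b, grads$fc$b, "fc_b")
  list(model = model, state = st)
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the CNN classifier
#'
#' Minimizes binary cross-entropy with Adam. Deterministic given
#' `config$seed` (initialization and shuffling both derive from it).
#'
#' @param x Array `N x L x 3` of training windows.
#' @param y 0/1 labels per window (1 = faller); both classes required.
#' @param config A [cnn_config()].
#' @param index Optional integer multiset of row indices defining the
#'   training stream (a row listed k times is trained on k times per
#'   epoch); defaults to each row once. Labels are taken per index.
#' @return A `cnn_fit` with the trained model, per-epoch `loss_curve`,
#'   and a training `manifest`.
#' @export
train_classifier <- function(x, y, config = cnn_config(), index = NULL) {
  if (is.null(index)) index <- seq_len(dim(x)[1])
  if (length(unique(y[index])) < 2) stopf("training set contains a single class")
  with_seed(config$seed, {
    # build_cnn seeds itself from config$seed and restores the stream, so
    # the shuffling RNG below stays on this with_seed stream
    model <- build_cnn(config, dim(x)[2], dim(x)[3])
    st <- adam_init(model)
    n <- length(index)
    bs <- min(config$batch_size, n)
    loss_curve <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(index)
      batch_losses <- numeric(0)
      at <- 1L
      while (at <= n) {
        rows <- ord[at:min(at + bs - 1L, n)]
        at <- at + bs
        Xb <- x[rows, , , drop = FALSE]
        yb <- y[rows]
        fw <- cnn_forward(model, Xb, training = TRUE)
        model <- cnn_update_running(model, fw$cache)
        batch_losses <- c(batch_losses, bce_loss(fw$prob, yb))
        dlogits <- (fw$prob - yb) / length(yb)
        grads <- cnn_backward(model, Xb, fw$cache, dlogits)
        stepped <- adam_step(model, grads, st, config$learning_rate)
        model <- stepped$model
        st <- stepped$state
      }
      loss_curve[epoch] <- mean(batch_losses)
    }
    structure(list(model = model, config = config, loss_curve = loss_curve,
                   manifest = list(n_windows = n,
                                   class_balance = mean(y[index]),
                                   seed = config$seed)),
              class = "cnn_fit")
  })
}

#' Predict fall probability
#'
#' @param fit A fitted classifier (`cnn_fit` or `svm_fit`).
#' @param newdata For a CNN: array `N x L x 3` or a `segment_set`; for an
#'   SVM: matrix/data.frame of the 9 summary features.
#' @param batch_size Prediction batch size (CNN).
#' @return Numeric vector of P(faller) in `[0, 1]`.
#' @export
predict_fall_probability <- function(fit, newdata, batch_size = 512L) {
  UseMethod("predict_fall_probability")
}

#' @export
predict_fall_probability.cnn_fit <- function(fit, newdata, batch_size = 512L) {
  x <- if (inherits(newdata, "segment_set")) newdata$x else newdata
  if (length(dim(x)) != 3 || dim(x)[2] != fit$model$input_len ||
      dim(x)[3] != fit$model$in_channels)
    stopf("segment shape mismatch: expected N x %d x %d",
          fit$model$input_len, fit$model$in_channels)
  n <- dim(x)[1]
  out <- numeric(n)
  at <- 1L
  while (at <= n) {
    rows <- at:min(at + batch_size - 1L, n)
    out[rows] <- cnn_forward(fit$model, x[rows, , , drop = FALSE],
                             training = FALSE)
    at <- at + batch_size
  }
  out
}

#' Threshold fall probabilities into classes
#'
#' Predicts faller iff `p_fall >= threshold`; the boundary (tie) is
#' assigned to the faller class, favouring sensitivity in screening.
#'
#' @param p_fall Probabilities in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 labels.
#' @export
classify <- function(p_fall, threshold = 0.5) {
  if (any(p_fall < 0 | p_fall > 1)) stopf("probabilities must lie in [0, 1]")
  as.integer(p_fall >= threshold)
}
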