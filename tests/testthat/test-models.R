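test_that("backpropagation matches finite-difference gradients", {
  set.seed(77)
  cfg <- cnn_config(filters = c(3, 3, 4, 4), kernels = c(3, 3, 3, 3),
                    epochs = 1, batch_size = 4, seed = 9)
  L <- 24
  model <- build_cnn(cfg, input_len = L, in_channels = 2)
  X <- array(rnorm(5 * L * 2), c(5, L, 2))
  y <- c(1, 0, 1, 0, 1)
  fw <- tugfall:::cnn_forward(model, X, training = TRUE)
  gr <- tugfall:::cnn_backward(model, X, fw$cache,
                               (fw$prob - y) / length(y))
  num_grad <- function(set, get, i) {
    h <- 1e-5
    v <- get(); v0 <- v[i]
    v[i] <- v0 + h
    lp <- tugfall:::bce_loss(tugfall:::cnn_forward(set(v), X, TRUE)$prob, y)
    v[i] <- v0 - h
    lm <- tugfall:::bce_loss(tugfall:::cnn_forward(set(v), X, TRUE)$prob, y)
    (lp - lm) / (2 * h)
  }
  for (blk in 1:4) for (nm in c("W", "gamma", "beta")) {
    par <- model$conv[[blk]][[nm]]
    for (i in sample(length(par), min(3, length(par)))) {
      ng <- num_grad(function(v) { m <- model; m$conv[[blk]][[nm]] <- v; m },
                     function() model$conv[[blk]][[nm]], i)
      expect_equal(gr$conv[[blk]][[nm]][i], ng, tolerance = 1e-4)
    }
  }
  for (i in sample(length(model$fc$W), 4)) {
    ng <- num_grad(function(v) { m <- model; m$fc$W <- v; m },
                   function() model$fc$W, i)
    expect_equal(gr$fc$W[i], ng, tolerance = 1e-4)
  }
})

test_that("architecture shape, output range and parameter count are as designed", {
  cfg <- cnn_config(filters = c(4, 4, 8, 8), kernels = c(5, 5, 5, 5))
  model <- build_cnn(cfg, 300, 3)
  # valid convolutions and two pools: 300->296->292->146->142->138->69
  expect_equal(model$flat_dim, 69 * 8)
  # conv weights k*Cin*F per block, BN gamma+beta per filter, FC + bias
  chans <- c(3, cfg$filters)
  expected <- sum(cfg$kernels * chans[1:4] * chans[2:5]) +
    2 * sum(cfg$filters) + model$flat_dim + 1
  expect_equal(model$n_params, expected)
  # doubling the last block's filters doubles its conv weight count
  cfg2 <- cnn_config(filters = c(4, 4, 8, 16), kernels = c(5, 5, 5, 5))
  m2 <- build_cnn(cfg2, 300, 3)
  expect_equal(length(m2$conv[[4]]$W), 2 * length(model$conv[[4]]$W))
  # sigmoid head: probabilities strictly inside (0, 1)
  set.seed(2)
  p <- tugfall:::cnn_forward(model, array(rnorm(6 * 300 * 3), c(6, 300, 3)))
  expect_true(all(p > 0 & p < 1))
  # same seed -> identical initial parameters
  expect_identical(build_cnn(cfg, 300, 3)$conv[[1]]$W, model$conv[[1]]$W)
  # input shorter than the receptive field is rejected
  expect_error(build_cnn(cfg, 10, 3), "receptive field")
})

test_that("training separates constant-level classes and is reproducible", {
  set.seed(8)
  n <- 32; L <- 300
  x <- array(0, c(n, L, 3))
  y <- rep(c(0, 1), each = n / 2)
  x[y == 0, , ] <- 0.2
  x[y == 1, , ] <- 0.8
  x <- x + array(rnorm(n * L * 3, 0, 0.02), c(n, L, 3))
  cfg <- cnn_config(filters = c(4, 4, 8, 8), epochs = 12, batch_size = 16,
                    seed = 3)
  fit <- train_classifier(x, y, cfg)
  p <- predict_fall_probability(fit, x)
  expect_equal(mean(classify(p) == y), 1.0)
  expect_gt(mean(p[y == 1]), mean(p[y == 0]))
  # deterministic retrain
  fit2 <- train_classifier(x, y, cfg)
  expect_identical(fit$model$fc$W, fit2$model$fc$W)
  expect_identical(fit$loss_curve, fit2$loss_curve)
  # single-class training set is rejected
  expect_error(train_classifier(x, rep(1, n), cfg), "single class")
  # shape mismatch at prediction
  expect_error(predict_fall_probability(fit, array(0, c(2, 100, 3))),
               "shape mismatch")
})

test_that("classification thresholds probabilities with ties to faller", {
  expect_equal(classify(c(0, 1, 0.5, 0.49)), c(0L, 1L, 1L, 0L))
  expect_equal(classify(c(0.3, 0.6), threshold = 0.3), c(1L, 1L))
  expect_error(classify(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("SVM separates well-spaced Gaussian classes and is deterministic", {
  set.seed(19)
  n <- 200
  mu <- rep(0, 9)
  x0 <- matrix(rnorm(n / 2 * 9), n / 2, 9)
  x1 <- matrix(rnorm(n / 2 * 9, mean = 3), n / 2, 9)
  x <- rbind(x0, x1)
  colnames(x) <- paste0("f", 1:9)
  y <- rep(c(0, 1), each = n / 2)
  tr <- sample(n, n / 2)
  fit <- fit_svm(x[tr, ], y[tr])
  p <- predict_fall_probability(fit, x[-tr, ])
  expect_gt(mean(classify(p) == y[-tr]), 0.95)
  expect_gt(roc_auc(p, y[-tr]), 0.99)
  # identical inputs -> identical fit (no RNG in the solver path)
  fit2 <- fit_svm(x[tr, ], y[tr])
  p2 <- predict_fall_probability(fit2, x[-tr, ])
  expect_identical(p, p2)
  expect_error(fit_svm(x, rep(1, n)), "single class")
})

test_that("SVM score orientation makes larger mean faller probability", {
  set.seed(23)
  # identical class distributions: held-out AUC near 0.5
  x <- matrix(rnorm(400 * 9), 400, 9)
  y <- rep(c(0, 1), 200)
  fit <- fit_svm(x[1:200, ], y[1:200])
  p_new <- predict_fall_probability(fit, x[201:400, ])
  expect_lt(abs(roc_auc(p_new, y[201:400]) - 0.5), 0.15)
})
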