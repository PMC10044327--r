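test_that("all-zero parameters give the closed-form cell step", {
  p <- init_lstm_params(d = 2, H = 3, seed = 1)
  p$Wx[] <- 0; p$Wh[] <- 0; p$b[] <- 0
  st <- lstm_cell_forward(c(1.7, -0.3), list(h = rep(0, 3), c = rep(0, 3)), p)
  expect_equal(st$f, rep(0.5, 3))
  expect_equal(st$c, rep(0.25, 3))
  expect_equal(st$h, rep(0.5 * tanh(0.25), 3), tolerance = 1e-12)
})

test_that("a saturated forget gate with a closed input gate retains the cell state", {
  p <- init_lstm_params(d = 1, H = 2, seed = 2)
  p$Wx[] <- 0; p$Wh[] <- 0
  p$b[1:2] <- 50      # f -> 1
  p$b[5:6] <- -50     # i -> 0
  st <- list(h = c(0.1, -0.2), c = c(0.7, -1.3))
  for (t in 1:5) {
    st_new <- lstm_cell_forward(0.3, st, p)
    st <- list(h = st_new$h, c = st_new$c)
  }
  expect_equal(st$c, c(0.7, -1.3), tolerance = 1e-12)
})

test_that("forward pass matches the per-equation oracle on random instances", {
  withr::with_seed(42, specs <- data.frame(
    H = sample(2:8, 100, replace = TRUE),
    d = sample(1:4, 100, replace = TRUE),
    Tn = sample(2:10, 100, replace = TRUE),
    g = sample(c("sigmoid", "tanh"), 100, replace = TRUE)
  ))
  worst <- 0
  for (k in seq_len(100)) {
    p <- rand_params(specs$d[k], specs$H[k], specs$g[k], seed = k)
    withr::with_seed(k, X <- matrix(rnorm(specs$Tn[k] * specs$d[k]),
                                    specs$Tn[k], specs$d[k]))
    worst <- max(worst, max(abs(forward_sequence(X, p) - oracle_lstm(X, p)$Y)))
  }
  expect_lt(worst, 1e-10)
})

test_that("gate activations stay in (0,1) and the hidden state is bounded by 1", {
  p <- rand_params(3, 6, "sigmoid", seed = 7)
  st <- list(h = rep(0, 6), c = rep(0, 6))
  withr::with_seed(7, X <- matrix(3 * rnorm(60), 20, 3))
  for (t in 1:20) {
    st_new <- lstm_cell_forward(X[t, ], st, p)
    for (gate in c("f", "g", "i", "o")) {
      expect_true(all(st_new[[gate]] > 0 & st_new[[gate]] < 1))
    }
    expect_true(all(abs(st_new$h) <= 1))
    st <- list(h = st_new$h, c = st_new$c)
  }
})

test_that("analytic gradients match finite differences on a tiny instance", {
  for (gg in c("sigmoid", "tanh")) {
    p <- rand_params(2, 3, gg, seed = 11)
    withr::with_seed(12, {
      X <- lapply(1:4, function(t) matrix(rnorm(4), 2, 2))
      Yt <- lapply(1:4, function(t) matrix(rnorm(12), 2, 6))
    })
    lg <- grfest:::lstm_loss_grad(X, Yt, p)
    eps <- 1e-6
    withr::with_seed(13, {
      for (k in c("Wx", "Wh", "b", "Wout", "bout")) {
        for (ii in sample(length(p[[k]]), min(6, length(p[[k]])))) {
          pp <- p; pp[[k]][ii] <- pp[[k]][ii] + eps
          pm <- p; pm[[k]][ii] <- pm[[k]][ii] - eps
          num <- (grfest:::lstm_loss_grad(X, Yt, pp)$loss -
                    grfest:::lstm_loss_grad(X, Yt, pm)$loss) / (2 * eps)
          ana <- lg$grads[[k]][ii]
          expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-4)
        }
      }
    })
  }
})

test_that("evaluation-mode forward is deterministic; zero dropout matches training mode", {
  p <- rand_params(2, 4, "sigmoid", seed = 21)
  withr::with_seed(22, X <- matrix(rnorm(40), 20, 2))
  expect_identical(forward_sequence(X, p), forward_sequence(X, p))
  expect_equal(forward_sequence(X, p, dropout_p = 0, training = TRUE),
               forward_sequence(X, p), tolerance = 1e-12)
  # one-frame window equals the head applied to the single-step state
  st <- lstm_cell_forward(X[1, ], list(h = rep(0, 4), c = rep(0, 4)), p)
  expect_equal(as.numeric(forward_sequence(X[1, , drop = FALSE], p)),
               as.numeric(st$h %*% p$Wout) + p$bout, tolerance = 1e-12)
})

test_that("training learns a constructed identifiable problem and is reproducible", {
  # wrench = fixed linear map of the inputs, no noise
  withr::with_seed(31, {
    n <- 1200
    X <- matrix(rnorm(n * 3), n, 3)
    for (j in 1:3) X[, j] <- as.numeric(stats::filter(X[, j], rep(1 / 8, 8),
                                                      sides = 1))
    X[is.na(X)] <- 0
    A <- matrix(rnorm(18), 3, 6)
  })
  Y <- X %*% A
  feat <- tibble::as_tibble(as.data.frame(X))
  names(feat) <- c("f1", "f2", "f3")
  feat$time <- seq_len(n) / 74.074
  Y <- as.data.frame(Y)
  names(Y) <- wrench_channels()
  feat <- dplyr::bind_cols(feat, Y)

  halves <- split_half(feat)
  std <- standardize(halves$train, halves$test, cols = c("f1", "f2", "f3"))
  ds <- structure(list(
    train = std$train, test = std$test, stats = std$stats,
    input_cols = c("f1", "f2", "f3"), target_cols = wrench_channels(),
    pattern_id = 0L, window_length = 16
  ), class = "grf_dataset")

  cfg <- train_config(hidden_size = 8, dropout_p = 0, learning_rate = 0.02,
                      max_epochs = 50, patience = 50, seed = 5)
  m <- fit_grf_lstm(ds, cfg)
  est <- predict(m, ds$test, standardized = TRUE)
  rmse <- vapply(wrench_channels(), function(ch) {
    percent_rmse(est[[ch]], ds$test[[ch]])
  }, numeric(1))
  expect_true(all(rmse < 5))

  # identical seed -> identical trajectory
  m2 <- fit_grf_lstm(ds, cfg)
  expect_identical(m$log$train_loss, m2$log$train_loss)
  expect_identical(m$params$Wx, m2$params$Wx)

  # training loss trends downward (allow 5% wiggle)
  tl <- m$log$train_loss
  expect_true(all(diff(tl) < 0.05 * tl[-length(tl)]))
  expect_lt(tl[length(tl)], tl[1])
})

test_that("prediction is deterministic and dimension mismatches are caught", {
  p <- rand_params(2, 3, "sigmoid", seed = 51)
  expect_error(
    lstm_cell_forward(c(1, 2, 3), list(h = rep(0, 3), c = rep(0, 3)), p),
    "expects d = 2"
  )
})
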