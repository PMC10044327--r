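# Independent per-equation LSTM oracle: explicit per-gate weight slices
# and plain loops over units and time, written separately from the
# packed-matrix implementation it checks.
oracle_lstm <- function(X, p) {
  H <- p$H
  sig <- function(x) 1 / (1 + exp(-x))
  Wxf <- p$Wx[, 1:H, drop = FALSE]
  Wxg <- p$Wx[, H + 1:H, drop = FALSE]
  Wxi <- p$Wx[, 2 * H + 1:H, drop = FALSE]
  Wxo <- p$Wx[, 3 * H + 1:H, drop = FALSE]
  Whf <- p$Wh[, 1:H, drop = FALSE]
  Whg <- p$Wh[, H + 1:H, drop = FALSE]
  Whi <- p$Wh[, 2 * H + 1:H, drop = FALSE]
  Who <- p$Wh[, 3 * H + 1:H, drop = FALSE]
  bf <- p$b[1:H]; bg <- p$b[H + 1:H]
  bi <- p$b[2 * H + 1:H]; bo <- p$b[3 * H + 1:H]
  h <- rep(0, H); cc <- rep(0, H)
  Y <- matrix(NA_real_, nrow(X), p$n_out)
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    f <- sig(as.numeric(x %*% Wxf) + as.numeric(h %*% Whf) + bf)
    zg <- as.numeric(x %*% Wxg) + as.numeric(h %*% Whg) + bg
    g <- if (p$g_gate == "tanh") tanh(zg) else sig(zg)
    i <- sig(as.numeric(x %*% Wxi) + as.numeric(h %*% Whi) + bi)
    o <- sig(as.numeric(x %*% Wxo) + as.numeric(h %*% Who) + bo)
    cc <- f * cc + g * i
    h <- o * tanh(cc)
    Y[t, ] <- as.numeric(h %*% p$Wout) + p$bout
  }
  list(h = h, c = cc, Y = Y)
}

rand_params <- function(d, H, g_gate, seed) {
  p <- init_lstm_params(d, H, g_gate = g_gate, seed = seed)
  withr::with_seed(seed + 1000L, {
    p$Wx[] <- rnorm(length(p$Wx))
    p$Wh[] <- 0.5 * rnorm(length(p$Wh))
    p$b[] <- 0.3 * rnorm(length(p$b))
    p$Wout[] <- rnorm(length(p$Wout))
    p$bout[] <- rnorm(length(p$bout))
  })
  p
}
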