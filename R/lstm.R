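# LSTM regressor written from its gate equations.
#
# Gate order in the packed weight matrices is (f, g, i, o):
#   f_t = sigma(x_t Wxf + h_{t-1} Whf + bf)      forget gate
#   g_t = phi  (x_t Wxg + h_{t-1} Whg + bg)      generation gate
#   i_t = sigma(x_t Wxi + h_{t-1} Whi + bi)      input gate
#   o_t = sigma(x_t Wxo + h_{t-1} Who + bo)      output gate
#   c_t = f_t * c_{t-1} + g_t * i_t
#   h_t = o_t * tanh(c_t)
# phi is the generation-gate nonlinearity: the sigmoid by default (the
# form the equations are printed with), with a conventional tanh variant
# available (`g_gate = "tanh"`). A per-frame affine head maps h_t to the
# six wrench channels.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize LSTM parameters
#'
#' Weights drawn uniformly in +/- 1/sqrt(H), seeded; the forget-gate bias
#' starts at +1 to ease learning of long memory.
#'
#' @param d Input dimensionality.
#' @param H Hidden size (default 64).
#' @param n_out Output channels (default 6, the wrench).
#' @param g_gate Generation-gate nonlinearity: `"sigmoid"` (as the
#'   equations are printed) or `"tanh"` (the conventional form).
#' @param seed Integer seed.
#' @return An `lstm_params` list: `Wx` (d x 4H), `Wh` (H x 4H), `b` (4H),
#'   `Wout` (H x n_out), `bout` (n_out), plus dimensions and `g_gate`.
#' @export
init_lstm_params <- function(d, H = 64, n_out = 6,
                             g_gate = c("sigmoid", "tanh"), seed = 1L) {
  g_gate <- match.arg(g_gate)
  withr::with_seed(as.integer(seed), {
    r <- 1 / sqrt(H)
    p <- list(
      Wx = matrix(runif(d * 4 * H, -r, r), d, 4 * H),
      Wh = matrix(runif(H * 4 * H, -r, r), H, 4 * H),
      b = rep(0, 4 * H),
      Wout = matrix(runif(H * n_out, -r, r), H, n_out),
      bout = rep(0, n_out)
    )
    p$b[seq_len(H)] <- 1  # forget-gate bias
    p$d <- d; p$H <- H; p$n_out <- n_out; p$g_gate <- g_gate
    class(p) <- "lstm_params"
    p
  })
}

g_nonlin <- function(z, g_gate) if (g_gate == "tanh") tanh(z) else sigmoid(z)

#' One LSTM cell step
#'
#' Computes the four gates, the new cell state and the new hidden state
#' for a single time step. `x` may be a length-`d` vector or a `B x d`
#' matrix (a batch).
#'
#' @param x Input vector (length d) or matrix (B x d).
#' @param state List with `h` and `c` (vectors of length H, or `B x H`
#'   matrices); use zeros to start a sequence.
#' @param params An `lstm_params`.
#' @return List with `h`, `c` and the gate activations `f`, `g`, `i`, `o`.
#' @examples
#' p <- init_lstm_params(d = 2, H = 3, seed = 1)
#' st <- lstm_cell_forward(c(0.5, -1), list(h = rep(0, 3), c = rep(0, 3)), p)
#' @export
lstm_cell_forward <- function(x, state, params) {
  H <- params$H
  vec_in <- is.null(dim(x))
  if (vec_in) {
    x <- matrix(x, nrow = 1)
    state <- list(h = matrix(state$h, nrow = 1),
                  c = matrix(state$c, nrow = 1))
  }
  if (ncol(x) != params$d) {
    abort(sprintf("Input has %d columns but the model expects d = %d.",
                  ncol(x), params$d))
  }
  z <- x %*% params$Wx + state$h %*% params$Wh +
    matrix(params$b, nrow(x), 4 * H, byrow = TRUE)
  f <- sigmoid(z[, seq_len(H), drop = FALSE])
  g <- g_nonlin(z[, H + seq_len(H), drop = FALSE], params$g_gate)
  i <- sigmoid(z[, 2 * H + seq_len(H), drop = FALSE])
  o <- sigmoid(z[, 3 * H + seq_len(H), drop = FALSE])
  c_new <- f * state$c + g * i
  h_new <- o * tanh(c_new)
  out <- list(h = h_new, c = c_new, f = f, g = g, i = i, o = o)
  if (vec_in) out <- lapply(out, function(m) m[1, ])
  out
}

# Batched forward over a window. X is a list over time of B x d matrices.
# Returns outputs and (optionally) the caches needed for backprop.
lstm_forward_pass <- function(X, params, dropout_p = 0, training = FALSE,
                              keep_cache = FALSE, init_state = NULL) {
  H <- params$H
  Tn <- length(X)
  B <- nrow(X[[1]])
  h <- if (is.null(init_state)) matrix(0, B, H) else init_state$h
  cc <- if (is.null(init_state)) matrix(0, B, H) else init_state$c
  Y <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  use_dropout <- training && dropout_p > 0
  for (t in seq_len(Tn)) {
    st <- lstm_cell_forward(X[[t]], list(h = h, c = cc), params)
    h_out <- st$h
    mask <- NULL
    if (use_dropout) {
      mask <- matrix(runif(B * H) >= dropout_p, B, H) / (1 - dropout_p)
      h_out <- st$h * mask
    }
    Y[[t]] <- h_out %*% params$Wout +
      matrix(params$bout, B, params$n_out, byrow = TRUE)
    if (keep_cache) {
      cache[[t]] <- list(x = X[[t]], h_prev = h, c_prev = cc,
                         f = st$f, g = st$g, i = st$i, o = st$o,
                         c = st$c, h = st$h, tanh_c = tanh(st$c),
                         mask = mask)
    }
    h <- st$h
    cc <- st$c
  }
  list(Y = Y, cache = cache, state = list(h = h, c = cc))
}

#' Forward pass over a window of frames
#'
#' Applies the LSTM cell stepwise from a zero state and the affine output
#' head per frame. In training mode, inverted dropout is applied to the
#' hidden state before the head; evaluation mode is deterministic.
#'
#' @param window Numeric matrix, frames x d.
#' @param params An `lstm_params`.
#' @param dropout_p Dropout probability on the hidden state (training
#'   mode only).
#' @param training Logical; enables dropout.
#' @return Numeric matrix, frames x 6, the per-frame wrench output.
#' @export
forward_sequence <- function(window, params, dropout_p = 0,
                             training = FALSE) {
  window <- as.matrix(window)
  X <- lapply(seq_len(nrow(window)), function(t) window[t, , drop = FALSE])
  out <- lstm_forward_pass(X, params, dropout_p = dropout_p,
                           training = training)
  do.call(rbind, out$Y)
}

# MSE loss and analytic gradients via backpropagation through time for
# one batch of windows. X, targets: lists over time of B x d / B x 6
# matrices. Returns loss (mean over frames, batch and channels) and
# gradients with the same shapes as the parameters.
lstm_loss_grad <- function(X, targets, params, dropout_p = 0,
                           training = FALSE) {
  H <- params$H
  Tn <- length(X)
  B <- nrow(X[[1]])
  fw <- lstm_forward_pass(X, params, dropout_p = dropout_p,
                          training = training, keep_cache = TRUE)
  denom <- Tn * B * params$n_out
  loss <- 0
  grads <- list(
    Wx = matrix(0, params$d, 4 * H), Wh = matrix(0, H, 4 * H),
    b = rep(0, 4 * H), Wout = matrix(0, H, params$n_out),
    bout = rep(0, params$n_out)
  )
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  gi <- seq_len(H)
  for (t in Tn:1) {
    ca <- fw$cache[[t]]
    err <- fw$Y[[t]] - targets[[t]]
    loss <- loss + sum(err^2)
    dY <- 2 * err / denom
    h_for_head <- if (is.null(ca$mask)) ca$h else ca$h * ca$mask
    grads$Wout <- grads$Wout + crossprod(h_for_head, dY)
    grads$bout <- grads$bout + colSums(dY)
    dh <- dY %*% t(params$Wout)
    if (!is.null(ca$mask)) dh <- dh * ca$mask
    dh <- dh + dh_next
    do_ <- dh * ca$tanh_c
    dc <- dh * ca$o * (1 - ca$tanh_c^2) + dc_next
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    di <- dc * ca$g
    dZ <- matrix(0, B, 4 * H)
    dZ[, gi] <- df * ca$f * (1 - ca$f)
    dZ[, H + gi] <- if (params$g_gate == "tanh") dg * (1 - ca$g^2) else dg * ca$g * (1 - ca$g)
    dZ[, 2 * H + gi] <- di * ca$i * (1 - ca$i)
    dZ[, 3 * H + gi] <- do_ * ca$o * (1 - ca$o)
    grads$Wx <- grads$Wx + crossprod(ca$x, dZ)
    grads$Wh <- grads$Wh + crossprod(ca$h_prev, dZ)
    grads$b <- grads$b + colSums(dZ)
    dh_next <- dZ %*% t(params$Wh)
    dc_next <- dc * ca$f
  }
  list(loss = loss / denom, grads = grads)
}

adam_init <- function(params) {
  keys <- c("Wx", "Wh", "b", "Wout", "bout")
  list(
    m = lapply(params[keys], function(p) p * 0),
    v = lapply(params[keys], function(p) p * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(grads)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration for the LSTM regressor
#'
#' Defaults follow the study configuration: a single LSTM layer with 64
#' hidden units, 50% dropout, batch size 64, learning rate 0.001, Adam.
#' The epoch budget and early-stopping patience are the package's own
#' choices (the number of epochs is not part of the study configuration).
#'
#' @param hidden_size Hidden units H (default 64).
#' @param batch_size Windows per gradient step (default 64).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param dropout_p Dropout probability on the hidden state (default 0.5,
#'   training mode only).
#' @param max_epochs Epoch cap (default 400).
#' @param patience Early-stopping patience, in epochs without validation
#'   improvement (default 25).
#' @param val_fraction Tail fraction of the training half held out for
#'   early stopping (default 0.2).
#' @param g_gate Generation-gate nonlinearity, `"sigmoid"` or `"tanh"`.
#' @param seed Seed for initialization, batch order and dropout.
#' @return A `grf_train_config` list.
#' @export
train_config <- function(hidden_size = 64, batch_size = 64,
                         learning_rate = 0.001, dropout_p = 0.5,
                         max_epochs = 400, patience = 25,
                         val_fraction = 0.2,
                         g_gate = c("sigmoid", "tanh"), seed = 1L) {
  g_gate <- match.arg(g_gate)
  if (learning_rate <= 0) abort("learning_rate must be positive.")
  if (dropout_p < 0 || dropout_p >= 1) abort("dropout_p must be in [0, 1).")
  structure(
    list(hidden_size = hidden_size, batch_size = batch_size,
         learning_rate = learning_rate, dropout_p = dropout_p,
         max_epochs = max_epochs, patience = patience,
         val_fraction = val_fraction, g_gate = g_gate,
         seed = as.integer(seed)),
    class = "grf_train_config"
  )
}

# Stack a set of equal-length windows into a list over time of B x k
# matrices.
stack_windows <- function(mat, windows) {
  Tn <- length(windows[[1]])
  lapply(seq_len(Tn), function(t) {
    idx <- vapply(windows, function(w) w[t], integer(1))
    mat[idx, , drop = FALSE]
  })
}

#' Fit the LSTM wrench regressor
#'
#' Trains on the dataset's training half with truncated backpropagation
#' through non-overlapping windows, minimizing the mean squared error over
#' all six wrench channels with Adam. Targets are z-scored internally with
#' training-half statistics (each channel weighted equally in the loss)
#' and predictions are returned in physical units. The last
#' `val_fraction` of the training half is held out for early stopping;
#' the parameters with the best validation loss are kept. A fixed seed
#' gives a reproducible trajectory.
#'
#' @param dataset A `grf_dataset` from [build_dataset()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses every 25 epochs.
#' @return A `grf_lstm` model: best parameters, scalers, the training log
#'   and configuration.
#' @export
fit_grf_lstm <- function(dataset, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "grf_dataset"),
            inherits(config, "grf_train_config"))
  Xmat <- as.matrix(dataset$train[, dataset$input_cols, drop = FALSE])
  Ymat <- as.matrix(dataset$train[, dataset$target_cols, drop = FALSE])
  t_mean <- colMeans(Ymat)
  t_sd <- apply(Ymat, 2, sd)
  t_sd[t_sd == 0] <- 1
  Ystd <- sweep(sweep(Ymat, 2, t_mean), 2, t_sd, "/")

  n <- nrow(Xmat)
  n_core <- max(floor(n * (1 - config$val_fraction)), dataset$window_length)
  n_core <- min(n_core, n)
  core_windows <- make_windows(n_core, dataset$window_length)
  val_idx <- if (n_core < n) (n_core + 1):n else integer(0)

  params <- init_lstm_params(
    d = ncol(Xmat), H = config$hidden_size, n_out = ncol(Ymat),
    g_gate = config$g_gate, seed = config$seed
  )
  opt <- adam_init(params)

  # group equal-length windows into batches; a trailing partial window
  # forms its own batch
  lens <- vapply(core_windows, length, integer(1))
  full <- core_windows[lens == dataset$window_length]
  partial <- core_windows[lens != dataset$window_length]
  batches <- list()
  if (length(full) > 0) {
    cut_id <- ceiling(seq_along(full) / config$batch_size)
    batches <- split(full, cut_id)
  }
  for (p in partial) batches[[length(batches) + 1]] <- list(p)

  val_X <- if (length(val_idx) > 0) {
    lapply(val_idx, function(ii) Xmat[ii, , drop = FALSE])
  } else NULL
  val_Y <- if (length(val_idx) > 0) Ystd[val_idx, , drop = FALSE] else NULL

  log <- list()
  best_val <- Inf
  best_params <- params
  stale <- 0
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      order_ <- sample.int(length(batches))
      ep_loss <- 0
      ep_frames <- 0
      for (bi in order_) {
        wins <- batches[[bi]]
        Xb <- stack_windows(Xmat, wins)
        Yb <- stack_windows(Ystd, wins)
        lg <- lstm_loss_grad(Xb, Yb, params,
                             dropout_p = config$dropout_p, training = TRUE)
        if (!is.finite(lg$loss)) {
          abort(sprintf("Training diverged (non-finite loss) at epoch %d.",
                        epoch))
        }
        st <- adam_step(params, lg$grads, opt, config$learning_rate)
        params <- st$params
        opt <- st$state
        nf <- length(Xb) * nrow(Xb[[1]])
        ep_loss <- ep_loss + lg$loss * nf
        ep_frames <- ep_frames + nf
      }
      train_loss <- ep_loss / ep_frames
      val_loss <- NA_real_
      if (!is.null(val_X)) {
        pred <- lstm_forward_pass(val_X, params)$Y
        val_loss <- mean((do.call(rbind, pred) - val_Y)^2)
        if (val_loss < best_val - 1e-10) {
          best_val <- val_loss
          best_params <- params
          stale <- 0
        } else {
          stale <- stale + 1
        }
      } else {
        best_params <- params
      }
      log[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                        val_loss = val_loss)
      if (verbose && epoch %% 25 == 0) {
        message(sprintf("epoch %4d  train %.5f  val %.5f", epoch,
                        train_loss, val_loss))
      }
      if (!is.null(val_X) && stale >= config$patience) break
    }
  })

  structure(
    list(
      params = best_params,
      feature_stats = dataset$stats,
      target_mean = t_mean, target_sd = t_sd,
      input_cols = dataset$input_cols, target_cols = dataset$target_cols,
      pattern_id = dataset$pattern_id, config = config,
      log = tibble::as_tibble(do.call(rbind, log))
    ),
    class = "grf_lstm"
  )
}

#' @export
print.grf_lstm <- function(x, ...) {
  cat(sprintf(
    "<grf_lstm> pattern %s: d = %d -> H = %d -> %d channels; %d epochs (best val %.4g)\n",
    x$pattern_id, x$params$d, x$params$H, x$params$n_out, nrow(x$log),
    suppressWarnings(min(x$log$val_loss, na.rm = TRUE))
  ))
  invisible(x)
}

#' Predict the wrench from features
#'
#' Runs the fitted model over a feature frame in a single continuous
#' evaluation-mode pass (deterministic) and returns the six wrench
#' channels in physical units on the 74.074 Hz timebase.
#'
#' @param object A `grf_lstm`.
#' @param features Feature tibble containing the model's input columns.
#'   With `standardized = FALSE` (default) raw features are z-scored with
#'   the stored training statistics first; pass `TRUE` for frames already
#'   standardized (e.g. the `test` half of the training `grf_dataset`).
#' @param standardized Whether `features` are already standardized.
#' @param ... Unused.
#' @return Tibble: `time` (when present in `features`) plus `Fx` .. `Mz`.
#' @export
predict.grf_lstm <- function(object, features, standardized = FALSE, ...) {
  missing <- setdiff(object$input_cols, names(features))
  if (length(missing) > 0) {
    abort(sprintf(
      "Features lack column(s) %s required by the trained pattern %s.",
      paste(missing, collapse = ", "), object$pattern_id
    ))
  }
  Xmat <- as.matrix(features[, object$input_cols, drop = FALSE])
  if (!standardized) {
    st <- object$feature_stats
    Xmat <- sweep(sweep(Xmat, 2, st$mean[match(object$input_cols, st$column)]),
                  2, st$sd[match(object$input_cols, st$column)], "/")
  }
  X <- lapply(seq_len(nrow(Xmat)), function(t) Xmat[t, , drop = FALSE])
  Yst <- do.call(rbind, lstm_forward_pass(X, object$params)$Y)
  Y <- sweep(sweep(Yst, 2, object$target_sd, "*"), 2, object$target_mean, "+")
  colnames(Y) <- object$target_cols
  out <- tibble::as_tibble(Y)
  if ("time" %in% names(features)) {
    out <- dplyr::bind_cols(tibble::tibble(time = features$time), out)
  }
  out
}

#' Predict the wrench (pipe-friendly wrapper)
#'
#' @inheritParams predict.grf_lstm
#' @param model A fitted `grf_lstm`.
#' @return See [predict.grf_lstm()].
#' @export
predict_wrench <- function(features, model, standardized = FALSE) {
  predict(model, features, standardized = standardized)
}

#' @describeIn fit_grf_lstm Per-epoch training log as a tibble.
#' @param x A `grf_lstm`.
#' @param ... Unused.
#' @export
tidy.grf_lstm <- function(x, ...) x$log

#' @describeIn fit_grf_lstm One-row model summary.
#' @export
glance.grf_lstm <- function(x, ...) {
  tibble::tibble(
    pattern_id = x$pattern_id,
    input_dim = x$params$d,
    hidden_size = x$params$H,
    epochs = nrow(x$log),
    best_val_loss = suppressWarnings(min(x$log$val_loss, na.rm = TRUE)),
    final_train_loss = x$log$train_loss[nrow(x$log)]
  )
}
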