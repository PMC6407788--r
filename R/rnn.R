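#' Sequence-regressor architecture
#'
#' A many-to-one recurrent regressor: an input layer the size of the recorded
#' population, a stack of LSTM layers, and a linear output layer producing
#' the spatial coordinates. The prediction is read out only at the final
#' timestep of the input sequence.
#'
#' @param n_inputs number of units (input channels).
#' @param hidden_per_layer LSTM nodes per layer (512 in the reference
#'   configuration; 64-128 for the CPU-scale test profile).
#' @param n_layers number of LSTM layers (2).
#' @param output_dim 2 for open-field x,y; 1 for a linearised track.
#' @return list of class `regressor_spec`.
#' @export
regressor_spec <- function(n_inputs, hidden_per_layer = 512, n_layers = 2,
                           output_dim = 2) {
  stopifnot(n_inputs >= 1, hidden_per_layer >= 1, n_layers >= 1,
            output_dim >= 1)
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden_per_layer = as.integer(hidden_per_layer),
                 n_layers = as.integer(n_layers),
                 output_dim = as.integer(output_dim)),
            class = "regressor_spec")
}

#' Training configuration for the sequence regressor
#'
#' Defaults follow the reference recipe: 50 epochs at a constant learning
#' rate of 0.001 with the RMSprop adaptive optimiser and mini-batches of 64,
#' minimising the mean squared error of the predicted coordinates. No early
#' stopping is used.
#'
#' @param epochs full passes over the training data.
#' @param learning_rate constant step size.
#' @param batch_size mini-batch size.
#' @param rho,eps RMSprop decay and stabiliser.
#' @param rng_seed seed for weight shuffling order.
#' @param shuffle reshuffle sample order each epoch.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 50, learning_rate = 0.001, batch_size = 64,
                         rho = 0.9, eps = 1e-7, rng_seed = 1L, shuffle = TRUE) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            rho > 0, rho < 1, eps > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), rho = rho, eps = eps,
                 rng_seed = as.integer(rng_seed), shuffle = isTRUE(shuffle)),
            class = "train_config")
}

sigm <- function(x) 1 / (1 + exp(-x))

#' Build an (untrained) LSTM sequence regressor
#'
#' Weights use the standard gating parameterisation: per layer one
#' `(n_in + h) x 4h` kernel (gate order input, forget, candidate, output)
#' plus a `4h` bias, and a final `h x output_dim` linear readout.
#' Initialisation is Glorot-uniform with the forget-gate bias set to 1,
#' deterministically from `seed`.
#'
#' @param spec a [regressor_spec()].
#' @param seed initialisation seed.
#' @return object of class `lstm_regressor` supporting
#'   [train_regressor()], [predict_positions()] and
#'   [loss_input_gradients()].
#' @export
build_regressor <- function(spec, seed = 1L) {
  H <- spec$hidden_per_layer
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    layers <- vector("list", spec$n_layers)
    n_in <- spec$n_inputs
    for (l in seq_len(spec$n_layers)) {
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1          # forget-gate bias
      layers[[l]] <- list(W = glorot(n_in + H, 4 * H), b = b)
      n_in <- H
    }
    Wy <- glorot(H, spec$output_dim)
    by <- numeric(spec$output_dim)
    structure(list(spec = spec, layers = layers, Wy = Wy, by = by,
                   seed = as.integer(seed), trained = FALSE,
                   loss_history = numeric(0)),
              class = "lstm_regressor")
  })
}

#' @export
print.lstm_regressor <- function(x, ...) {
  cat(sprintf("<lstm_regressor> %d inputs -> %d x %d LSTM -> %d outputs; %s; %d parameters\n",
              x$spec$n_inputs, x$spec$n_layers, x$spec$hidden_per_layer,
              x$spec$output_dim, if (x$trained) "trained" else "untrained",
              n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model an [build_regressor()] model.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1))) +
    length(model$Wy) + length(model$by)
}

# Forward pass. X: B x T x N array. Returns predictions and (optionally) the
# per-timestep cache needed for backpropagation through time.
lstm_forward <- function(model, X, keep_cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  H <- model$spec$hidden_per_layer
  L <- model$spec$n_layers
  cache <- if (keep_cache) vector("list", L) else NULL
  inp <- lapply(seq_len(Tn), function(t) matrix(X[, t, ], nrow = B))
  for (l in seq_len(L)) {
    W <- model$layers[[l]]$W
    bmat <- matrix(model$layers[[l]]$b, B, 4 * H, byrow = TRUE)
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    out <- vector("list", Tn)
    lc <- if (keep_cache) vector("list", Tn) else NULL
    i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
    for (t in seq_len(Tn)) {
      A <- cbind(inp[[t]], h)
      Z <- A %*% W + bmat
      gi <- sigm(Z[, i1, drop = FALSE]); gf <- sigm(Z[, i2, drop = FALSE])
      gg <- tanh(Z[, i3, drop = FALSE]); go <- sigm(Z[, i4, drop = FALSE])
      cprev <- cc
      cc <- gf * cprev + gi * gg
      tc <- tanh(cc)
      h <- go * tc
      out[[t]] <- h
      if (keep_cache)
        lc[[t]] <- list(A = A, i = gi, f = gf, g = gg, o = go,
                        cprev = cprev, tc = tc)
    }
    if (keep_cache) cache[[l]] <- lc
    inp <- out
  }
  hT <- inp[[Tn]]
  Y <- hT %*% model$Wy + matrix(model$by, B, length(model$by), byrow = TRUE)
  list(Y = Y, hT = hT, top = inp, cache = cache, B = B, Tn = Tn)
}

# Backward pass from dY (B x output_dim). Returns weight gradients and,
# when want_dx, the gradient with respect to the inputs (B x T x N array).
lstm_backward <- function(model, fw, dY, want_dx = FALSE) {
  B <- fw$B; Tn <- fw$Tn
  H <- model$spec$hidden_per_layer
  L <- model$spec$n_layers
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
  gWy <- crossprod(fw$hT, dY)
  gby <- colSums(dY)
  # incoming dh per timestep for the top layer: only the final step sees dY
  dh_in <- vector("list", Tn)
  zero_h <- matrix(0, B, H)
  for (t in seq_len(Tn)) dh_in[[t]] <- zero_h
  dh_in[[Tn]] <- tcrossprod(dY, model$Wy)
  grads <- vector("list", L)
  dX <- NULL
  for (l in L:1) {
    W <- model$layers[[l]]$W
    lc <- fw$cache[[l]]
    n_in <- nrow(W) - H
    gW <- matrix(0, nrow(W), ncol(W)); gb <- numeric(4 * H)
    dh_next <- zero_h; dc_next <- zero_h
    dIn <- vector("list", Tn)
    for (t in Tn:1) {
      s <- lc[[t]]
      dh <- dh_in[[t]] + dh_next
      do_ <- dh * s$tc
      dc <- dc_next + dh * s$o * (1 - s$tc^2)
      di <- dc * s$g; dg <- dc * s$i; df <- dc * s$cprev
      dc_next <- dc * s$f
      dZ <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                  dg * (1 - s$g^2), do_ * s$o * (1 - s$o))
      gW <- gW + crossprod(s$A, dZ)
      gb <- gb + colSums(dZ)
      dA <- tcrossprod(dZ, W)
      dIn[[t]] <- dA[, seq_len(n_in), drop = FALSE]
      dh_next <- dA[, n_in + i1, drop = FALSE]
    }
    grads[[l]] <- list(W = gW, b = gb)
    if (l > 1L) dh_in <- dIn
    else if (want_dx) {
      dX <- array(0, dim = c(B, Tn, n_in))
      for (t in seq_len(Tn)) dX[, t, ] <- dIn[[t]]
    }
  }
  list(layers = grads, Wy = gWy, by = gby, dX = dX)
}

#' Train the sequence regressor
#'
#' Minimises the mean squared error of the coordinates (mean over samples of
#' the summed squared coordinate error) with RMSprop at a constant learning
#' rate, for exactly `cfg$epochs` passes; no early stopping. The run is
#' deterministic given the model's initialisation seed and `cfg$rng_seed`.
#'
#' @param model an untrained (or previously trained) [build_regressor()].
#' @param data a [build_sequences()] dataset whose unit count matches the
#'   spec.
#' @param cfg a [train_config()].
#' @return the trained model, with `loss_history` (one mean training loss per
#'   epoch) attached.
#' @export
train_regressor <- function(model, data, cfg = train_config()) {
  X <- data$inputs; Yt <- as.matrix(data$targets)
  D <- dim(X)[1]
  if (D == 0L) stop("empty training data")
  if (dim(X)[3] != model$spec$n_inputs)
    stop("input unit count does not match the regressor spec")
  if (ncol(Yt) != model$spec$output_dim)
    stop("target dimensionality does not match the regressor spec")
  rms <- list(layers = lapply(model$layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b)))),
    Wy = matrix(0, nrow(model$Wy), ncol(model$Wy)),
    by = numeric(length(model$by)))
  upd <- function(w, g, r) {
    r <- cfg$rho * r + (1 - cfg$rho) * g^2
    list(w = w - cfg$learning_rate * g / (sqrt(r) + cfg$eps), r = r)
  }
  hist <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- if (cfg$shuffle)
      with_seed(child_seed(cfg$rng_seed, 100 + ep), sample.int(D))
    else seq_len(D)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1, D, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, D)]
      B <- length(idx)
      Xb <- X[idx, , , drop = FALSE]
      Tb <- Yt[idx, , drop = FALSE]
      fw <- lstm_forward(model, Xb, keep_cache = TRUE)
      err <- fw$Y - Tb
      loss <- mean(rowSums(err^2))
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d; lower the learning rate", ep))
      bw <- lstm_backward(model, fw, 2 * err / B)
      for (l in seq_along(model$layers)) {
        u <- upd(model$layers[[l]]$W, bw$layers[[l]]$W, rms$layers[[l]]$W)
        model$layers[[l]]$W <- u$w; rms$layers[[l]]$W <- u$r
        u <- upd(model$layers[[l]]$b, bw$layers[[l]]$b, rms$layers[[l]]$b)
        model$layers[[l]]$b <- u$w; rms$layers[[l]]$b <- u$r
      }
      u <- upd(model$Wy, bw$Wy, rms$Wy); model$Wy <- u$w; rms$Wy <- u$r
      u <- upd(model$by, bw$by, rms$by); model$by <- u$w; rms$by <- u$r
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    hist[ep] <- ep_loss / nb
  }
  model$trained <- TRUE
  model$loss_history <- c(model$loss_history, hist)
  model
}

#' Predict positions for input sequences
#'
#' Forward pass only; deterministic given fixed weights. Predictions are not
#' clamped to the arena.
#'
#' @param model a (trained) [build_regressor()] model.
#' @param inputs samples x seq_len x units array, or a `sequence_dataset`.
#' @param batch_size forward batch size (memory control only).
#' @return matrix samples x output_dim of coordinates (cm).
#' @export
predict_positions <- function(model, inputs, batch_size = 256) {
  if (inherits(inputs, "sequence_dataset")) inputs <- inputs$inputs
  if (length(dim(inputs)) != 3L)
    stop("inputs must be a samples x seq_len x units array")
  if (dim(inputs)[3] != model$spec$n_inputs)
    stop("input unit count does not match the regressor spec")
  D <- dim(inputs)[1]
  out <- matrix(NA_real_, D, model$spec$output_dim)
  for (b0 in seq(1, D, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, D)
    out[idx, ] <- lstm_forward(model, inputs[idx, , , drop = FALSE])$Y
  }
  out
}

#' Gradient magnitudes of the loss with respect to the inputs
#'
#' For each sample, the per-sample squared-error loss is backpropagated
#' through time down to the input spike counts, giving
#' `|d loss_s / d input[s, t, n]|` for every timestep and unit. Only
#' magnitudes are returned; the sign of the gradient is discarded.
#'
#' @param model a [build_regressor()] model (trained or not).
#' @param data a `sequence_dataset` (its targets define the losses).
#' @param batch_size backward batch size.
#' @return object of class `gradient_tensor`: array D x seq_len x units of
#'   non-negative finite values.
#' @export
loss_input_gradients <- function(model, data, batch_size = 64) {
  X <- data$inputs; Yt <- as.matrix(data$targets)
  D <- dim(X)[1]
  g <- array(NA_real_, dim = dim(X), dimnames = dimnames(X))
  for (b0 in seq(1, D, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, D)
    fw <- lstm_forward(model, X[idx, , , drop = FALSE], keep_cache = TRUE)
    # per-sample loss: no 1/B factor, so rows stay independent
    bw <- lstm_backward(model, fw, 2 * (fw$Y - Yt[idx, , drop = FALSE]),
                        want_dx = TRUE)
    g[idx, , ] <- abs(bw$dX)
  }
  structure(g, class = "gradient_tensor")
}
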