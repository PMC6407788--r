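# The seed-pinned synthetic benchmark (40 place cells + 3 interneurons,
# 1200 s open field, 1400 ms windows) shared by the acceptance tests.
# Expensive artifacts are memoised so the flat-Bayes, sequence-regressor and
# sensitivity criteria reuse one simulated session and one trained model.

.bench <- new.env(parent = emptyenv())

bench_seed <- 11L

bench_cfg <- function() run_config(window_len_ms = 1400, stride_ms = 200,
                                   seq_len = 25, rng_seed = bench_seed)

bench_session <- function() {
  if (is.null(.bench$session))
    .bench$session <- simulate_session(sim_config(rng_seed = bench_seed))
  .bench$session
}

bench_flat_cv <- function() {
  if (is.null(.bench$flat)) {
    ses <- bench_session()
    .bench$flat <- run_cv(ses$spikes, ses$traj, "flat", bench_cfg())
  }
  .bench$flat
}

# Scaled CPU profile of the sequence regressor: hidden 128, 2 layers,
# 20 epochs, 25-step sequences, fold 1 only, every 2nd training sample.
bench_rnn <- function() {
  if (is.null(.bench$rnn)) {
    ses <- bench_session()
    cfg <- bench_cfg()
    span <- validate_session(ses$spikes, ses$traj)$usable_span
    wc <- count_in_windows(ses$spikes, cfg$window_len_s, cfg$stride_s, span)
    ds <- build_sequences(wc, ses$traj, cfg$seq_len)
    n <- dim(ds$inputs)[1]
    fold <- blocked_folds(n, cfg$n_folds, cfg$seq_len)[[1]]
    tr_idx <- fold$train_idx[seq(1, length(fold$train_idx), by = 2)]
    tr <- list(inputs = ds$inputs[tr_idx, , , drop = FALSE],
               targets = ds$targets[tr_idx, , drop = FALSE])
    model <- build_regressor(regressor_spec(length(ds$unit_ids), 128, 2, 2),
                             seed = bench_seed)
    model <- train_regressor(model, tr,
                             train_config(epochs = 20, rng_seed = bench_seed + 1))
    val <- ds
    val$inputs <- ds$inputs[fold$val_idx, , , drop = FALSE]
    val$targets <- ds$targets[fold$val_idx, , drop = FALSE]
    val$sample_to_window <- ds$sample_to_window[fold$val_idx]
    pred <- predict_positions(model, val)
    err <- sqrt(rowSums((pred - val$targets)^2))
    mean_tr <- colMeans(tr$targets)
    chance <- sqrt(rowSums((matrix(mean_tr, nrow(val$targets), 2,
                                   byrow = TRUE) - val$targets)^2))
    .bench$rnn <- list(model = model, val = val, pred = pred, err = err,
                       chance_err = chance, train_mean = mean_tr)
  }
  .bench$rnn
}

bench_gradients <- function() {
  if (is.null(.bench$grads)) {
    b <- bench_rnn()
    .bench$grads <- loss_input_gradients(b$model, b$val)
  }
  .bench$grads
}
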