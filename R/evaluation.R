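#' Leakage-safe blocked cross-validation folds
#'
#' Splits `n_samples` time-ordered samples into `k` contiguous blocks (the
#' remainder goes to the last block); fold f validates on block f and trains
#' on the rest. Because sample `s` is built from the `seq_len` windows ending
#' at `s`, samples `i` and `j` share at least one spike-count window iff
#' `|i - j| < seq_len`; every validation sample violating that against any
#' training sample is discarded. For `seq_len = 100` this removes 99 samples
#' at each train/validation border.
#'
#' @param n_samples number of samples.
#' @param k number of folds.
#' @param seq_len windows per sample (1 means no discards).
#' @return list of `fold_split` objects with `train_idx`, `val_idx`
#'   (retained), `discarded_idx`.
#' @export
blocked_folds <- function(n_samples, k = 10, seq_len = 100) {
  stopifnot(n_samples >= k, k >= 2, seq_len >= 1)
  block <- floor(n_samples / k)          # remainder goes to the last fold
  bounds <- c((0:(k - 1)) * block, n_samples)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    val_all <- (bounds[f] + 1L):bounds[f + 1L]
    train <- setdiff(seq_len(n_samples), val_all)
    if (length(train)) {
      lo <- if (bounds[f] >= 1L) bounds[f] else -Inf        # nearest train below
      hi <- if (bounds[f + 1L] < n_samples) bounds[f + 1L] + 1L else Inf
      keep <- (val_all - lo >= seq_len) & (hi - val_all >= seq_len)
    } else keep <- rep(TRUE, length(val_all))
    if (!any(keep))
      warning(sprintf("fold %d retains no validation samples after border discards", f))
    folds[[f]] <- structure(list(train_idx = train,
                                 val_idx = val_all[keep],
                                 discarded_idx = val_all[!keep]),
                            class = "fold_split")
  }
  folds
}

#' Prediction-error metrics
#'
#' Computes per-sample errors and their aggregates. `"2d"`: Euclidean
#' distance in continuous coordinates, plus per-coordinate absolute errors;
#' `"1d"`: absolute arc-length difference; `"bin2d"`: the bin-based variant
#' used by grid-decoders, measuring centre-of-decoded-bin to
#' centre-of-nearest-true-bin distance (both positions snapped to the
#' `bin_cm` grid).
#'
#' @param pred predicted positions (matrix n x dims).
#' @param truth true positions (same shape).
#' @param mode `"2d"`, `"1d"` or `"bin2d"`.
#' @param bin_cm grid for `"bin2d"`.
#' @return list with `table` (per-sample data frame), `med` (mean error,
#'   i.e. the MED statistic), `median_err`.
#' @export
compute_errors <- function(pred, truth, mode = c("2d", "1d", "bin2d"),
                           bin_cm = 2) {
  mode <- match.arg(mode)
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (nrow(pred) != nrow(truth) || ncol(pred) != ncol(truth))
    stop("pred and truth must have identical dimensions")
  snap <- function(p) (floor(p / bin_cm) + 0.5) * bin_cm
  if (mode == "bin2d") { pred <- snap(pred); truth <- snap(truth) }
  if (mode == "1d") {
    err <- abs(pred[, 1] - truth[, 1])
    tab <- data.frame(true_s = truth[, 1], pred_s = pred[, 1], err = err)
  } else {
    dx <- pred[, 1] - truth[, 1]; dy <- pred[, 2] - truth[, 2]
    err <- sqrt(dx^2 + dy^2)
    tab <- data.frame(true_x = truth[, 1], true_y = truth[, 2],
                      pred_x = pred[, 1], pred_y = pred[, 2],
                      err = err, err_x = abs(dx), err_y = abs(dy))
  }
  list(table = tab, med = mean(err), median_err = stats::median(err))
}

#' Histogram of decoding errors
#'
#' Errors are grouped into `bin_cm` bins from zero; the final bin collects
#' all errors above `cap_cm`.
#'
#' @param errors non-negative errors (cm).
#' @param bin_cm bin width.
#' @param cap_cm overflow threshold.
#' @return named integer vector of counts (sums to `length(errors)`).
#' @export
error_histogram <- function(errors, bin_cm = 2, cap_cm = 50) {
  stopifnot(all(errors >= 0))
  edges <- seq(0, cap_cm, by = bin_cm)
  idx <- findInterval(errors, c(edges, Inf), left.open = FALSE,
                      rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges))
  names(counts) <- c(sprintf("[%g,%g)", edges[-length(edges)], edges[-1]),
                     sprintf(">%g", cap_cm))
  counts
}

#' Project 2D positions onto a Z-track and linearise
#'
#' Each point is projected orthogonally onto the nearest point of the track
#' polyline; the 1D coordinate is the cumulative arc length of that
#' projection, ranging from 0 at the start of the first arm to the summed
#' segment length at the far end.
#'
#' @param points2d n x 2 matrix of positions (cm).
#' @param track an [arena_ztrack()].
#' @return numeric vector of arc-length coordinates (cm).
#' @export
linearize_z <- function(points2d, track) {
  if (track$kind != "ztrack") stop("linearize_z needs a ztrack arena")
  pts <- as.matrix(points2d)
  P <- track$corners
  cum <- c(0, cumsum(track$segment_lengths))
  best_d2 <- rep(Inf, nrow(pts)); best_s <- numeric(nrow(pts))
  for (sgm in 1:3) {
    a <- P[sgm, ]; b <- P[sgm + 1, ]
    v <- b - a; len2 <- sum(v^2)
    if (len2 <= 0) stop("degenerate (zero-length) track segment")
    tt <- pmin(pmax(((pts[, 1] - a[1]) * v[1] + (pts[, 2] - a[2]) * v[2]) / len2, 0), 1)
    px <- a[1] + tt * v[1]; py <- a[2] + tt * v[2]
    d2 <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cum[sgm] + tt[upd] * sqrt(len2)
  }
  best_s
}

#' Instantaneous movement speed at given times
#'
#' Speed at a sample is the distance covered in the 200 ms around it divided
#' by 0.2 s (the tracking-derived convention used for the speed/error
#' analysis).
#'
#' @param traj a [trajectory()].
#' @param at times, seconds.
#' @param dt_s measurement interval (0.2 s).
#' @return speeds in cm/s (`NA` where the interval leaves the tracked span).
#' @export
speed_at <- function(traj, at, dt_s = 0.2) {
  p1 <- interp_position(traj, at - dt_s / 2)
  p2 <- interp_position(traj, at + dt_s / 2)
  sqrt(rowSums((p2 - p1)^2, na.rm = FALSE)) / dt_s
}

center_of <- function(arena) {
  if (arena$kind == "box2d") c(arena$width / 2, arena$height / 2)
  else arena$total_length / 2
}

# subset a windowed_counts to a set of window indices
wc_subset <- function(wc, idx) {
  wc$counts <- wc$counts[, idx, drop = FALSE]
  wc$window_centers <- wc$window_centers[idx]
  wc
}

# restrict spikes + trajectory to a union of closed time intervals
restrict_session <- function(spikes, traj, intervals) {
  inside <- function(t) {
    ok <- rep(FALSE, length(t))
    for (r in seq_len(nrow(intervals)))
      ok <- ok | (t >= intervals[r, 1] & t <= intervals[r, 2])
    ok
  }
  st <- lapply(spikes$spike_times, function(t) t[inside(t)])
  sp <- spike_data(st, session_span = spikes$session_span,
                   unit_ids = spikes$unit_ids)
  keep <- inside(traj$timestamps)
  tr <- traj
  tr$timestamps <- traj$timestamps[keep]
  tr$positions <- traj$positions[keep, , drop = FALSE]
  list(spikes = sp, traj = tr)
}

# contiguous index runs -> time intervals covered by those windows
window_runs_to_intervals <- function(idx, wc) {
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  brk <- which(diff(idx) > 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  cbind(wc$window_centers[starts] - wc$window_len_s / 2,
        wc$window_centers[ends] + wc$window_len_s / 2)
}

#' Blocked cross-validated decoding of a session
#'
#' Runs the full pipeline for one decoder: windowed counts over the usable
#' span, contiguous blocked folds with border discards, per-fold model
#' estimation on training data only (ratemaps and occupancy prior for the
#' Bayesian decoders; LSTM training for the sequence regressor) and
#' validation-set decoding. The Bayesian decoders are deterministic and run
#' once; the sequence regressor is retrained `n_repeats` times with distinct
#' seeds and the reported errors are the average of the per-realization
#' errors (not the error of the averaged prediction).
#'
#' For the Bayesian decoders the effective sample-dependency length used for
#' border discards is `ceiling(window_len/stride)` overlapping windows; for
#' the sequence decoder it is `seq_len`.
#'
#' @param spikes a [spike_data()].
#' @param traj a [trajectory()].
#' @param decoder `"flat"`, `"memory"` or `"rnn"`.
#' @param cfg a [run_config()].
#' @param folds_to_run optional subset of fold indices (e.g. a single fold
#'   for a quick benchmark); default all.
#' @param hidden,n_layers,epochs sequence-regressor profile (defaults follow
#'   the reference architecture; use e.g. `hidden = 128, epochs = 20` for the
#'   CPU-scale profile).
#' @param n_repeats realizations of the stochastic decoder (default from
#'   `cfg`; forced to 1 for the deterministic Bayesian decoders).
#' @param prior_mode occupancy prior source for the memory decoder:
#'   `"train_only"` (leakage-safe default) or `"full_trial"`.
#' @param train_subsample keep every `train_subsample`-th training sample for
#'   the sequence regressor (compute control; 1 = all).
#' @param verbose print per-fold progress.
#' @return object of class `cv_result`: `summary` (mean/median error,
#'   baseline errors), `per_fold` data frame, `samples` data frame with one
#'   row per retained validation sample and realization.
#' @export
run_cv <- function(spikes, traj, decoder = c("flat", "memory", "rnn"),
                   cfg = run_config(), folds_to_run = NULL,
                   hidden = 512, n_layers = 2, epochs = 50,
                   n_repeats = NULL,
                   prior_mode = c("train_only", "full_trial"),
                   train_subsample = 1L, verbose = FALSE) {
  decoder <- match.arg(decoder)
  prior_mode <- match.arg(prior_mode)
  rep_n <- if (decoder == "rnn") {
    if (is.null(n_repeats)) cfg$n_repeats else as.integer(n_repeats)
  } else 1L
  span <- validate_session(spikes, traj)$usable_span
  wc <- count_in_windows(spikes, cfg$window_len_s, cfg$stride_s, span)
  dims <- ncol(traj$positions)
  ctr <- center_of(traj$arena)

  if (decoder == "rnn") {
    ds <- build_sequences(wc, traj, cfg$seq_len)
    n <- dim(ds$inputs)[1]
    dep_len <- cfg$seq_len
  } else {
    truth_all <- interp_position(traj, wc$window_centers)
    ok <- stats::complete.cases(truth_all)
    wc <- wc_subset(wc, which(ok))
    truth_all <- truth_all[ok, , drop = FALSE]
    n <- ncol(wc$counts)
    dep_len <- ceiling(wc$window_len_s / wc$stride_s)
  }
  folds <- blocked_folds(n, cfg$n_folds, dep_len)
  if (is.null(folds_to_run)) folds_to_run <- seq_along(folds)

  samples <- list(); per_fold <- list()
  for (f in folds_to_run) {
    fold <- folds[[f]]
    if (!length(fold$val_idx)) next
    if (verbose) message(sprintf("fold %d: %d train / %d val samples",
                                 f, length(fold$train_idx), length(fold$val_idx)))
    if (decoder %in% c("flat", "memory")) {
      ivl <- window_runs_to_intervals(fold$train_idx, wc)
      sub <- restrict_session(spikes, traj, ivl)
      maps <- compute_ratemaps(sub$spikes, sub$traj, bin_cm = cfg$bin_cm,
                               sigma_bins = cfg$smooth_sigma_bins,
                               rate_floor_hz = cfg$rate_floor_hz,
                               span = range(ivl))
      truth <- truth_all[fold$val_idx, , drop = FALSE]
      if (decoder == "flat") {
        dec <- decode_flat(wc_subset(wc, fold$val_idx), maps)
        pred <- dec$positions
      } else {
        occ_src <- if (prior_mode == "full_trial")
          compute_occupancy(traj, cfg$bin_cm)$occupancy_s else maps$occupancy_s
        pr <- occupancy_prior(occ_src * maps$visited, mode = prior_mode)
        mp <- memory_params(cfg$memory_history, cfg$memory_scale,
                            cfg$min_sigma_cm)
        # continuity applies within contiguous retained runs only
        runs <- split(seq_along(fold$val_idx),
                      cumsum(c(1, diff(fold$val_idx) > 1)))
        pred <- matrix(NA_real_, length(fold$val_idx), dims)
        for (r in runs) {
          dec <- decode_with_memory(wc_subset(wc, fold$val_idx[r]), maps,
                                    prior = pr, mp = mp)
          pred[r, ] <- dec$positions
        }
      }
      e <- compute_errors(pred, truth, mode = if (dims == 2) "2d" else "1d")
      chance <- compute_errors(matrix(ctr, nrow(truth), dims, byrow = TRUE),
                               truth, mode = if (dims == 2) "2d" else "1d")
      tab <- e$table
      tab$fold <- f; tab$realization <- 1L
      tab$sample_idx <- fold$val_idx
      tab$window_center_s <- wc$window_centers[fold$val_idx]
      tab$chance_err <- chance$table$err
      samples[[length(samples) + 1L]] <- tab
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        fold = f, realization = 1L, n_val = nrow(tab),
        mean_cm = e$med, median_cm = e$median_err)
    } else {
      tr_idx <- fold$train_idx
      if (train_subsample > 1L)
        tr_idx <- tr_idx[seq(1L, length(tr_idx), by = train_subsample)]
      tr <- list(inputs = ds$inputs[tr_idx, , , drop = FALSE],
                 targets = ds$targets[tr_idx, , drop = FALSE])
      va_in <- ds$inputs[fold$val_idx, , , drop = FALSE]
      truth <- ds$targets[fold$val_idx, , drop = FALSE]
      tr_mean <- colMeans(tr$targets)
      for (rep_i in seq_len(rep_n)) {
        sd0 <- child_seed(cfg$rng_seed, 1000 * f + rep_i)
        model <- build_regressor(regressor_spec(length(wc$unit_ids), hidden,
                                                n_layers, dims), seed = sd0)
        model <- train_regressor(model, tr,
                                 train_config(epochs = epochs,
                                              rng_seed = sd0 + 1))
        pred <- predict_positions(model, va_in)
        e <- compute_errors(pred, truth, mode = if (dims == 2) "2d" else "1d")
        chance <- compute_errors(matrix(tr_mean, nrow(truth), dims, byrow = TRUE),
                                 truth, mode = if (dims == 2) "2d" else "1d")
        tab <- e$table
        tab$fold <- f; tab$realization <- rep_i
        tab$sample_idx <- fold$val_idx
        tab$window_center_s <- wc$window_centers[ds$sample_to_window[fold$val_idx]]
        tab$chance_err <- chance$table$err
        samples[[length(samples) + 1L]] <- tab
        per_fold[[length(per_fold) + 1L]] <- data.frame(
          fold = f, realization = rep_i, n_val = nrow(tab),
          mean_cm = e$med, median_cm = e$median_err)
      }
    }
  }
  samples <- do.call(rbind, samples)
  per_fold <- do.call(rbind, per_fold)
  by_rel <- split(samples$err, samples$realization)
  chance_by_rel <- split(samples$chance_err, samples$realization)
  summary <- list(
    decoder = decoder,
    mean_cm = mean(vapply(by_rel, mean, numeric(1))),
    median_cm = mean(vapply(by_rel, stats::median, numeric(1))),
    chance_mean_cm = mean(vapply(chance_by_rel, mean, numeric(1))),
    chance_median_cm = mean(vapply(chance_by_rel, stats::median, numeric(1))),
    n_samples = nrow(samples), n_realizations = rep_n)
  structure(list(summary = summary, per_fold = per_fold, samples = samples,
                 window_len_s = wc$window_len_s),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_result> %s decoder, %g s windows: mean %.2f cm, median %.2f cm (chance median %.2f cm; %d sample errors)\n",
              s$decoder, x$window_len_s, s$mean_cm, s$median_cm,
              s$chance_median_cm, s$n_samples))
  invisible(x)
}

#' Scan decoding error over window lengths
#'
#' Repeats cross-validated decoding for each window length (the canonical
#' scan is 200-4000 ms in 200 ms steps at a fixed 200 ms stride) and
#' tabulates mean and median error per length — the error-versus-window
#' curve is typically convex with its minimum at an intermediate length.
#'
#' @param spikes,traj the session.
#' @param window_lens_ms window lengths to scan, ms.
#' @param decoder passed to [run_cv()].
#' @param cfg base [run_config()]; its window length is overridden.
#' @param ... further arguments to [run_cv()].
#' @return data frame with `window_ms`, `mean_cm`, `median_cm`.
#' @export
window_scan <- function(spikes, traj, window_lens_ms = seq(200, 4000, 200),
                        decoder = "flat", cfg = run_config(), ...) {
  rows <- lapply(window_lens_ms, function(w) {
    cfg_w <- cfg
    cfg_w$window_len_s <- w / 1000
    r <- run_cv(spikes, traj, decoder = decoder, cfg = cfg_w, ...)
    data.frame(window_ms = w, mean_cm = r$summary$mean_cm,
               median_cm = r$summary$median_cm)
  })
  do.call(rbind, rows)
}

#' Error-covariate analysis
#'
#' Relates per-sample decoding error to behavioural and neural covariates:
#' (i) Spearman correlation of error with the number of training positions
#' within 10 cm of the predicted point (local training density); (ii) with
#' the summed population spike count in the sample's window; (iii) of each
#' coordinate's error with the animal's distance to the perpendicular wall,
#' restricted to samples within 25 cm of that wall; and (iv) mean/median
#' error by movement-speed class (stationary < 0.5 cm/s; moving 0.5-10.5;
#' fast > 10.5 cm/s) with two-sided Welch t-tests between classes.
#'
#' @param errtab per-sample data frame with columns `true_x, true_y, pred_x,
#'   pred_y, err, err_x, err_y` plus optional `speed` (cm/s) and `pop_count`.
#' @param train_positions matrix of training-sample target positions (cm).
#' @param arena the box arena.
#' @return list with `correlations` (covariate, rho, n), `speed_classes`
#'   (class, n, mean_cm, median_cm), and `speed_tests` (Welch t-tests:
#'   stationary vs moving, moving vs fast).
#' @export
covariate_analysis <- function(errtab, train_positions, arena) {
  stopifnot(arena$kind == "box2d")
  sp_cor <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b, method = "spearman")
  }
  rows <- list()
  if (!is.null(train_positions)) {
    tp <- as.matrix(train_positions)
    dens <- vapply(seq_len(nrow(errtab)), function(i) {
      sum((tp[, 1] - errtab$pred_x[i])^2 +
            (tp[, 2] - errtab$pred_y[i])^2 <= 100) }, numeric(1))
    rows$density <- data.frame(covariate = "local_training_density",
                               rho = sp_cor(errtab$err, dens),
                               n = nrow(errtab))
  }
  if (!is.null(errtab$pop_count))
    rows$pop <- data.frame(covariate = "summed_population_count",
                           rho = sp_cor(errtab$err, errtab$pop_count),
                           n = nrow(errtab))
  wx <- pmin(errtab$true_x, arena$width - errtab$true_x)
  wy <- pmin(errtab$true_y, arena$height - errtab$true_y)
  nx <- wx <= 25; ny <- wy <= 25
  rows$wall <- data.frame(
    covariate = c("wall_distance_x", "wall_distance_y", "wall_distance_pooled"),
    rho = c(sp_cor(errtab$err_x[nx], wx[nx]),
            sp_cor(errtab$err_y[ny], wy[ny]),
            sp_cor(c(errtab$err_x[nx], errtab$err_y[ny]), c(wx[nx], wy[ny]))),
    n = c(sum(nx), sum(ny), sum(nx) + sum(ny)))
  correlations <- do.call(rbind, rows)
  rownames(correlations) <- NULL

  speed_classes <- NULL; speed_tests <- list()
  if (!is.null(errtab$speed)) {
    cls <- cut(errtab$speed, c(-Inf, 0.5, 10.5, Inf),
               labels = c("stationary", "moving", "fast"))
    keep <- !is.na(cls)
    tab <- lapply(levels(cls), function(lv) {
      e <- errtab$err[keep & cls == lv]
      if (length(e) < 3)
        return(data.frame(class = lv, n = length(e), mean_cm = NA,
                          median_cm = NA, note = "skipped: < 3 samples"))
      data.frame(class = lv, n = length(e), mean_cm = mean(e),
                 median_cm = stats::median(e), note = "")
    })
    speed_classes <- do.call(rbind, tab)
    e_stat <- errtab$err[keep & cls == "stationary"]
    e_mov <- errtab$err[keep & cls != "stationary"]
    e_mid <- errtab$err[keep & cls == "moving"]
    e_fast <- errtab$err[keep & cls == "fast"]
    safe_t <- function(a, b) tryCatch(stats::t.test(a, b),
                                      error = function(e) NULL)
    if (length(e_stat) >= 3 && length(e_mov) >= 3)
      speed_tests$stationary_vs_moving <- safe_t(e_stat, e_mov)
    if (length(e_mid) >= 3 && length(e_fast) >= 3)
      speed_tests$moving_vs_fast <- safe_t(e_mid, e_fast)
  }
  list(correlations = correlations, speed_classes = speed_classes,
       speed_tests = speed_tests)
}

#' Population-downsampling experiment
#'
#' For each population size, draws `n_sets` random unit subsets and runs the
#' full cross-validated decoding on each; reports the mean-of-means and
#' mean-of-medians per size. Decoding error typically decreases with
#' population size.
#'
#' @param spikes,traj the session.
#' @param sizes population sizes (the canonical scan is 5 to 55 in steps of
#'   5); sizes above the recorded count are skipped with a warning.
#' @param n_sets random subsets per size.
#' @param decoder,cfg,... passed to [run_cv()].
#' @return data frame with `size, n_sets, mean_of_means_cm,
#'   mean_of_medians_cm`.
#' @export
downsampling_experiment <- function(spikes, traj, sizes = seq(5, 55, 5),
                                    n_sets = 10, decoder = "flat",
                                    cfg = run_config(), ...) {
  N <- n_units(spikes)
  rows <- list()
  for (sz in sizes) {
    if (sz > N) { warning(sprintf("size %d > %d units; skipped", sz, N)); next }
    means <- medians <- numeric(n_sets)
    for (j in seq_len(n_sets)) {
      sub <- downsample_units(spikes, sz,
                              seed = child_seed(cfg$rng_seed, sz * 100 + j))
      r <- run_cv(sub, traj, decoder = decoder, cfg = cfg, ...)
      means[j] <- r$summary$mean_cm; medians[j] <- r$summary$median_cm
    }
    rows[[length(rows) + 1L]] <- data.frame(
      size = sz, n_sets = n_sets, mean_of_means_cm = mean(means),
      mean_of_medians_cm = mean(medians))
  }
  do.call(rbind, rows)
}
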