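#' Knockout-without-retraining sensitivity scan
#'
#' For each unit in turn, its activity is zeroed in all validation samples
#' (the model is never retrained, so it cannot compensate), predictions are
#' recomputed, and the increase in mean Euclidean error over the intact
#' model quantifies how crucial the unit is. Units are ranked by that error
#' increase (rank 1 = most influential).
#'
#' @param model a trained [build_regressor()] model.
#' @param val_data a `sequence_dataset` of validation samples (untouched by
#'   training).
#' @param baseline_errors optional per-sample errors of the intact model on
#'   `val_data`; computed if missing.
#' @return object of class `knockout_report`: data frame with `unit_id,
#'   mean_err_cm, delta_cm, rank`; attribute `baseline_mean_cm`.
#' @export
knockout_scan <- function(model, val_data, baseline_errors = NULL) {
  truth <- as.matrix(val_data$targets)
  if (is.null(baseline_errors)) {
    pred0 <- predict_positions(model, val_data)
    baseline_errors <- sqrt(rowSums((pred0 - truth)^2))
  }
  base_mean <- mean(baseline_errors)
  ids <- val_data$unit_ids
  res <- data.frame(unit_id = ids, mean_err_cm = NA_real_,
                    delta_cm = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    ko <- knockout_unit(val_data, i)
    pred <- predict_positions(model, ko)
    m <- mean(sqrt(rowSums((pred - truth)^2)))
    res$mean_err_cm[i] <- m
    res$delta_cm[i] <- m - base_mean
  }
  res$rank <- rank(-res$delta_cm, ties.method = "first")
  structure(res, class = c("knockout_report", "data.frame"),
            baseline_mean_cm = base_mean)
}

#' Aggregate a gradient tensor along one dimension
#'
#' The D x T x N tensor of input-gradient magnitudes can be averaged across
#' samples and timesteps (one sensitivity value per unit), across samples
#' and units (a temporal importance profile over the sequence), or — given
#' each sample's true position — across a spatial bin grid (a per-unit
#' "sensitivity field").
#'
#' @param g a [loss_input_gradients()] tensor.
#' @param axis `"units"`, `"timesteps"` or `"space"`.
#' @param positions D x 2 matrix of sample positions (required for
#'   `"space"`): each sample's gradient is assigned to the bin of its true
#'   location.
#' @param arena,bin_cm spatial grid for `"space"`.
#' @return for `"units"`: named vector length N; for `"timesteps"`: vector
#'   length T; for `"space"`: units x bins matrix (NA where no samples), with
#'   the grid attached as attribute `grid`.
#' @export
aggregate_gradients <- function(g, axis = c("units", "timesteps", "space"),
                                positions = NULL, arena = NULL, bin_cm = 10) {
  axis <- match.arg(axis)
  stopifnot(all(is.finite(g)))
  if (axis == "units") return(apply(g, 3, mean))
  if (axis == "timesteps") return(apply(g, 2, mean))
  if (is.null(positions) || is.null(arena))
    stop("axis = 'space' needs sample positions and an arena")
  grid <- bin_grid(arena, bin_cm)
  idx <- bin_index(grid, as.matrix(positions))
  per_sample <- apply(g, c(1, 3), mean)     # D x N mean over timesteps
  out <- matrix(NA_real_, dim(g)[3], nrow(grid$centers))
  for (bn in sort(unique(idx)))
    out[, bn] <- colMeans(per_sample[idx == bn, , drop = FALSE])
  attr(out, "grid") <- grid
  out
}

#' Normalised sensitivity versus normalised firing rate
#'
#' Pools all (sample, timestep, unit) pairs after normalising each unit's
#' spike counts and gradient magnitudes by their own 99th percentiles (the
#' percentile, not the maximum, so a single outlier count in a low-firing
#' unit does not dominate; a few normalised values may exceed 1). The pooled
#' pairs are binned by normalised rate and the mean normalised gradient per
#' bin is returned — the curve typically falls at the highest rates,
#' indicating lower sensitivity near place-field centres.
#'
#' @param counts D x T x N array of input spike counts.
#' @param grads matching [loss_input_gradients()] tensor.
#' @param pct normalisation percentile (99).
#' @param n_bins number of normalised-rate bins on `[0, max]`.
#' @return object of class `sensitivity_curve`: data frame with `rate_bin_lo,
#'   rate_bin_hi, rate_mid, mean_grad, n`; excluded all-zero units recorded
#'   in attribute `excluded_units`.
#' @export
sensitivity_vs_rate_curve <- function(counts, grads, pct = 99, n_bins = 10) {
  stopifnot(all(dim(counts) == dim(grads)))
  N <- dim(counts)[3]
  rate_n <- grad_n <- vector("list", N)
  excluded <- character(0)
  ids <- dimnames(counts)[[3]]
  if (is.null(ids)) ids <- as.character(seq_len(N))
  for (i in seq_len(N)) {
    cv <- as.vector(counts[, , i]); gv <- as.vector(grads[, , i])
    qc <- stats::quantile(cv, pct / 100, names = FALSE)
    qg <- stats::quantile(gv, pct / 100, names = FALSE)
    if (qc <= 0 || all(cv == 0)) { excluded <- c(excluded, ids[i]); next }
    if (qg <= 0) qg <- max(gv, .Machine$double.eps)
    rate_n[[i]] <- cv / qc; grad_n[[i]] <- gv / qg
  }
  r <- unlist(rate_n); g <- unlist(grad_n)
  if (!length(r)) stop("no units with non-zero counts")
  edges <- seq(0, max(r), length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(r, edges, rightmost.closed = TRUE), 1L), n_bins)
  df <- data.frame(rate_bin_lo = edges[-length(edges)], rate_bin_hi = edges[-1])
  df$rate_mid <- (df$rate_bin_lo + df$rate_bin_hi) / 2
  df$mean_grad <- vapply(seq_len(n_bins),
                         function(b) if (any(idx == b)) mean(g[idx == b]) else NA_real_,
                         numeric(1))
  df$n <- tabulate(idx, n_bins)
  structure(df, class = c("sensitivity_curve", "data.frame"),
            excluded_units = excluded)
}

#' Tie-corrected Spearman rank correlation
#'
#' Used to compare unit rankings from different sensitivity measures (e.g.
#' knockout deltas versus mean gradient magnitudes) or against spatial
#' information scores.
#'
#' @param scores_a,scores_b numeric vectors of equal length (>= 3).
#' @return rho in `[-1, 1]`, or `NA` (with a warning) for constant input.
#' @export
rank_correlation <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 3)
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    warning("rank correlation undefined for constant input")
    return(NA_real_)
  }
  stats::cor(scores_a, scores_b, method = "spearman")
}
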