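#' Windowed spike counts
#'
#' Slides half-open windows `[start, start + window_len_s)` across the usable
#' span at a fixed stride and counts each unit's spikes per window. A spike
#' exactly at a window's start boundary is counted; one at the end boundary is
#' not. Windows that would extend past the end of the span are dropped, so
#' consecutive windows overlap by exactly `1 - stride/window_len`.
#'
#' @param spikes a [spike_data()].
#' @param window_len_s window length, seconds (>= stride).
#' @param stride_s shift between consecutive window starts, seconds.
#' @param span length-2 numeric; defaults to the session span.
#' @return object of class `windowed_counts`: list with `counts` (units x
#'   windows integer matrix), `window_centers`, `window_len_s`, `stride_s`,
#'   `unit_ids`.
#' @export
count_in_windows <- function(spikes, window_len_s, stride_s, span = NULL) {
  stopifnot(stride_s > 0, window_len_s >= stride_s)
  if (is.null(span)) span <- spikes$session_span
  if (diff(span) <= 0) stop("empty span")
  if (span[2] - span[1] < window_len_s) stop("span shorter than one window")
  starts <- seq(span[1], span[2] - window_len_s + 1e-9, by = stride_s)
  starts <- starts[starts + window_len_s <= span[2] + 1e-9]
  nw <- length(starts)
  counts <- matrix(0L, n_units(spikes), nw,
                   dimnames = list(spikes$unit_ids, NULL))
  n_lt <- function(times, v) findInterval(v, times, left.open = TRUE)
  for (i in seq_len(n_units(spikes))) {
    t <- spikes$spike_times[[i]]
    if (length(t))
      counts[i, ] <- n_lt(t, starts + window_len_s) - n_lt(t, starts)
  }
  structure(list(counts = counts, window_centers = starts + window_len_s / 2,
                 window_len_s = window_len_s, stride_s = stride_s,
                 unit_ids = spikes$unit_ids),
            class = "windowed_counts")
}

#' @export
print.windowed_counts <- function(x, ...) {
  cat(sprintf("<windowed_counts> %d units x %d windows (len %g s, stride %g s)\n",
              nrow(x$counts), ncol(x$counts), x$window_len_s, x$stride_s))
  invisible(x)
}

#' Build fixed-length input sequences with position targets
#'
#' Packs runs of `seq_len` consecutive spike-count windows into one sample
#' each; the target is the position linearly interpolated at the centre of
#' the sample's last window. Sample `s` covers window indices
#' `(s_last - seq_len + 1):s_last`, so the first possible last-window index is
#' `seq_len` — early windows are not padded. Samples whose target time falls
#' outside the tracked span are dropped (count reported via a message).
#'
#' @param wc a [count_in_windows()] result.
#' @param traj a [trajectory()].
#' @param seq_len windows per sample.
#' @return object of class `sequence_dataset`: `inputs` (samples x seq_len x
#'   units array), `targets` (samples x dims), `sample_to_window` (index of
#'   each sample's last window), `window_centers`, `unit_ids`, `dims`.
#' @export
build_sequences <- function(wc, traj, seq_len) {
  nw <- ncol(wc$counts)
  if (seq_len < 1 || seq_len > nw) stop("seq_len must be in [1, n_windows]")
  last <- seq.int(seq_len, nw)
  tgt_t <- wc$window_centers[last]
  tgt <- interp_position(traj, tgt_t)
  ok <- stats::complete.cases(tgt)
  if (any(!ok)) message(sprintf("dropped %d sample(s) with target outside tracked span", sum(!ok)))
  last <- last[ok]; tgt <- tgt[ok, , drop = FALSE]
  nU <- nrow(wc$counts)
  inputs <- array(0, dim = c(length(last), seq_len, nU),
                  dimnames = list(NULL, NULL, wc$unit_ids))
  tc <- t(wc$counts)  # windows x units, for contiguous slicing
  for (s in seq_along(last))
    inputs[s, , ] <- tc[(last[s] - seq_len + 1):last[s], , drop = FALSE]
  structure(list(inputs = inputs, targets = tgt, sample_to_window = last,
                 window_centers = wc$window_centers, unit_ids = wc$unit_ids,
                 dims = ncol(tgt), seq_len = as.integer(seq_len)),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat(sprintf("<sequence_dataset> %d samples x %d timesteps x %d units -> %dD targets\n",
              dim(x$inputs)[1], dim(x$inputs)[2], dim(x$inputs)[3], x$dims))
  invisible(x)
}

#' Zero one unit's activity
#'
#' Returns a copy of a windowed-count matrix or a sequence dataset with the
#' named unit's counts set to zero everywhere; the input is untouched. This is
#' the transform behind knockout-without-retraining sensitivity analysis.
#'
#' @param data a `windowed_counts` or `sequence_dataset`.
#' @param unit unit id (character) or index.
#' @return object of the same class as `data`.
#' @export
knockout_unit <- function(data, unit) UseMethod("knockout_unit")

resolve_unit <- function(unit_ids, unit) {
  if (is.character(unit)) {
    i <- match(unit, unit_ids)
    if (is.na(i)) stop(sprintf("unknown unit '%s'", unit))
  } else {
    i <- as.integer(unit)
    if (i < 1L || i > length(unit_ids)) stop("unit index out of range")
  }
  i
}

#' @export
knockout_unit.windowed_counts <- function(data, unit) {
  i <- resolve_unit(data$unit_ids, unit)
  data$counts[i, ] <- 0L
  data
}

#' @export
knockout_unit.sequence_dataset <- function(data, unit) {
  i <- resolve_unit(data$unit_ids, unit)
  data$inputs[, , i] <- 0
  data
}

#' Randomly downsample the recorded population
#'
#' Selects `k` units uniformly without replacement (deterministic given
#' `seed`), preserving the original unit order.
#'
#' @param spikes a [spike_data()].
#' @param k subset size, `1 <= k <= N`.
#' @param seed RNG seed for the draw.
#' @return a [spike_data()] with `k` units.
#' @export
downsample_units <- function(spikes, k, seed = 1L) {
  N <- n_units(spikes)
  if (k < 1 || k > N) stop(sprintf("k must be in [1, %d]", N))
  keep <- sort(with_seed(seed, sample.int(N, k)))
  spike_data(spikes$spike_times[keep], session_span = spikes$session_span,
             unit_ids = spikes$unit_ids[keep])
}
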