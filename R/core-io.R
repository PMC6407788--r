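#' Arena descriptors
#'
#' An arena describes the geometry the animal moves in: either a rectangular
#' open-field box (positions are 2D x,y in cm, origin at one corner, x
#' rightward, y upward) or an elevated Z-shaped track (positions are 1D
#' arc-length in cm after linearisation).
#'
#' The default Z-track consists of two parallel 190 cm arms joined by a
#' 220 cm diagonal, giving a 600 cm total run. Default corner coordinates
#' place the arms horizontally; the vertical offset is chosen so the diagonal
#' has exactly the configured length.
#'
#' @param width,height box dimensions in cm.
#' @param segment_lengths ordered segment lengths in cm (three segments).
#' @param corners optional 4 x 2 matrix of segment endpoint coordinates (cm);
#'   derived from `segment_lengths` when `NULL`.
#' @return an object of class `arena` (subclass `arena_box` or
#'   `arena_ztrack`).
#' @export
arena_box <- function(width = 100, height = 100) {
  stopifnot(width > 0, height > 0)
  structure(list(kind = "box2d", width = width, height = height),
            class = c("arena_box", "arena"))
}

#' @rdname arena_box
#' @export
arena_ztrack <- function(segment_lengths = c(190, 220, 190), corners = NULL) {
  if (length(segment_lengths) != 3L || any(segment_lengths <= 0))
    stop("a Z-track needs exactly 3 positive segment lengths")
  if (is.null(corners)) {
    a1 <- segment_lengths[1]; dg <- segment_lengths[2]; a3 <- segment_lengths[3]
    if (dg <= a1) stop("diagonal must be longer than the arm it spans")
    h <- sqrt(dg^2 - a1^2)
    corners <- rbind(c(0, h), c(a1, h), c(0, 0), c(a3, 0))
  }
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(4L, 2L))) stop("corners must be a 4 x 2 matrix")
  seg <- sqrt(rowSums((corners[-1, , drop = FALSE] - corners[-4, , drop = FALSE])^2))
  if (any(seg <= 0)) stop("degenerate (zero-length) track segment")
  structure(list(kind = "ztrack", segment_lengths = seg, corners = corners,
                 total_length = sum(seg)),
            class = c("arena_ztrack", "arena"))
}

#' @export
print.arena <- function(x, ...) {
  if (x$kind == "box2d")
    cat(sprintf("<arena_box> %g x %g cm\n", x$width, x$height))
  else
    cat(sprintf("<arena_ztrack> segments %s cm, total %g cm\n",
                paste(signif(x$segment_lengths, 4), collapse = " + "),
                x$total_length))
  invisible(x)
}

arena_dims <- function(arena) if (arena$kind == "box2d") 2L else 1L

arena_bounds <- function(arena) {
  if (arena$kind == "box2d")
    rbind(c(0, arena$width), c(0, arena$height))
  else
    rbind(c(0, arena$total_length))
}

#' Construct a spike-data object
#'
#' Holds per-unit spike times (seconds, sorted ascending) for one recording
#' session.
#'
#' @param spike_times named list of numeric vectors, one per unit, in seconds.
#' @param session_span length-2 numeric `(t_start, t_end)`; inferred from the
#'   spikes when `NULL`.
#' @param unit_ids unit labels; default the names of `spike_times`.
#' @return object of class `spike_data`.
#' @export
spike_data <- function(spike_times, session_span = NULL, unit_ids = names(spike_times)) {
  if (is.null(unit_ids)) unit_ids <- paste0("u", seq_along(spike_times))
  unit_ids <- as.character(unit_ids)
  if (anyDuplicated(unit_ids)) stop("unit ids must be unique")
  spike_times <- lapply(spike_times, function(t) sort(as.numeric(t)))
  names(spike_times) <- unit_ids
  all_t <- unlist(spike_times, use.names = FALSE)
  if (is.null(session_span)) {
    session_span <- if (length(all_t)) range(all_t) else c(0, 0)
  }
  if (length(all_t) && (min(all_t) < session_span[1] || max(all_t) > session_span[2]))
    stop("spike times fall outside session_span")
  structure(list(unit_ids = unit_ids, spike_times = spike_times,
                 session_span = as.numeric(session_span)),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  n <- vapply(x$spike_times, length, integer(1))
  cat(sprintf("<spike_data> %d units, %d spikes, span [%.2f, %.2f] s\n",
              length(x$unit_ids), sum(n), x$session_span[1], x$session_span[2]))
  invisible(x)
}

n_units <- function(spikes) length(spikes$unit_ids)

#' Construct a trajectory object
#'
#' A tracked position trace: strictly increasing timestamps (nominal 50 Hz)
#' and positions, either 2D (x, y in cm) for a box arena or 1D arc-length (cm)
#' for a linearised track.
#'
#' @param timestamps numeric, seconds, strictly increasing.
#' @param positions numeric matrix (n x 2 or n x 1) or vector, cm.
#' @param arena an [arena_box()] or [arena_ztrack()].
#' @param clamp if `TRUE` (default) positions outside the arena are clamped to
#'   its bounds with a warning; if `FALSE` they are an error.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(timestamps, positions, arena, clamp = TRUE) {
  timestamps <- as.numeric(timestamps)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (nrow(positions) != length(timestamps))
    stop("timestamps and positions must have equal length")
  if (length(timestamps) && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  d <- arena_dims(arena)
  if (ncol(positions) != d)
    stop(sprintf("arena '%s' needs %d position column(s), got %d",
                 arena$kind, d, ncol(positions)))
  b <- arena_bounds(arena)
  n_out <- 0L
  for (j in seq_len(d)) {
    out <- positions[, j] < b[j, 1] | positions[, j] > b[j, 2]
    if (any(out)) {
      if (!clamp) stop(sprintf("%d position(s) outside arena bounds", sum(out)))
      n_out <- n_out + sum(out)
      positions[, j] <- pmin(pmax(positions[, j], b[j, 1]), b[j, 2])
    }
  }
  if (n_out > 0L)
    warning(sprintf("clamped %d out-of-arena coordinate value(s)", n_out))
  dimnames(positions) <- list(NULL, if (d == 2L) c("x", "y") else "s")
  structure(list(timestamps = timestamps, positions = positions, arena = arena),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples over %.1f s (%dD, arena %s)\n",
              length(x$timestamps),
              diff(range(x$timestamps)), ncol(x$positions), x$arena$kind))
  invisible(x)
}

traj_span <- function(traj) range(traj$timestamps)

#' Interpolate a trajectory at arbitrary times
#'
#' Linear interpolation per coordinate. Times outside the tracked span return
#' `NA` rows.
#'
#' @param traj a [trajectory()].
#' @param at numeric times, seconds.
#' @return matrix `length(at)` x dims.
#' @export
interp_position <- function(traj, at) {
  d <- ncol(traj$positions)
  out <- matrix(NA_real_, length(at), d, dimnames = list(NULL, colnames(traj$positions)))
  sp <- traj_span(traj)
  ok <- at >= sp[1] & at <= sp[2]
  for (j in seq_len(d))
    out[ok, j] <- stats::approx(traj$timestamps, traj$positions[, j],
                                xout = at[ok], ties = "ordered")$y
  out
}

#' Run configuration for decoding experiments
#'
#' Collects the tunable parameters shared across the feature, ratemap, decoder
#' and cross-validation stages. Times are given in ms in the argument names
#' (matching the windowing conventions of the decoding literature) but stored
#' in seconds internally.
#'
#' @param window_len_ms spike-count window length; the canonical scan is
#'   200-4000 ms in 200 ms increments.
#' @param stride_ms shift between consecutive windows (200 ms).
#' @param seq_len number of consecutive windows fed to the sequence regressor.
#' @param bin_cm spatial bin side (2 cm).
#' @param smooth_sigma_bins Gaussian smoothing width for ratemaps, in bins.
#' @param n_folds number of blocked cross-validation folds.
#' @param n_repeats independent realizations of the stochastic decoder.
#' @param memory_history continuity-constraint history length, steps.
#' @param memory_scale continuity sigma scale (1 open field, 5 linear track).
#' @param min_sigma_cm floor for the continuity sigma.
#' @param rate_floor_hz floor applied to ratemaps so Poisson log-likelihoods
#'   stay finite.
#' @param rng_seed master seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(window_len_ms = 1400, stride_ms = 200, seq_len = 100,
                       bin_cm = 2, smooth_sigma_bins = 1.5, n_folds = 10,
                       n_repeats = 10, memory_history = 15, memory_scale = 1,
                       min_sigma_cm = 2, rate_floor_hz = 0.01, rng_seed = 1L) {
  stopifnot(window_len_ms >= stride_ms, stride_ms > 0, seq_len >= 1,
            bin_cm > 0, n_folds >= 2, n_repeats >= 1, memory_history >= 1,
            memory_scale > 0, min_sigma_cm > 0, rate_floor_hz >= 0)
  structure(list(window_len_s = window_len_ms / 1000,
                 stride_s = stride_ms / 1000,
                 seq_len = as.integer(seq_len), bin_cm = bin_cm,
                 smooth_sigma_bins = smooth_sigma_bins,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 memory_history = as.integer(memory_history),
                 memory_scale = memory_scale, min_sigma_cm = min_sigma_cm,
                 rate_floor_hz = rate_floor_hz,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read spike times from a delimited table
#'
#' Expects a comma-separated file with a header row and columns `unit_id`,
#' `time_s`. Rows are grouped by unit and times sorted ascending.
#'
#' @param path file path.
#' @param session_span optional override for the session span; inferred as
#'   the spike-time range otherwise.
#' @param strict error (rather than return an empty object) on an empty table.
#' @return a [spike_data()].
#' @export
read_spikes <- function(path, session_span = NULL, strict = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "time_s")
  if (!all(need %in% names(tab)))
    stop(sprintf("spike table must have columns %s", paste(need, collapse = ", ")))
  if (nrow(tab) == 0L) {
    if (strict) stop("spike table is empty")
    return(spike_data(stats::setNames(list(), character()), session_span = session_span))
  }
  t_num <- suppressWarnings(as.numeric(tab$time_s))
  bad <- which(is.na(t_num) & !is.na(tab$time_s))
  if (length(bad))
    stop(sprintf("non-numeric time_s at row %d ('%s')", bad[1], tab$time_s[bad[1]]))
  spl <- split(t_num, as.character(tab$unit_id))
  spike_data(spl, session_span = session_span)
}

#' @rdname read_spikes
#' @param spikes a [spike_data()] to write.
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(
    unit_id = rep(spikes$unit_ids, vapply(spikes$spike_times, length, integer(1))),
    time_s = unlist(spikes$spike_times, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a position trace from a delimited table
#'
#' Expects columns `time_s, x_cm, y_cm` (box arena) or `time_s, s_cm`
#' (linearised track). Duplicate timestamps are dropped (keeping the first
#' occurrence, with a message); decreasing timestamps are an error.
#'
#' @param path file path.
#' @param arena arena descriptor; selects which column set is required.
#' @param clamp clamp out-of-arena positions (default) or reject them.
#' @return a [trajectory()].
#' @export
read_positions <- function(path, arena, clamp = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(tab)) stop("position table must have column time_s")
  d <- arena_dims(arena)
  cols <- if (d == 2L) c("x_cm", "y_cm") else "s_cm"
  if (!all(cols %in% names(tab)))
    stop(sprintf("position table must have columns %s", paste(cols, collapse = ", ")))
  t <- as.numeric(tab$time_s)
  if (any(diff(t) < 0)) stop("timestamps decrease: position table is not time-ordered")
  keep <- !duplicated(t)
  if (any(!keep)) message(sprintf("dropped %d duplicated timestamp(s)", sum(!keep)))
  trajectory(t[keep], as.matrix(tab[keep, cols, drop = FALSE]), arena, clamp = clamp)
}

#' @rdname read_positions
#' @param traj a [trajectory()] to write.
#' @export
write_positions <- function(traj, path) {
  d <- ncol(traj$positions)
  df <- if (d == 2L)
    data.frame(time_s = traj$timestamps, x_cm = traj$positions[, 1],
               y_cm = traj$positions[, 2])
  else
    data.frame(time_s = traj$timestamps, s_cm = traj$positions[, 1])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate a spike/trajectory session pair
#'
#' Checks the temporal overlap of the neural and positional recordings and
#' summarises per-unit firing statistics. Decoding is restricted to the
#' intersection of the two spans.
#'
#' @param spikes a [spike_data()].
#' @param traj a [trajectory()].
#' @return a `session_report` list with elements `usable_span`, `units`
#'   (data frame: unit_id, n_spikes, mean_rate_hz, frac_outside, silent) and
#'   `n_position_samples`.
#' @export
validate_session <- function(spikes, traj) {
  if (length(traj$timestamps) == 0L) stop("trajectory is empty")
  ts <- traj_span(traj)
  lo <- max(spikes$session_span[1], ts[1])
  hi <- min(spikes$session_span[2], ts[2])
  if (hi <= lo) stop("spike and trajectory spans do not overlap")
  dur <- hi - lo
  units <- data.frame(
    unit_id = spikes$unit_ids,
    n_spikes = vapply(spikes$spike_times, length, integer(1)),
    stringsAsFactors = FALSE)
  units$n_inside <- vapply(spikes$spike_times,
                           function(t) sum(t >= lo & t <= hi), integer(1))
  units$mean_rate_hz <- units$n_inside / dur
  units$frac_outside <- ifelse(units$n_spikes > 0,
                               1 - units$n_inside / units$n_spikes, 0)
  units$silent <- units$n_spikes == 0L
  rownames(units) <- NULL
  structure(list(usable_span = c(lo, hi), units = units,
                 n_position_samples = length(traj$timestamps)),
            class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> usable span [%.2f, %.2f] s; %d units (%d silent); %d position samples\n",
              x$usable_span[1], x$usable_span[2], nrow(x$units),
              sum(x$units$silent), x$n_position_samples))
  invisible(x)
}
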