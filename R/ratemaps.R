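#' Spatial bin grid for an arena
#'
#' Square bins of side `bin_cm` for a box arena (bins ordered x-fastest), or
#' `bin_cm` arc-length segments for a linearised track.
#'
#' @param arena arena descriptor.
#' @param bin_cm bin side, cm.
#' @return list with `centers` (nbins x dims matrix), `nx`, `ny` (2D only),
#'   `bin_cm`, `dims`.
#' @export
bin_grid <- function(arena, bin_cm = 2) {
  b <- arena_bounds(arena)
  if (arena$kind == "box2d") {
    nx <- ceiling(arena$width / bin_cm); ny <- ceiling(arena$height / bin_cm)
    cx <- (seq_len(nx) - 0.5) * bin_cm
    cy <- (seq_len(ny) - 0.5) * bin_cm
    centers <- cbind(x = rep(cx, times = ny), y = rep(cy, each = nx))
    list(centers = centers, nx = nx, ny = ny, bin_cm = bin_cm, dims = 2L)
  } else {
    nb <- ceiling(arena$total_length / bin_cm)
    centers <- cbind(s = (seq_len(nb) - 0.5) * bin_cm)
    list(centers = centers, nx = nb, ny = 1L, bin_cm = bin_cm, dims = 1L)
  }
}

# linear bin index for positions (n x dims) on a grid; clamped to the grid
bin_index <- function(grid, pos) {
  ix <- pmin(pmax(floor(pos[, 1] / grid$bin_cm) + 1L, 1L), grid$nx)
  if (grid$dims == 2L) {
    iy <- pmin(pmax(floor(pos[, 2] / grid$bin_cm) + 1L, 1L), grid$ny)
    ix + (iy - 1L) * grid$nx
  } else ix
}

# Mass-conserving truncated-Gaussian smoothing on a (possibly masked) grid.
# Each source bin's kernel is renormalised over the visited bins it reaches,
# so the total over visited bins is preserved exactly.
smooth_masked <- function(values, mask, grid, sigma_bins) {
  if (sigma_bins <= 0) return(values)
  r <- ceiling(4 * sigma_bins)
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma_bins^2))
  conv <- function(v) {
    if (grid$dims == 2L) {
      m <- matrix(v, grid$nx, grid$ny)
      out <- matrix(0, grid$nx, grid$ny)
      for (a in off) for (b in off) {
        if (abs(a) >= grid$nx || abs(b) >= grid$ny) next
        w <- k1[a + r + 1] * k1[b + r + 1]
        xs <- max(1, 1 - a):min(grid$nx, grid$nx - a)
        ys <- max(1, 1 - b):min(grid$ny, grid$ny - b)
        out[xs + a, ys + b] <- out[xs + a, ys + b] + w * m[xs, ys]
      }
      as.vector(out)
    } else {
      out <- numeric(grid$nx)
      for (a in off) {
        if (abs(a) >= grid$nx) next
        xs <- max(1, 1 - a):min(grid$nx, grid$nx - a)
        out[xs + a] <- out[xs + a] + k1[a + r + 1] * v[xs]
      }
      out
    }
  }
  w_reach <- conv(as.numeric(mask))        # kernel mass each source keeps
  u <- ifelse(mask & w_reach > 0, values / w_reach, 0)
  out <- conv(u)
  out[!mask] <- NA_real_
  out
}

#' Spatial occupancy
#'
#' Dwell seconds per spatial bin: each tracking sample contributes its
#' inter-sample interval (the forward difference; the last sample contributes
#' the median interval) to the bin containing it.
#'
#' Tracking gaps (intervals much longer than the nominal one, e.g. across a
#' removed validation block) are capped at `max_gap_factor` times the median
#' interval so one sample cannot absorb the gap as dwell time.
#'
#' @param traj a [trajectory()].
#' @param bin_cm bin side, cm.
#' @param max_gap_factor cap on an interval, in units of the median interval.
#' @return list with `occupancy_s` (vector over bins) and the `grid`.
#' @export
compute_occupancy <- function(traj, bin_cm = 2, max_gap_factor = 5) {
  if (length(traj$timestamps) == 0L) stop("empty trajectory")
  grid <- bin_grid(traj$arena, bin_cm)
  dts <- diff(traj$timestamps)
  dt_last <- if (length(dts)) stats::median(dts) else 0
  if (length(dts)) dts <- pmin(dts, max_gap_factor * dt_last)
  w <- c(dts, dt_last)
  idx <- bin_index(grid, traj$positions)
  occ <- numeric(nrow(grid$centers))
  tab <- rowsum(w, idx)
  occ[as.integer(rownames(tab))] <- tab[, 1]
  list(occupancy_s = occ, grid = grid)
}

#' Smoothed per-unit firing-rate maps
#'
#' The canonical ratemap construction: spikes are assigned to the bin of the
#' position interpolated at spike time, dwell time is binned the same way,
#' both maps are smoothed with a truncated Gaussian kernel (default sigma
#' 1.5 bins, radius 4 sigma, renormalised over visited bins) and the rate is
#' the ratio smoothed-spikes / smoothed-dwell, floored at `rate_floor_hz` so
#' Poisson likelihoods stay finite. Bins never visited (zero raw dwell) are
#' masked and excluded from decoding.
#'
#' @param spikes a [spike_data()].
#' @param traj a [trajectory()].
#' @param bin_cm bin side, cm.
#' @param sigma_bins Gaussian smoothing width in bins (0 disables smoothing).
#' @param rate_floor_hz minimum rate on visited bins.
#' @param span restrict to this time span (default: intersection of spike and
#'   trajectory spans).
#' @return object of class `ratemap_set`: `rate_hz` (units x bins, NA off the
#'   visited mask), `occupancy_s`, `visited`, `grid`, `unit_ids`.
#' @export
compute_ratemaps <- function(spikes, traj, bin_cm = 2, sigma_bins = 1.5,
                             rate_floor_hz = 0.01, span = NULL) {
  if (is.null(span)) span <- validate_session(spikes, traj)$usable_span
  keep <- traj$timestamps >= span[1] & traj$timestamps <= span[2]
  if (!any(keep)) stop("no tracking samples inside span")
  tr <- traj
  tr$timestamps <- traj$timestamps[keep]
  tr$positions <- traj$positions[keep, , drop = FALSE]
  occ <- compute_occupancy(tr, bin_cm)
  grid <- occ$grid
  visited <- occ$occupancy_s > 0
  sm_occ <- smooth_masked(occ$occupancy_s, visited, grid, sigma_bins)
  nb <- nrow(grid$centers)
  rate <- matrix(NA_real_, n_units(spikes), nb,
                 dimnames = list(spikes$unit_ids, NULL))
  for (i in seq_len(n_units(spikes))) {
    t <- spikes$spike_times[[i]]
    t <- t[t >= span[1] & t <= span[2]]
    smap <- numeric(nb)
    if (length(t)) {
      pos <- interp_position(tr, t)
      ok <- stats::complete.cases(pos)
      if (length(t) && !any(ok))
        warning(sprintf("unit %s: all spikes outside tracked span; all-floor map",
                        spikes$unit_ids[i]))
      if (any(ok)) {
        idx <- bin_index(grid, pos[ok, , drop = FALSE])
        tab <- rowsum(rep(1, sum(ok)), idx)
        smap[as.integer(rownames(tab))] <- tab[, 1]
      }
    }
    sm_spk <- smooth_masked(smap, visited, grid, sigma_bins)
    r <- ifelse(visited, pmax(sm_spk / pmax(sm_occ, .Machine$double.eps),
                              rate_floor_hz), NA_real_)
    rate[i, ] <- r
  }
  structure(list(rate_hz = rate, occupancy_s = occ$occupancy_s,
                 visited = visited, grid = grid, unit_ids = spikes$unit_ids,
                 sigma_bins = sigma_bins, rate_floor_hz = rate_floor_hz),
            class = "ratemap_set")
}

#' @export
print.ratemap_set <- function(x, ...) {
  cat(sprintf("<ratemap_set> %d units on %d bins (%d visited), %g cm bins, sigma %g bins\n",
              nrow(x$rate_hz), ncol(x$rate_hz), sum(x$visited),
              x$grid$bin_cm, x$sigma_bins))
  invisible(x)
}

#' Occupancy prior over visited bins
#'
#' Normalised dwell time: the probability of the animal being in each visited
#' bin, estimated directly from the behavioural data. `mode` records whether
#' the occupancy came from the full trial or from training data only (the
#' leakage-safe default used by the cross-validation driver).
#'
#' @param occupancy_s dwell seconds per bin (e.g. from [compute_occupancy()]
#'   or a [compute_ratemaps()] result).
#' @param mode provenance label, `"train_only"` or `"full_trial"`.
#' @return object of class `occupancy_prior`: `prob` (sums to 1 over visited
#'   bins, zero elsewhere), `visited`, `mode`.
#' @export
occupancy_prior <- function(occupancy_s, mode = c("train_only", "full_trial")) {
  mode <- match.arg(mode)
  tot <- sum(occupancy_s)
  if (tot <= 0) stop("all-zero occupancy")
  structure(list(prob = occupancy_s / tot, visited = occupancy_s > 0,
                 mode = mode),
            class = "occupancy_prior")
}

#' Skaggs spatial information (bits per spike)
#'
#' The classical spatial information score from the place-field literature
#' (defined in the cited literature, not re-derived here):
#' `sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)` with
#' `lambda_bar = sum_i p_i lambda_i`, where `p_i` is the occupancy
#' probability of bin i and `lambda_i` the unit's firing rate there.
#'
#' @param rate_map rates per bin (Hz); NA bins ignored.
#' @param occupancy_s dwell seconds per bin (same length).
#' @return bits per spike (>= 0), or `NA` for a silent unit.
#' @export
skaggs_information <- function(rate_map, occupancy_s) {
  stopifnot(length(rate_map) == length(occupancy_s))
  ok <- !is.na(rate_map) & occupancy_s > 0
  p <- occupancy_s[ok] / sum(occupancy_s[ok])
  lam <- rate_map[ok]
  lbar <- sum(p * lam)
  if (lbar <= 0) return(NA_real_)
  term <- ifelse(lam > 0, p * (lam / lbar) * log2(lam / lbar), 0)
  max(sum(term), 0)
}
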