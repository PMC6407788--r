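#' Simulation configuration
#'
#' Parameters of the synthetic place-cell session generator. Defaults mirror
#' a typical ~20-minute single-animal recording: a few tens of simultaneously
#' held place cells plus a small number of high-rate, weakly tuned
#' interneuron-like units, tracked at 50 Hz.
#'
#' @param n_place_units number of place cells.
#' @param n_interneurons number of interneuron-like units.
#' @param duration_s session length, seconds.
#' @param sample_rate_hz tracking rate (50 Hz).
#' @param mean_speed_cm_s target mean running speed.
#' @param speed_sd_cm_s speed jitter (Z-track running); 0 gives constant speed.
#' @param pause_prob open field: per-second probability of initiating a
#'   stationary pause; Z-track: probability of dwelling at each corner/end.
#' @param pause_mean_s mean pause duration (exponential).
#' @param overdispersion_k gamma shape of the per-second rate multiplier;
#'   `Inf` gives pure Poisson spiking, finite k gives Fano factors above 1.
#' @param rng_seed master seed; all outputs are pure functions of
#'   (config, seed).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_place_units = 40, n_interneurons = 3,
                       duration_s = 1200, sample_rate_hz = 50,
                       mean_speed_cm_s = 15, speed_sd_cm_s = 3,
                       pause_prob = 0.05, pause_mean_s = 1.5,
                       overdispersion_k = 3, rng_seed = 1L) {
  stopifnot(n_place_units >= 0, n_interneurons >= 0, duration_s > 0,
            sample_rate_hz > 0, mean_speed_cm_s > 0, speed_sd_cm_s >= 0,
            pause_prob >= 0, pause_prob <= 1, pause_mean_s > 0,
            overdispersion_k > 0)
  structure(list(n_place_units = as.integer(n_place_units),
                 n_interneurons = as.integer(n_interneurons),
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 mean_speed_cm_s = mean_speed_cm_s,
                 speed_sd_cm_s = speed_sd_cm_s,
                 pause_prob = pause_prob, pause_mean_s = pause_mean_s,
                 overdispersion_k = overdispersion_k,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# deterministic child seed from a master seed, kept below 2^31
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 9973) %% 2147483629
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an open-field foraging trajectory
#'
#' Heading-persistent random walk: an Ornstein-Uhlenbeck velocity process
#' (relaxation time 1 s) whose stationary speed distribution has the
#' configured mean, integrated at the tracking rate, reflected at the walls,
#' and interrupted by stationary pauses.
#'
#' @param cfg a [sim_config()].
#' @param arena an [arena_box()].
#' @return a [trajectory()] with `duration_s * sample_rate_hz` samples.
#' @export
simulate_trajectory_2d <- function(cfg, arena) {
  if (arena$kind != "box2d") stop("simulate_trajectory_2d needs a box arena")
  n <- round(cfg$duration_s * cfg$sample_rate_hz)
  dt <- 1 / cfg$sample_rate_hz
  tau <- 1                                   # velocity relaxation time, s
  sigma_v <- cfg$mean_speed_cm_s / sqrt(pi / 2)  # Rayleigh mean -> per-axis sd
  a <- exp(-dt / tau)
  b <- sigma_v * sqrt(1 - a^2)
  with_seed(child_seed(cfg$rng_seed, 1), {
    pos <- matrix(0, n, 2)
    p <- c(arena$width, arena$height) / 2
    v <- stats::rnorm(2, 0, sigma_v)
    pause_left <- 0
    lims <- c(arena$width, arena$height)
    for (k in seq_len(n)) {
      if (pause_left > 0) {
        pause_left <- pause_left - dt
      } else {
        if (stats::runif(1) < cfg$pause_prob * dt) {
          pause_left <- stats::rexp(1, 1 / cfg$pause_mean_s)
        } else {
          v <- a * v + b * stats::rnorm(2)
          p <- p + v * dt
          for (j in 1:2) {       # reflect at walls, flip that velocity axis
            if (p[j] < 0) { p[j] <- -p[j]; v[j] <- -v[j] }
            if (p[j] > lims[j]) { p[j] <- 2 * lims[j] - p[j]; v[j] <- -v[j] }
            p[j] <- min(max(p[j], 0), lims[j])
          }
        }
      }
      pos[k, ] <- p
    }
    trajectory(seq_len(n) * dt, pos, arena)
  })
}

#' Simulate Z-track lap running
#'
#' Back-and-forth laps along the track arc-length, at a jittered running
#' speed, with reward dwells at the two corners and the track ends. Positions
#' are returned as 1D arc-length (cm).
#'
#' @param cfg a [sim_config()].
#' @param arena an [arena_ztrack()].
#' @return a [trajectory()] with 1D positions in `[0, total_length]`.
#' @export
simulate_trajectory_z <- function(cfg, arena) {
  if (arena$kind != "ztrack") stop("simulate_trajectory_z needs a ztrack arena")
  n <- round(cfg$duration_s * cfg$sample_rate_hz)
  dt <- 1 / cfg$sample_rate_hz
  L <- arena$total_length
  stops <- cumsum(arena$segment_lengths)[1:2]  # corner arc positions
  with_seed(child_seed(cfg$rng_seed, 2), {
    s <- numeric(n)
    pos <- 0; dir <- 1; pause_left <- 0
    speed <- cfg$mean_speed_cm_s
    for (k in seq_len(n)) {
      if (pause_left > 0) {
        pause_left <- pause_left - dt
      } else {
        if (cfg$speed_sd_cm_s > 0) {
          speed <- speed + (cfg$mean_speed_cm_s - speed) * dt +
            cfg$speed_sd_cm_s * sqrt(2 * dt) * stats::rnorm(1)
          speed <- max(speed, 1)
        }
        old <- pos
        pos <- pos + dir * speed * dt
        if (pos >= L) { pos <- L; dir <- -1 }
        if (pos <= 0) { pos <- 0; dir <- 1 }
        at_end <- pos %in% c(0, L) && old != pos
        crossed <- any((old - stops) * (pos - stops) < 0)
        if ((at_end || crossed) && cfg$pause_prob > 0 &&
            stats::runif(1) < cfg$pause_prob)
          pause_left <- stats::rexp(1, 1 / cfg$pause_mean_s)
      }
      s[k] <- pos
    }
    trajectory(seq_len(n) * dt, matrix(s, ncol = 1), arena)
  })
}

#' Draw a synthetic tuning set
#'
#' Place cells get Gaussian spatial tuning: centers uniform over the arena,
#' field widths sigma ~ U(6, 14) cm, peak rates ~ U(5, 20) Hz and baselines
#' ~ U(0.05, 0.5) Hz — typical dorsal CA1 values. Interneuron-like units get
#' a high spatially flat rate (~4x a typical place-cell peak) with only weak
#' residual modulation.
#'
#' @param cfg a [sim_config()].
#' @param arena arena descriptor; centers are drawn in its coordinates.
#' @param seed optional seed override (default derived from `cfg$rng_seed`).
#' @return a `tuning_set` data frame with columns `unit_id, unit_class,
#'   center_x, center_y` (`center_s` for 1D), `sigma_cm, peak_hz, baseline_hz`.
#' @export
make_tuning_set <- function(cfg, arena, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(cfg$rng_seed, 3)
  d <- arena_dims(arena)
  b <- arena_bounds(arena)
  np <- cfg$n_place_units; ni <- cfg$n_interneurons
  with_seed(seed, {
    n <- np + ni
    centers <- matrix(0, n, d)
    for (j in seq_len(d)) centers[, j] <- stats::runif(n, b[j, 1], b[j, 2])
    sigma <- c(stats::runif(np, 6, 14), stats::runif(ni, 60, 80))
    peak <- c(stats::runif(np, 5, 20), numeric(ni))
    base <- c(stats::runif(np, 0.05, 0.5), stats::runif(ni, 30, 60))
    if (ni > 0) peak[np + seq_len(ni)] <- base[np + seq_len(ni)] * 1.1
    df <- data.frame(
      unit_id = sprintf("u%02d", seq_len(n)),
      unit_class = rep(c("place", "interneuron"), c(np, ni)),
      stringsAsFactors = FALSE)
    if (d == 2L) { df$center_x <- centers[, 1]; df$center_y <- centers[, 2] }
    else df$center_s <- centers[, 1]
    df$sigma_cm <- sigma; df$peak_hz <- peak; df$baseline_hz <- base
    class(df) <- c("tuning_set", "data.frame")
    df
  })
}

tuning_centers <- function(tuning) {
  cols <- intersect(c("center_x", "center_y", "center_s"), names(tuning))
  as.matrix(tuning[, cols, drop = FALSE])
}

# instantaneous rate of every unit at given positions (n x d matrix)
tuning_rate_at <- function(tuning, pos) {
  centers <- tuning_centers(tuning)
  n <- nrow(pos)
  rate <- matrix(0, nrow(tuning), n)
  for (i in seq_len(nrow(tuning))) {
    d2 <- rowSums((pos - matrix(centers[i, ], n, ncol(pos), byrow = TRUE))^2)
    rate[i, ] <- tuning$baseline_hz[i] +
      (tuning$peak_hz[i] - tuning$baseline_hz[i]) *
      exp(-d2 / (2 * tuning$sigma_cm[i]^2))
  }
  rate
}

#' Generate spikes from a tuning set and a trajectory
#'
#' Each unit fires as an inhomogeneous Poisson process with rate
#' `baseline + (peak - baseline) * exp(-||pos(t) - center||^2 / (2 sigma^2))`,
#' realised by thinning a homogeneous process at the unit's rate bound. With
#' finite `overdispersion_k` the rate is additionally multiplied, per 1-second
#' block, by an i.i.d. gamma(k, scale 1/k) variate (mean 1, variance 1/k),
#' producing the super-Poisson count variability seen in place-cell data.
#'
#' @param tuning a [make_tuning_set()] result.
#' @param traj a [trajectory()] over the same arena kind.
#' @param cfg a [sim_config()].
#' @return a [spike_data()] spanning the trajectory's time range.
#' @export
generate_spikes <- function(tuning, traj, cfg) {
  d <- ncol(traj$positions)
  if (ncol(tuning_centers(tuning)) != d)
    stop("tuning set and trajectory disagree on arena dimensionality")
  sp <- traj_span(traj)
  dur <- sp[2] - sp[1]
  n_blocks <- max(1L, ceiling(dur))
  with_seed(child_seed(cfg$rng_seed, 4), {
    spikes <- vector("list", nrow(tuning))
    for (i in seq_len(nrow(tuning))) {
      mult <- if (is.finite(cfg$overdispersion_k))
        stats::rgamma(n_blocks, shape = cfg$overdispersion_k,
                      scale = 1 / cfg$overdispersion_k)
      else rep(1, n_blocks)
      lam_max <- max(tuning$peak_hz[i], tuning$baseline_hz[i]) * max(mult)
      if (lam_max <= 0) { spikes[[i]] <- numeric(0); next }
      n_cand <- stats::rpois(1, lam_max * dur)
      if (n_cand == 0L) { spikes[[i]] <- numeric(0); next }
      t_cand <- sort(stats::runif(n_cand, sp[1], sp[2]))
      pos <- interp_position(traj, t_cand)
      lam <- tuning_rate_at(tuning[i, , drop = FALSE], pos)[1, ]
      blk <- pmin(floor(t_cand - sp[1]) + 1L, n_blocks)
      lam <- lam * mult[blk]
      keep <- stats::runif(n_cand) < lam / lam_max
      spikes[[i]] <- t_cand[keep]
    }
    names(spikes) <- tuning$unit_id
    spike_data(spikes, session_span = sp)
  })
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper: trajectory, tuning set and spikes in one call. The
#' default configuration (40 place cells + 3 interneurons, 1200 s, open
#' field) is the package's standard synthetic benchmark.
#'
#' @param cfg a [sim_config()].
#' @param arena arena descriptor (default 1 m x 1 m box).
#' @return list with elements `spikes`, `traj`, `tuning`, `cfg`, `arena`.
#' @export
simulate_session <- function(cfg = sim_config(), arena = arena_box()) {
  traj <- if (arena$kind == "box2d") simulate_trajectory_2d(cfg, arena)
          else simulate_trajectory_z(cfg, arena)
  tuning <- make_tuning_set(cfg, arena)
  spikes <- generate_spikes(tuning, traj, cfg)
  list(spikes = spikes, traj = traj, tuning = tuning, cfg = cfg, arena = arena)
}
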