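test_that("open-field trajectories have the right length, bounds and determinism", {
  cfg <- sim_config(duration_s = 60, rng_seed = 3)
  box <- arena_box()
  tr <- simulate_trajectory_2d(cfg, box)
  expect_equal(length(tr$timestamps), 3000L)          # 60 s at 50 Hz
  expect_true(all(tr$positions >= 0 & tr$positions <= 100))
  tr2 <- simulate_trajectory_2d(cfg, box)
  expect_identical(tr$positions, tr2$positions)
  tr3 <- simulate_trajectory_2d(sim_config(duration_s = 60, rng_seed = 4), box)
  expect_false(identical(tr$positions, tr3$positions))
})

test_that("open-field running speed matches the configured mean", {
  cfg <- sim_config(duration_s = 600, mean_speed_cm_s = 15, rng_seed = 5)
  tr <- simulate_trajectory_2d(cfg, arena_box())
  sp <- speed_at(tr, seq(5, 595, by = 0.5))
  moving <- sp[!is.na(sp) & sp > 0.5]
  expect_lt(abs(mean(moving) - 15) / 15, 0.10)
})

test_that("Z-track laps stay on the track and have the kinematic lap time", {
  zt <- arena_ztrack()
  cfg <- sim_config(duration_s = 300, mean_speed_cm_s = 20,
                    speed_sd_cm_s = 0, pause_prob = 0, rng_seed = 6)
  tr <- simulate_trajectory_z(cfg, zt)
  expect_true(all(tr$positions >= 0 & tr$positions <= 600))
  # constant speed v, no pauses: full out-and-back lap takes ~ 2 * 600 / v
  ends <- which(tr$positions[, 1] == 0)
  gaps <- diff(tr$timestamps[ends[c(1, diff(ends)) > 1]])
  expect_lt(abs(mean(gaps) - 2 * 600 / 20) / (2 * 600 / 20), 0.05)
  tr2 <- simulate_trajectory_z(cfg, zt)
  expect_identical(tr$positions, tr2$positions)
})

test_that("tuning sets respect class structure and arena bounds", {
  cfg <- sim_config(n_place_units = 12, n_interneurons = 2, rng_seed = 8)
  tun <- make_tuning_set(cfg, arena_box())
  expect_equal(nrow(tun), 14L)
  expect_equal(sum(tun$unit_class == "interneuron"), 2L)
  expect_true(all(tun$center_x >= 0 & tun$center_x <= 100))
  expect_true(all(tun$center_y >= 0 & tun$center_y <= 100))
  expect_true(all(tun$peak_hz >= tun$baseline_hz - 1e-12 |
                    tun$unit_class == "interneuron"))
  expect_true(all(tun$sigma_cm > 0))
  # interneurons fire far above place-cell peaks
  expect_gt(min(tun$baseline_hz[tun$unit_class == "interneuron"]),
            max(tun$peak_hz[tun$unit_class == "place"]))
  expect_identical(make_tuning_set(cfg, arena_box()), tun)
  empty <- make_tuning_set(sim_config(n_place_units = 0, n_interneurons = 0),
                           arena_box())
  expect_equal(nrow(empty), 0L)
})

test_that("spike generation matches Poisson expectations", {
  box <- arena_box()
  cfg <- sim_config(duration_s = 100, overdispersion_k = Inf, rng_seed = 9)
  tr <- simulate_trajectory_2d(cfg, box)
  # constant 10 Hz unit: a flat tuning curve (peak = baseline)
  tun <- data.frame(unit_id = "flat", unit_class = "place",
                    center_x = 50, center_y = 50, sigma_cm = 10,
                    peak_hz = 10, baseline_hz = 10)
  counts <- vapply(1:30, function(s) {
    cfg_s <- sim_config(duration_s = 100, overdispersion_k = Inf, rng_seed = s)
    length(generate_spikes(tun, tr, cfg_s)$spike_times$flat)
  }, numeric(1))
  # N(1000, sqrt(1000)): essentially all draws inside 3 sigma
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))

  # zero-rate units emit nothing
  tun0 <- tun; tun0$peak_hz <- 0; tun0$baseline_hz <- 0
  expect_length(generate_spikes(tun0, tr, cfg)$spike_times$flat, 0L)
})

test_that("gamma rate mixing produces super-Poisson count variability", {
  box <- arena_box()
  cfg <- sim_config(duration_s = 400, overdispersion_k = 2, rng_seed = 10)
  tr <- simulate_trajectory_2d(cfg, box)
  tun <- data.frame(unit_id = "flat", unit_class = "place",
                    center_x = 50, center_y = 50, sigma_cm = 10,
                    peak_hz = 8, baseline_hz = 8)
  sp <- generate_spikes(tun, tr, cfg)
  wc <- count_in_windows(sp, 1, 1, span = c(0, 400))
  k <- as.numeric(wc$counts)
  fano <- stats::var(k) / mean(k)
  # gamma(k = 2) mixture: expected Fano 1 + mean/k = 1 + 4 = 5
  expect_gt(fano, 1.5)

  sp_p <- generate_spikes(tun, tr,
                          sim_config(duration_s = 400, overdispersion_k = Inf,
                                     rng_seed = 10))
  kp <- as.numeric(count_in_windows(sp_p, 1, 1, span = c(0, 400))$counts)
  expect_lt(stats::var(kp) / mean(kp), fano)
})

test_that("a full session is a pure function of config and seed", {
  s1 <- small_session(duration_s = 60, seed = 12)
  s2 <- small_session(duration_s = 60, seed = 12)
  expect_identical(s1$spikes$spike_times, s2$spikes$spike_times)
  expect_identical(s1$traj$positions, s2$traj$positions)
  expect_identical(s1$tuning, s2$tuning)
})
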