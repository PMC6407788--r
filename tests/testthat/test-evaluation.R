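test_that("blocked folds discard exactly the border samples that share windows", {
  folds <- blocked_folds(4000, k = 10, seq_len = 100)
  expect_length(folds, 10L)
  retained <- vapply(folds, function(f) length(f$val_idx), integer(1))
  expect_equal(retained, c(301L, rep(202L, 8), 301L))
  # exhaustive pairwise span-overlap oracle: samples i, j share a window
  # iff |i - j| < seq_len
  for (f in folds[c(1, 5, 10)]) {
    dmin <- vapply(f$val_idx, function(v) min(abs(v - f$train_idx)), numeric(1))
    expect_true(all(dmin >= 100))
    if (length(f$discarded_idx)) {
      ddisc <- vapply(f$discarded_idx, function(v) min(abs(v - f$train_idx)),
                      numeric(1))
      expect_true(all(ddisc < 100))
    }
    expect_equal(sort(c(f$val_idx, f$discarded_idx, f$train_idx)),
                 seq_len(4000))
  }
})

test_that("seq_len = 1 keeps every sample; short blocks can empty a fold", {
  folds <- blocked_folds(1000, k = 10, seq_len = 1)
  expect_equal(vapply(folds, function(f) length(f$val_idx), integer(1)),
               rep(100L, 10))
  expect_true(all(vapply(folds, function(f) length(f$discarded_idx) == 0L,
                         logical(1))))
  w <- capture_warnings(folds2 <- blocked_folds(1000, k = 10, seq_len = 100))
  expect_length(w, 8)                    # one per emptied interior fold
  expect_true(all(grepl("retains no validation samples", w)))
  inner <- vapply(folds2[2:9], function(f) length(f$val_idx), integer(1))
  expect_equal(inner, rep(0L, 8))
})

test_that("error metrics match hand calculations and a re-computation oracle", {
  e <- compute_errors(rbind(c(3, 4), c(0, 0)), rbind(c(0, 0), c(0, 0)))
  expect_equal(e$table$err, c(5, 0))
  expect_equal(e$med, 2.5)
  expect_equal(e$median_err, 2.5)

  ident <- compute_errors(cbind(1:5, 6:10), cbind(1:5, 6:10))
  expect_equal(ident$med, 0)

  set.seed(70)
  pred <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  truth <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  e2 <- compute_errors(pred, truth)
  oracle <- sqrt((pred[, 1] - truth[, 1])^2 + (pred[, 2] - truth[, 2])^2)
  expect_equal(e2$table$err, oracle, tolerance = 1e-12)
  expect_equal(e2$med, mean(oracle), tolerance = 1e-12)
  expect_equal(e2$median_err, median(oracle), tolerance = 1e-12)
  expect_equal(e2$table$err_x, abs(pred[, 1] - truth[, 1]), tolerance = 1e-12)
  expect_equal(e2$table$err, sqrt(e2$table$err_x^2 + e2$table$err_y^2),
               tolerance = 1e-12)

  # bin mode: both positions snap to 2 cm bin centres
  e3 <- compute_errors(rbind(c(0.5, 0.5)), rbind(c(1.0, 1.0)), mode = "bin2d")
  expect_equal(e3$med, 0)                       # same bin, centre (1, 1)
  e4 <- compute_errors(rbind(c(2.1, 1.0)), rbind(c(1.0, 1.0)), mode = "bin2d")
  expect_equal(e4$med, 2)                       # adjacent bin centres

  s1 <- compute_errors(cbind(c(10, 20)), cbind(c(12, 26)), mode = "1d")
  expect_equal(s1$table$err, c(2, 6))
  expect_error(compute_errors(cbind(1:3, 1:3), cbind(1:2, 1:2)), "identical")
})

test_that("error histograms bin at 2 cm with an overflow bucket", {
  h <- error_histogram(c(1, 3, 55))
  expect_equal(unname(h[c("[0,2)", "[2,4)", ">50")]), c(1L, 1L, 1L))
  expect_equal(sum(h), 3L)
  set.seed(71)
  e <- rexp(500, 1 / 15)
  expect_equal(sum(error_histogram(e)), 500L)
  h0 <- error_histogram(rep(0, 7))
  expect_equal(unname(h0["[0,2)"]), 7L)
})

test_that("Z-track linearisation projects to arc length", {
  zt <- arena_ztrack()
  # the arm1/diagonal corner sits at arc length 190; the far end at 600
  expect_equal(linearize_z(rbind(zt$corners[2, ]), zt), 190)
  expect_equal(linearize_z(rbind(zt$corners[4, ]), zt), 600)
  expect_equal(linearize_z(rbind(zt$corners[1, ]), zt), 0)
  # 5 cm lateral offset from arm1 at 100 cm along: still 100
  p <- zt$corners[1, ] + c(100, 5)
  expect_equal(linearize_z(rbind(p), zt), 100)
  # projection is idempotent for on-track points
  on_track <- zt$corners[3, ] + 0.4 * (zt$corners[4, ] - zt$corners[3, ])
  s <- linearize_z(rbind(on_track), zt)
  expect_equal(s, 190 + 220 + 0.4 * 190, tolerance = 1e-9)
  expect_error(linearize_z(rbind(c(0, 0)),
                           arena_ztrack(corners = rbind(c(0, 0), c(0, 0),
                                                        c(1, 0), c(2, 0)))),
               "degenerate")
})

test_that("covariate analysis recovers engineered correlations", {
  n <- 60
  set.seed(72)
  errtab <- data.frame(true_x = runif(n, 0, 100), true_y = runif(n, 0, 100),
                       pred_x = runif(n, 0, 100), pred_y = runif(n, 0, 100))
  errtab$err <- seq(1, 10, length.out = n)
  errtab$err_x <- errtab$err / 2; errtab$err_y <- errtab$err / 2
  errtab$pop_count <- -errtab$err           # perfectly anti-aligned
  errtab$speed <- c(rep(0.1, 10), rep(5, 40), rep(20, 10))
  res <- covariate_analysis(errtab, train_positions = NULL, arena = arena_box())
  rho_pop <- res$correlations$rho[res$correlations$covariate ==
                                    "summed_population_count"]
  expect_equal(rho_pop, -1)
  expect_equal(unname(unlist(res$speed_classes$n)), c(10, 40, 10))
  expect_true(all(c("stationary_vs_moving", "moving_vs_fast") %in%
                    names(res$speed_tests)))

  # wall-distance bookkeeping: point (10, 50) is 10 cm from the x wall
  wx <- pmin(errtab$true_x, 100 - errtab$true_x)
  expect_equal(min(pmin(c(10), 100 - 10)), 10)  # arithmetic sanity
  errtab2 <- errtab
  errtab2$true_x <- seq(1, 24, length.out = n)  # all near the x wall
  errtab2$err_x <- errtab2$true_x               # perfectly rank-aligned
  res2 <- covariate_analysis(errtab2, NULL, arena_box())
  rho_wx <- res2$correlations$rho[res2$correlations$covariate ==
                                    "wall_distance_x"]
  expect_equal(rho_wx, 1)

  # constant error: correlations undefined, flagged NA
  errtab$err[] <- 4; errtab$err_x[] <- 2; errtab$err_y[] <- 2
  res3 <- covariate_analysis(errtab, NULL, arena_box())
  expect_true(is.na(res3$correlations$rho[res3$correlations$covariate ==
                                            "summed_population_count"]))
})

test_that("flat-decoder cross-validation is deterministic and beats chance", {
  ses <- small_session(duration_s = 200, n_place = 12, n_inter = 1, seed = 73)
  cfg <- run_config(window_len_ms = 1400, n_folds = 5, rng_seed = 73)
  cv1 <- run_cv(ses$spikes, ses$traj, "flat", cfg)
  cv2 <- run_cv(ses$spikes, ses$traj, "flat", cfg)
  expect_identical(cv1$samples$err, cv2$samples$err)
  expect_lt(cv1$summary$median_cm, cv1$summary$chance_median_cm)
  # every reported error comes from a retained validation sample
  n_windows <- ncol(count_in_windows(ses$spikes, 1.4, 0.2,
                                     validate_session(ses$spikes,
                                                      ses$traj)$usable_span)$counts)
  folds <- blocked_folds(n_windows, 5, ceiling(1.4 / 0.2))
  retained <- sort(unlist(lapply(folds, function(f) f$val_idx)))
  expect_true(all(cv1$samples$sample_idx %in% retained))
  per_fold_meds <- cv1$per_fold$median_cm
  expect_true(all(per_fold_meds < cv1$summary$chance_median_cm * 1.5))
})

test_that("window scan produces one row per length with an interior optimum", {
  ses <- small_session(duration_s = 200, n_place = 12, n_inter = 1, seed = 74)
  cfg <- run_config(n_folds = 5, rng_seed = 74)
  scan <- window_scan(ses$spikes, ses$traj, window_lens_ms = c(200, 1400, 4000),
                      decoder = "flat", cfg = cfg)
  expect_equal(scan$window_ms, c(200, 1400, 4000))
  expect_equal(nrow(scan), 3L)
  # short windows are count-starved: the 200 ms error exceeds the 1400 ms one
  expect_gt(scan$median_cm[1], scan$median_cm[2])
})

test_that("downsampling experiment runs the configured subsets", {
  ses <- small_session(duration_s = 120, n_place = 8, n_inter = 0, seed = 75)
  cfg <- run_config(window_len_ms = 1400, n_folds = 4, rng_seed = 75)
  res <- downsampling_experiment(ses$spikes, ses$traj, sizes = c(4, 8),
                                 n_sets = 2, decoder = "flat", cfg = cfg)
  expect_equal(res$size, c(4, 8))
  expect_true(all(is.finite(res$mean_of_means_cm)))
  expect_warning(downsampling_experiment(ses$spikes, ses$traj, sizes = 20,
                                         n_sets = 1, cfg = cfg),
                 "skipped")
})
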