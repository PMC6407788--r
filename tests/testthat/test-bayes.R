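test_that("Poisson log-likelihoods match the product formula on a toy", {
  maps <- toy_maps(rbind(c(1, 5, 1), c(5, 1, 1)))
  ll <- log_likelihood_map(c(5, 0), maps, T_s = 1)
  # enumerated directly: likelihoods proportional to (e^-6, 3125 e^-6, e^-2)
  expect_equal(exp(ll - ll[1]), c(1, 3125, exp(4)), tolerance = 1e-9)
  expect_equal(which.max(ll), 2L)

  # K = 0: log-likelihood reduces to -T * sum_i alpha_i(x)
  ll0 <- log_likelihood_map(c(0, 0), maps, T_s = 2)
  expect_equal(ll0, -2 * colSums(maps$rate_hz), tolerance = 1e-12)
  expect_error(log_likelihood_map(c(-1, 0), maps, 1), "negative")
  expect_error(log_likelihood_map(c(1, 0, 0), maps, 1), "units")
})

test_that("log-domain evaluation agrees with the direct-domain oracle", {
  set.seed(50)
  for (rep in 1:50) {
    nu <- sample(1:4, 1); nb <- sample(2:6, 1)
    rate <- matrix(runif(nu * nb, 0.05, 20), nu, nb)
    K <- rpois(nu, 3); K[K > 10] <- 10
    T_s <- runif(1, 0.2, 4)
    maps <- toy_maps(rate)
    ll <- log_likelihood_map(K, maps, T_s)
    direct <- apply(rate, 2, function(a)
      prod((T_s * a)^K / factorial(K) * exp(-T_s * a)))
    expect_equal(exp(ll), direct, tolerance = 1e-9)
  }
})

test_that("flat decoding picks the maximum-likelihood bin with normalised posterior", {
  maps <- toy_maps(rbind(c(1, 5, 1), c(5, 1, 1)))
  d <- decode_flat(toy_wc(cbind(c(5L, 0L))), maps)
  expect_equal(d$bin, 2L)
  expect_gt(d$posterior[1, 2], 0.98)
  expect_equal(rowSums(d$posterior), 1, tolerance = 1e-9)
  expect_equal(d$positions[1, ], maps$grid$centers[2, ], ignore_attr = TRUE)

  # identical ratemaps in all bins: uniform posterior, tie broken to bin 1
  maps_u <- toy_maps(rbind(c(2, 2, 2), c(3, 3, 3)))
  du <- decode_flat(toy_wc(cbind(c(1L, 2L), c(0L, 4L))), maps_u)
  expect_equal(du$bin, c(1L, 1L))
  expect_equal(du$posterior[1, ], rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(decode_flat(toy_wc(cbind(c(1L, 1L)), unit_ids = c("x", "y")),
                           maps), "unit ids")
})

test_that("flat decoding equals exhaustive enumeration on random toys", {
  set.seed(51)
  for (rep in 1:200) {
    nu <- sample(1:4, 1); nb <- sample(2:6, 1)
    rate <- matrix(runif(nu * nb, 0.05, 15), nu, nb)
    K <- matrix(pmin(rpois(nu * 3, 2), 8L), nu, 3)
    T_s <- runif(1, 0.5, 2)
    maps <- toy_maps(rate)
    d <- decode_flat(toy_wc(K, window_len_s = T_s, stride_s = T_s), maps)
    for (w in 1:3) {
      post <- oracle_flat_posterior(K[, w], rate, T_s)
      expect_equal(d$posterior[w, ], post, tolerance = 1e-9)
      expect_equal(d$bin[w], which.max(post))
    }
  }
})

test_that("likelihood argmax follows a single-bin rate advantage", {
  # raising one unit's rate at the bin where its count dominates never moves
  # the argmax away from that bin
  set.seed(52)
  for (rep in 1:30) {
    nu <- sample(2:4, 1); nb <- sample(3:6, 1)
    rate <- matrix(runif(nu * nb, 0.5, 5), nu, nb)
    j <- sample(nb, 1); i <- sample(nu, 1)
    rate[i, j] <- 50                      # strong advantage at bin j
    K <- integer(nu); K[i] <- 30L         # count evidence for unit i
    maps <- toy_maps(rate)
    d <- decode_flat(toy_wc(matrix(K, ncol = 1)), maps)
    expect_equal(d$bin, j)
  }
})

test_that("memory decoder with uniform prior and no continuity reduces to flat", {
  ses <- small_session(duration_s = 90, n_place = 8, n_inter = 1, seed = 53)
  maps <- compute_ratemaps(ses$spikes, ses$traj)
  wc <- count_in_windows(ses$spikes, 1.0, 0.5)
  dflat <- decode_flat(wc, maps)
  dmem <- decode_with_memory(wc, maps, prior = NULL, continuity = FALSE)
  expect_equal(dmem$bin, dflat$bin)
  expect_equal(dmem$positions, dflat$positions, tolerance = 1e-9)
  expect_equal(dmem$posterior, dflat$posterior, tolerance = 1e-9)
})

test_that("a tight continuity constraint can override the likelihood", {
  # first window pins the decode at bin 3 (strong likelihood), second window's
  # counts favour bin 2, but sigma floored at a fraction of the bin spacing
  # keeps the decode at bin 3
  rate <- rbind(c(1, 5, 1), c(1, 1, 20))
  maps2 <- toy_maps(rate)
  K <- cbind(c(0L, 9L), c(5L, 0L))
  mp <- memory_params(history_len = 15, scale = 1, min_sigma_cm = 0.2)
  d <- decode_with_memory(toy_wc(K), maps2, prior = NULL, mp = mp)
  expect_equal(d$bin[1], 3L)
  expect_equal(d$bin[2], 3L)              # continuity wins over likelihood
  dfree <- decode_flat(toy_wc(K), maps2)
  expect_equal(dfree$bin[2], 2L)          # ...which alone would say bin 2

  # a stationary decoded history floors sigma and keeps the path put
  K3 <- cbind(c(0L, 9L), c(0L, 9L), c(0L, 9L), c(5L, 0L))
  d3 <- decode_with_memory(toy_wc(K3), maps2, prior = NULL, mp = mp)
  expect_true(all(d3$bin == 3L))
})

test_that("occupancy prior shifts the first decoded window", {
  maps_u <- toy_maps(rbind(c(2, 2, 2)))
  pr <- occupancy_prior(c(0.1, 0.1, 9.8))
  d <- decode_with_memory(toy_wc(cbind(0L)), maps_u, prior = pr,
                          continuity = FALSE)
  expect_equal(d$bin[1], 3L)
  expect_equal(d$posterior[1, 3], 0.98, tolerance = 1e-9)
})
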