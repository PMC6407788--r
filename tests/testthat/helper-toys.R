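# Hand-constructed fixtures and independent oracles shared across tests.

# A minimal ratemap_set built directly from a units x bins rate matrix
# (1D bin centers at 1, 3, 5, ... unless centers given).
toy_maps <- function(rate, centers = NULL, bin_cm = 2) {
  rate <- as.matrix(rate)
  nb <- ncol(rate)
  if (is.null(centers))
    centers <- cbind(x = (seq_len(nb) - 0.5) * bin_cm, y = rep(0, nb))
  structure(list(rate_hz = rate, occupancy_s = rep(1, nb),
                 visited = rep(TRUE, nb),
                 grid = list(centers = centers, nx = nb, ny = 1L,
                             bin_cm = bin_cm, dims = ncol(centers)),
                 unit_ids = rownames(rate) %||% paste0("u", seq_len(nrow(rate))),
                 sigma_bins = 0, rate_floor_hz = 0),
            class = "ratemap_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# windowed_counts wrapper around a units x windows count matrix
toy_wc <- function(counts, window_len_s = 1, stride_s = 1,
                   unit_ids = NULL) {
  counts <- as.matrix(counts)
  structure(list(counts = counts,
                 window_centers = seq_len(ncol(counts)) * stride_s -
                   stride_s + window_len_s / 2,
                 window_len_s = window_len_s, stride_s = stride_s,
                 unit_ids = unit_ids %||% rownames(counts) %||%
                   paste0("u", seq_len(nrow(counts)))),
            class = "windowed_counts")
}

# Direct-domain Poisson decoding oracle: evaluates the product formula
# prod_i (T a_i(x))^k_i / k_i! exp(-T a_i(x)) bin by bin, no logs.
oracle_flat_posterior <- function(counts_K, rate, T_s) {
  lik <- apply(rate, 2, function(a)
    prod((T_s * a)^counts_K / factorial(counts_K) * exp(-T_s * a)))
  lik / sum(lik)
}

# Brute-force mass-conserving masked Gaussian smoothing (double loop).
oracle_smooth <- function(values, mask, nx, ny, sigma) {
  r <- ceiling(4 * sigma)
  k <- function(d2) exp(-d2 / (2 * sigma^2))
  out <- matrix(0, nx, ny)
  vm <- matrix(values, nx, ny); mm <- matrix(mask, nx, ny)
  for (sx in 1:nx) for (sy in 1:ny) {
    if (!mm[sx, sy] || vm[sx, sy] == 0) next
    xs <- max(1, sx - r):min(nx, sx + r)
    ys <- max(1, sy - r):min(ny, sy + r)
    w <- outer(xs, ys, function(a, b) k((a - sx)^2 + (b - sy)^2)) *
      mm[xs, ys]
    out[xs, ys] <- out[xs, ys] + vm[sx, sy] * w / sum(w)
  }
  out[!mm] <- NA_real_
  as.vector(out)
}

# small deterministic sequence dataset for regressor tests
toy_sequences <- function(D = 6, Tn = 5, N = 3, seed = 42, targets = NULL) {
  set.seed(seed)
  X <- array(stats::rpois(D * Tn * N, 2), dim = c(D, Tn, N),
             dimnames = list(NULL, NULL, paste0("u", seq_len(N))))
  if (is.null(targets)) targets <- matrix(stats::rnorm(D * 2, 50, 10), D, 2)
  structure(list(inputs = X, targets = targets,
                 sample_to_window = seq_len(D) + Tn - 1L,
                 window_centers = seq_len(D + Tn - 1L) * 0.2,
                 unit_ids = paste0("u", seq_len(N)), dims = ncol(targets),
                 seq_len = Tn),
            class = "sequence_dataset")
}

# a short synthetic open-field session for integration-style tests
small_session <- function(duration_s = 150, n_place = 10, n_inter = 1,
                          seed = 7) {
  simulate_session(sim_config(n_place_units = n_place,
                              n_interneurons = n_inter,
                              duration_s = duration_s, rng_seed = seed))
}
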